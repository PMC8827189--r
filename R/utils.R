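# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Cholesky factor with a single logged jitter attempt.  Zero-length terminal
## branches produce duplicated rows in phylogenetic covariance matrices; a
## diagonal jitter of 1e-10 * mean(diag) restores positive definiteness
## without materially changing any estimate.  Anything beyond that is an
## error, never a silent regularization.
chol_pd <- function(V, context = "covariance matrix") {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    jit <- 1e-10 * mean(diag(V))
    message("gctherm: adding diagonal jitter ", format(jit),
            " to a singular ", context)
    U <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
    if (is.null(U)) stop("singular model ", context,
                         ": not positive definite even after jitter")
  }
  U
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Multivariate normal log-density with constant mean, via Cholesky.
ldmvn <- function(y, mu, V) {
  U <- chol_pd(V)
  z <- forwardsolve(t(U), y - mu)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(z^2))
}

## Bounded scalar maximization with a 5-interval multistart, to avoid the
## local optima that single-bracket golden-section search can fall into on
## profile likelihood surfaces.
profile_optimize <- function(fn, lower, upper, n_intervals = 5L,
                             tol = 1e-4) {
  brk <- seq(lower, upper, length.out = n_intervals + 1L)
  vals <- vapply(brk, fn, numeric(1))
  i <- which.max(vals)
  best <- list(maximum = brk[i], objective = vals[i])
  o <- stats::optimize(fn, lower = brk[max(1L, i - 1L)],
                       upper = brk[min(length(brk), i + 1L)],
                       maximum = TRUE, tol = tol * (upper - lower))
  if (o$objective > best$objective) best <- o
  best
}

## Deterministic sub-stream seeds: a counter-based key so that component i of
## a generator never perturbs component j, and adding rounds never reshuffles
## earlier ones.  Kept strictly below 2^31 - 1.
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  h <- 0
  for (k in key) h <- (h * 1000003 + (as.double(k) %% 2147483647)) %% 2147483629
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
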