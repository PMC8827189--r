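# Levy-jump trait evolution: Brownian motion plus a compound Poisson
# process of discrete Gaussian jumps.  The likelihood marginalizes the
# per-branch jump counts by importance sampling from the Poisson prior
# (common random numbers across parameter values: a fixed uniform matrix is
# inverted through the Poisson quantile function, so counts vary smoothly
# with the jump intensity).

branch_table <- function(tree) {
  n <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- ifelse(child <= n, tree$tip.label[child],
                if (!is.null(tree$node.label))
                  tree$node.label[child - n] else paste0("node", child))
  lab[lab == "" | is.na(lab)] <- paste0("node", child[lab == "" | is.na(lab)])
  data.frame(branch = child, label = lab, length = tree$edge.length,
             stringsAsFactors = FALSE)
}

## n x B indicator matrix: Z[i, b] = 1 iff tip i descends from branch b
## (the branch above child node b's subtree).
branch_indicators <- function(tree) {
  n <- length(tree$tip.label)
  B <- nrow(tree$edge)
  edge <- reorder(tree, "postorder")$edge
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(edge)))
    desc[[edge[e, 1]]] <- c(desc[[edge[e, 1]]], desc[[edge[e, 2]]])
  Z <- matrix(0, n, B)
  for (b in seq_len(B)) Z[desc[[tree$edge[b, 2]]], b] <- 1
  rownames(Z) <- tree$tip.label
  Z
}

jump_prep <- function(tree) {
  validate_tree(tree)
  list(tree = tree,
       C = ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label],
       Z = branch_indicators(tree),
       branches = branch_table(tree),
       zz_cache = new.env(parent = emptyenv()))
}

## per-branch outer product Z_b Z_b', cached lazily (only jumped branches
## ever need it)
branch_outer <- function(prep, b) {
  key <- as.character(b)
  hit <- prep$zz_cache[[key]]
  if (is.null(hit)) {
    hit <- tcrossprod(prep$Z[, b])
    prep$zz_cache[[key]] <- hit
  }
  hit
}

#' Simulate traits under the Levy-jump model
#'
#' Evolves a trait down the tree: each branch of length \eqn{t} adds a
#' Brownian increment \eqn{N(0, \sigma^2 t)} plus \eqn{K \sim
#' Poisson(\lambda_J t)} jumps, each \eqn{N(0, \sigma_J^2)}.
#'
#' @param tree Rooted tree with branch lengths.
#' @param sigma2 Brownian rate (per unit branch length).
#' @param lambda_j Jump intensity (expected jumps per unit branch length).
#' @param sigmaj2 Jump size variance.
#' @param mu0 Root state.
#' @param seed Integer seed.
#' @return List with \code{tips} (named tip values) and \code{truth} (one
#'   row per branch: child node id, label, length, jump count, summed jump
#'   size).
#' @export
simulate_levy <- function(tree, sigma2, lambda_j, sigmaj2, mu0 = 0,
                          seed = 1L) {
  validate_tree(tree)
  stopifnot(sigma2 >= 0, lambda_j >= 0, sigmaj2 >= 0)
  n <- length(tree$tip.label)
  edge <- reorder(tree, "cladewise")$edge
  len <- reorder(tree, "cladewise")$edge.length
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- mu0
  bt <- branch_table(tree)
  counts <- jump_sum <- numeric(nrow(bt))
  names(counts) <- names(jump_sum) <- bt$branch
  with_seed(seed, {
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; ch <- edge[e, 2]; t <- len[e]
      k <- stats::rpois(1, lambda_j * t)
      js <- if (k > 0) sum(stats::rnorm(k, 0, sqrt(sigmaj2))) else 0
      val[ch] <- val[p] + stats::rnorm(1, 0, sqrt(sigma2 * t)) + js
      counts[as.character(ch)] <- k
      jump_sum[as.character(ch)] <- js
    }
  })
  bt$n_jumps <- counts[as.character(bt$branch)]
  bt$jump_sum <- jump_sum[as.character(bt$branch)]
  list(tips = stats::setNames(val[seq_len(n)], tree$tip.label), truth = bt)
}

## Draw per-branch jump-count configurations: U is an M x B uniform matrix
## (held fixed for common random numbers); counts capped at cap, beyond
## which prior mass is negligible at the intensities used here.
draw_configs <- function(U, lambda_j, lens, cap = 10L) {
  M <- nrow(U); B <- ncol(U)
  K <- matrix(stats::qpois(U, rep(lambda_j * lens, each = M)), M, B)
  K[K > cap] <- cap
  K
}

## Log-density of y under each configuration row of K, with duplicate
## configurations evaluated once.
config_logdens <- function(y, mu0, sigma2, sigmaj2, K, prep) {
  C <- prep$C
  M <- nrow(K)
  ## group duplicate configurations via a two-channel numeric hash (exact
  ## count vectors are small integers, so collisions are negligible and the
  ## grouping only trades duplicate Cholesky factorizations)
  B <- ncol(K)
  w <- cbind(log(seq_len(B) + 1), sqrt(seq_len(B) + 0.5))
  h <- K %*% w
  key <- paste(h[, 1], h[, 2])
  uk <- which(!duplicated(key))
  ld_u <- vapply(uk, function(m) {
    km <- K[m, ]
    nz <- which(km > 0)
    V <- sigma2 * C
    for (b in nz) V <- V + (sigmaj2 * km[b]) * branch_outer(prep, b)
    ldmvn(y, mu0, V)
  }, numeric(1))
  ld_u[match(key, key[uk])]
}

#' Monte-Carlo marginal log-likelihood of the Levy-jump model
#'
#' Importance sampling from the Poisson prior over per-branch jump counts:
#' \eqn{\log L = \log \frac{1}{M}\sum_m N(y;\ \mu_0 1,\ \sigma^2 C +
#' \sigma_J^2 \sum_b k_b^{(m)} V_b)} where \eqn{V_b} is the indicator
#' block of tips sharing branch \eqn{b}.  With \eqn{\lambda_J = 0} or
#' \eqn{\sigma_J^2 = 0} every draw is the zero configuration and the value
#' equals the closed-form Brownian log-likelihood.
#'
#' @param tree Rooted tree (or a prepared structure from an earlier call).
#' @param y Named tip values.
#' @param params List with \code{sigma2}, \code{lambda_j}, \code{sigmaj2},
#'   \code{mu0}.
#' @param M Number of importance draws (>= 100).
#' @param seed Seed for the draws (ignored when \code{U} is supplied).
#' @param U Optional fixed M x B uniform matrix for common random numbers.
#' @return List with \code{logL}, \code{se} (Monte-Carlo standard error of
#'   logL), and the draw internals (\code{ld}, \code{K}) for reuse.
#' @export
mc_loglik <- function(tree, y, params, M = 1000L, seed = 1L, U = NULL) {
  prep <- if (is.list(tree) && !inherits(tree, "phylo")) tree
          else jump_prep(tree)
  stopifnot(M >= 100L || !is.null(U))
  y <- y[rownames(prep$C)]
  B <- ncol(prep$Z)
  if (is.null(U)) U <- with_seed(seed, matrix(stats::runif(M * B), M, B))
  M <- nrow(U)
  if (params$sigmaj2 == 0 || params$lambda_j == 0) {
    ll <- ldmvn(y, params$mu0, params$sigma2 * prep$C)
    return(list(logL = ll, se = 0, ld = rep(ll, M),
                K = matrix(0L, M, B), U = U))
  }
  K <- draw_configs(U, params$lambda_j, prep$branches$length)
  ld <- config_logdens(y, params$mu0, params$sigma2, params$sigmaj2,
                       K, prep)
  logL <- logsumexp(ld) - log(M)
  w <- exp(ld - max(ld))
  se <- stats::sd(w) / (mean(w) * sqrt(M))
  list(logL = logL, se = se, ld = ld, K = K, U = U)
}

#' Fit the Levy-jump model and compare it to Brownian motion
#'
#' Maximizes the importance-sampled log-likelihood over
#' \eqn{(\sigma^2, \lambda_J, \sigma_J^2, \mu_0)} with common random
#' numbers (the same uniform draws across all parameter evaluations), then
#' reports AIC against the closed-form Brownian fit.  Free-parameter counts:
#' 4 for the jump model, 2 for Brownian motion (\eqn{\sigma^2, \mu_0}).
#'
#' @param tree Rooted tree with branch lengths.
#' @param y Named tip values.
#' @param M Importance draws per likelihood evaluation.
#' @param seed Seed for the common draws.
#' @param maxit Optimizer iteration cap (Nelder-Mead).
#' @return A \code{"jump_fit"}: parameter estimates, \code{logL} with MC
#'   standard error, \code{AIC}, the Brownian fit (\code{bm}), per-branch
#'   posterior probabilities (\code{pp}), and a convergence flag.
#' @export
fit_jump_model <- function(tree, y, M = 300L, seed = 1L, maxit = 300L) {
  prep <- jump_prep(tree)
  n <- nrow(prep$C)
  if (n < 10L) stop("need at least 10 tips")
  y <- y[rownames(prep$C)]
  ## closed-form BM fit (GLS mean, profiled sigma2)
  U <- chol_pd(prep$C, "phylogenetic covariance")
  one <- rep(1, n)
  yt <- forwardsolve(t(U), y); ot <- forwardsolve(t(U), one)
  mu_bm <- sum(yt * ot) / sum(ot^2)
  s2_bm <- sum((yt - mu_bm * ot)^2) / n
  ll_bm <- -0.5 * (n * log(2 * pi) + n * log(s2_bm) + n +
                   2 * sum(log(diag(U))))
  bm <- list(mu0 = mu_bm, sigma2 = s2_bm, logL = ll_bm,
             AIC = 2 * 2 - 2 * ll_bm)
  B <- ncol(prep$Z)
  Umat <- with_seed(derive_seed(seed, 77L), matrix(stats::runif(M * B), M, B))
  negll <- function(par) {
    p <- list(sigma2 = exp(par[1]), lambda_j = exp(par[2]),
              sigmaj2 = exp(par[3]), mu0 = par[4])
    -mc_loglik(prep, y, p, U = Umat)$logL
  }
  TL <- sum(tree$edge.length)
  starts <- list(
    c(log(s2_bm * 0.7), log(2 / TL), log(max(s2_bm, stats::var(y) / 2)),
      mu_bm),
    c(log(s2_bm * 0.3), log(6 / TL), log(stats::var(y)), mu_bm))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  params <- list(sigma2 = exp(par[1]), lambda_j = exp(par[2]),
                 sigmaj2 = exp(par[3]), mu0 = par[4])
  ml <- mc_loglik(prep, y, params, U = Umat)
  pp <- posterior_from_draws(ml, prep)
  structure(list(
    params = params, logL = ml$logL, mc_se = ml$se, M = M,
    AIC = 2 * 4 - 2 * ml$logL, bm = bm, pp = pp$pp, ess = pp$ess,
    converged = best$convergence == 0, seed = seed), class = "jump_fit")
}

#' @export
print.jump_fit <- function(x, ...) {
  cat("Levy-jump model fit\n")
  cat("  sigma2 =", signif(x$params$sigma2, 4),
      " lambda_J =", signif(x$params$lambda_j, 4),
      " sigmaJ2 =", signif(x$params$sigmaj2, 4),
      " mu0 =", signif(x$params$mu0, 4), "\n")
  cat("  logL =", signif(x$logL, 6), "(MC se", signif(x$mc_se, 3), ")",
      " AIC =", signif(x$AIC, 6), "\n")
  cat("  BM comparison: logL =", signif(x$bm$logL, 6),
      " AIC =", signif(x$bm$AIC, 6), "\n")
  cat("  branches with pp > 0.5:", sum(x$pp$pp > 0.5),
      " (ESS", signif(x$ess, 4), ")\n")
  invisible(x)
}

posterior_from_draws <- function(ml, prep) {
  w <- exp(ml$ld - logsumexp(ml$ld))
  pp <- as.vector(crossprod(ml$K > 0, w))
  ess <- 1 / sum(w^2)
  out <- prep$branches
  out$pp <- pp
  list(pp = out, ess = ess)
}

#' Per-branch posterior probability of at least one jump
#'
#' Self-normalized importance-sampling estimate: configurations drawn from
#' the Poisson prior are weighted by their Gaussian data density, and
#' \eqn{pp_b = \sum_m w_m \, 1\{k_b^{(m)} \ge 1\}}.
#'
#' @param tree Rooted tree with branch lengths.
#' @param y Named tip values.
#' @param fit A \code{"jump_fit"} or a parameter list
#'   (\code{sigma2}, \code{lambda_j}, \code{sigmaj2}, \code{mu0}).
#' @param M Importance draws.
#' @param seed Seed.
#' @return Data.frame (branch, label, length, pp) with attribute
#'   \code{ess}; a warning is attached when the effective sample size drops
#'   below 50.
#' @export
branch_jump_posteriors <- function(tree, y, fit, M = 1000L, seed = 1L) {
  params <- if (inherits(fit, "jump_fit")) fit$params else fit
  prep <- jump_prep(tree)
  ml <- mc_loglik(prep, y[rownames(prep$C)], params, M = M, seed = seed)
  res <- posterior_from_draws(ml, prep)
  out <- res$pp
  attr(out, "ess") <- res$ess
  if (res$ess < 50) {
    attr(out, "warning") <- "effective sample size below 50"
    warning("importance-sampling effective sample size below 50 (",
            signif(res$ess, 3), ")")
  }
  out
}

#' Precision-recall calibration of the jump-call threshold
#'
#' Simulates datasets under fitted Levy-jump parameters (with known truth),
#' recomputes branch posteriors for each, and scores calls at every
#' threshold of the grid: a branch is a true positive when called and truly
#' carrying at least one jump.  Returns the full precision-recall curve and
#' the smallest threshold reaching a requested precision.
#'
#' @param tree Rooted tree with branch lengths.
#' @param fit A \code{"jump_fit"} or parameter list.
#' @param n_sims Number of simulated datasets.
#' @param pp_grid Thresholds to score.
#' @param seed Master seed.
#' @param M Importance draws per simulated dataset.
#' @param target_precision Requested precision for threshold selection.
#' @return List with \code{curve} (threshold, TP, FP, FN, precision,
#'   recall) and \code{threshold} (smallest grid value whose precision
#'   meets the target; NA when unattained).
#' @export
calibrate_threshold <- function(tree, fit, n_sims = 20L,
                                pp_grid = seq(0, 0.95, by = 0.05),
                                seed = 1L, M = 500L,
                                target_precision = 0.85) {
  params <- if (inherits(fit, "jump_fit")) fit$params else fit
  prep <- jump_prep(tree)
  tp <- fp <- fn <- numeric(length(pp_grid))
  total_true <- 0L
  for (s in seq_len(n_sims)) {
    sim <- simulate_levy(tree, params$sigma2, params$lambda_j,
                         params$sigmaj2, params$mu0,
                         seed = derive_seed(seed, s))
    ml <- mc_loglik(prep, sim$tips[rownames(prep$C)], params, M = M,
                    seed = derive_seed(seed, s, 2L))
    pp <- posterior_from_draws(ml, prep)$pp
    truth <- sim$truth$n_jumps[match(pp$branch, sim$truth$branch)] > 0
    total_true <- total_true + sum(truth)
    for (g in seq_along(pp_grid)) {
      called <- pp$pp >= pp_grid[g]
      tp[g] <- tp[g] + sum(called & truth)
      fp[g] <- fp[g] + sum(called & !truth)
      fn[g] <- fn[g] + sum(!called & truth)
    }
  }
  if (total_true == 0L)
    stop("no true jumps across simulations: recall undefined")
  curve <- data.frame(threshold = pp_grid, TP = tp, FP = fp, FN = fn,
                      precision = ifelse(tp + fp > 0, tp / (tp + fp), NA),
                      recall = tp / (tp + fn))
  ## monotone cleanup (standard PR interpolation): interpolated precision at
  ## recall r is the best precision achievable at recall >= r, so the
  ## cleaned precision is nonincreasing in recall
  curve$precision_clean <- cummax(ifelse(is.na(curve$precision), 0,
                                         curve$precision))
  ok <- which(!is.na(curve$precision) &
              curve$precision >= target_precision)
  list(curve = curve,
       threshold = if (length(ok)) pp_grid[min(ok)] else NA_real_,
       target_precision = target_precision)
}

#' Correlation between jump magnitudes and co-trait changes
#'
#' For each called branch, the change in each trait is the
#' Brownian-GLS ancestral estimate at the child minus at the parent (the
#' observed value is used when the child is a tip).  Signed changes are
#' correlated by Spearman's rank correlation with tie-averaged ranks;
#' two-sided P is exact by permutation for \eqn{n \le 10} and a
#' t-approximation otherwise.
#'
#' @param tree Rooted tree with branch lengths.
#' @param x,y Named tip values of the two traits.
#' @param branches Child-node ids of the called branches (>= 5).
#' @return List with \code{n}, \code{rho}, \code{p.value}, and the signed
#'   per-branch changes \code{dx}, \code{dy}.
#' @export
jump_change_correlation <- function(tree, x, y, branches) {
  validate_tree(tree)
  if (length(branches) < 5L) stop("need at least 5 called branches")
  n <- length(tree$tip.label)
  ax <- ancestral_states(tree, x)
  ay <- ancestral_states(tree, y)
  node_val <- function(v, tipvals, anc)
    if (v <= n) unname(tipvals[tree$tip.label[v]])
    else unname(anc[as.character(v)])
  parent <- tree$edge[match(branches, tree$edge[, 2]), 1]
  if (anyNA(parent)) stop("unknown branch id(s)")
  dx <- vapply(seq_along(branches), function(i)
    node_val(branches[i], x, ax) - node_val(parent[i], x, ax), numeric(1))
  dy <- vapply(seq_along(branches), function(i)
    node_val(branches[i], y, ay) - node_val(parent[i], y, ay), numeric(1))
  ct <- spearman_perm(dx, dy)
  list(n = length(dx), rho = ct$rho, p.value = ct$p.value, dx = dx, dy = dy)
}

#' Spearman rank correlation with exact permutation P for small n
#'
#' Tie-averaged ranks; for \eqn{n \le} \code{exact_max} the two-sided P is
#' the exact fraction of the \eqn{n!} permutations with \eqn{|\rho|} at
#' least the observed value, otherwise the t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_max Largest n for exact enumeration (capped at 10).
#' @return List with \code{rho}, \code{p.value}, \code{method}.
#' @export
spearman_perm <- function(x, y, exact_max = 10L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= min(exact_max, 10L)) {
    rho_all <- perm_spearman_dist(rx, ry)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p.value = p, method = method)
}

## All-permutation Spearman distribution, blockwise over the first element
## (index permutations of n-1 built once) to keep memory modest at n = 10.
perm_spearman_dist <- function(rx, ry) {
  n <- length(rx)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) stop("constant ranks")
  perm_index <- function(m) {            # all permutations of 1..m, by row
    if (m == 1L) return(matrix(1L, 1))
    sub <- perm_index(m - 1L)
    do.call(rbind, lapply(seq_len(m), function(i) {
      rest <- seq_len(m)[-i]
      cbind(i, matrix(rest[sub], nrow(sub)))
    }))
  }
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  P <- perm_index(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest_vals <- cy[-i]
    M <- matrix(rest_vals[P], nrow(P))   # permuted values at positions 2..n
    out[[i]] <- cx[1] * cy[i] + as.vector(M %*% cx[-1])
  }
  unlist(out) / ((n - 1) * sx * sy)
}
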