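# PGLS machinery.  The model parameter (lambda, alpha or r) is estimated by
# maximum likelihood with the regression coefficients and sigma^2 profiled
# out analytically at each candidate value; the scalar search is bounded
# (lambda in [0,1], log alpha in [-10,10], r in [-10,1]) with a 5-interval
# multistart.

## GLS given the unit-rate structure matrix V0 (sigma2 factored out).
gls_profile <- function(y, X, V0) {
  n <- length(y)
  U <- chol_pd(V0, "model covariance")
  yt <- forwardsolve(t(U), y)
  Xt <- forwardsolve(t(U), X)
  colnames(Xt) <- colnames(X)
  qr_x <- qr(Xt)
  if (qr_x$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qr_x, yt)
  res <- yt - Xt %*% beta
  rss <- sum(res^2)
  s2_ml <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  logL <- -0.5 * (n * log(2 * pi) + n * log(s2_ml) + n + logdet)
  XtX_inv <- chol2inv(qr.R(qr_x))
  list(beta = drop(beta), rss = rss, sigma2_ml = s2_ml, logL = logL,
       cov_unit = XtX_inv, n = n)
}

param_bounds <- function(model) {
  switch(model,
    lambda = c(0, 1),        # lambda itself
    OU     = c(-10, 10),     # log(alpha)
    EB     = c(-10, 1),      # r
    NULL)
}

make_params <- function(model, theta) {
  switch(model,
    BM     = list(model = "BM", sigma2 = 1),
    lambda = list(model = "lambda", sigma2 = 1, lambda = theta),
    OU     = list(model = "OU", sigma2 = 1, alpha = exp(theta)),
    EB     = list(model = "EB", sigma2 = 1, r = theta))
}

## Core fitter on a precomputed phylo_cov (used by pgls() and, directly on
## covariance submatrices, by resample_pgls()).
pgls_fit_cov <- function(cov, y, X, model, fixed_param = NULL) {
  eval_theta <- function(theta) {
    V0 <- model_covariance(cov, make_params(model, theta))
    gls_profile(y, X, V0)
  }
  if (model == "BM") {
    theta_hat <- NA_real_
    fit <- eval_theta(NA_real_)
    n_par_extra <- 0L
  } else if (!is.null(fixed_param)) {
    theta_hat <- if (model == "OU") log(fixed_param) else fixed_param
    fit <- eval_theta(theta_hat)
    n_par_extra <- 0L
  } else {
    b <- param_bounds(model)
    opt <- profile_optimize(function(th) eval_theta(th)$logL, b[1], b[2])
    theta_hat <- opt$maximum
    fit <- eval_theta(theta_hat)
    n_par_extra <- 1L
  }
  p <- ncol(X)
  k <- p + 1L + n_par_extra                    # coefficients + sigma2 + param
  sigma2_res <- fit$rss / (fit$n - p)
  se <- sqrt(diag(fit$cov_unit) * sigma2_res)
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = fit$n - p)
  param <- switch(model, BM = NULL,
                  lambda = c(lambda = theta_hat),
                  OU = c(alpha = exp(theta_hat)),
                  EB = c(r = theta_hat))
  structure(list(
    coefficients = fit$beta, se = se, t = tval, p = pval,
    model = model, param = param, sigma2 = fit$sigma2_ml,
    logL = fit$logL, AIC = 2 * k - 2 * fit$logL, k = k,
    n = fit$n, df.residual = fit$n - p), class = "pgls_fit")
}

align_traits <- function(tree, ...) {
  vals <- list(...)
  keep <- tree$tip.label
  for (v in vals) keep <- intersect(keep, names(v)[!is.na(v)])
  dropped <- length(tree$tip.label) - length(keep)
  if (dropped > 0)
    message("gctherm: dropping ", dropped, " tip(s) with missing trait data")
  if (length(keep) < 3L) stop("fewer than 3 tips with complete data")
  keep
}

#' Phylogenetic generalized least squares regression
#'
#' Regresses a response trait on one or more predictors with residual
#' covariance derived from the phylogeny under one of four trait-evolution
#' models (see [model_covariance()]).  The model parameter (Pagel's
#' \eqn{\lambda}, OU \eqn{\alpha}, or EB \eqn{r}) is estimated by maximum
#' likelihood jointly with the coefficients; \eqn{\sigma^2} and the
#' coefficients are profiled analytically.  Slope standard errors come from
#' the GLS coefficient covariance with residual variance on
#' \eqn{n - p} degrees of freedom, and two-sided P values from the t
#' distribution with the same df.  AIC counts all free parameters
#' (coefficients, \eqn{\sigma^2}, and the model parameter when estimated) so
#' fits are comparable across models on identical data.
#'
#' @param tree Rooted tree with branch lengths.
#' @param y Named numeric response (tip labels as names).
#' @param x Named numeric predictor, or a matrix/data.frame of predictors
#'   with tip labels as rownames (multiple-predictor regression).
#' @param model One of \code{"BM"}, \code{"lambda"}, \code{"OU"},
#'   \code{"EB"}.
#' @param fixed_param Optional: fix the model parameter instead of
#'   estimating it (e.g. \code{lambda = 0} reduces to ordinary least
#'   squares).
#' @return A \code{"pgls_fit"} with coefficients, SE, t, two-sided P,
#'   fitted parameter, \eqn{\sigma^2} (ML), logL and AIC.
#' @examples
#' tr <- gen_tree(40, seed = 1)
#' sim <- simulate_traits(tr, diag(2), seed = 1, trait_names = c("x", "y"))
#' y <- setNames(sim$y, sim$tip); x <- setNames(sim$x, sim$tip)
#' pgls(tr, y, x, model = "lambda")
#' @export
pgls <- function(tree, y, x, model = c("BM", "lambda", "OU", "EB"),
                 fixed_param = NULL) {
  model <- match.arg(model)
  validate_tree(tree)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(names(x), "x"))
  x <- as.matrix(x)
  xl <- lapply(seq_len(ncol(x)), function(j)
    stats::setNames(x[, j], rownames(x)))
  keep <- do.call(align_traits, c(list(tree, y), xl))
  yk <- y[keep]
  Xk <- cbind("(Intercept)" = 1, x[keep, , drop = FALSE])
  if (length(keep) <= ncol(Xk) + 1L)
    stop("too few tips (", length(keep), ") for ", ncol(Xk), " coefficients")
  cov <- phylo_covariance(tree, keep)
  fit <- pgls_fit_cov(cov, yk, Xk, model, fixed_param)
  fit$call_model <- model
  fit
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$model, " model), n = ", x$n, "\n", sep = "")
  if (!is.null(x$param))
    cat("  ", names(x$param), " = ", signif(x$param, 4), "\n", sep = "")
  tab <- data.frame(Estimate = x$coefficients, SE = x$se,
                    t = x$t, p = x$p)
  print(signif(tab, 4))
  cat("sigma2 =", signif(x$sigma2, 4), " logL =", signif(x$logL, 6),
      " AIC =", signif(x$AIC, 6), "\n")
  invisible(x)
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood estimate of Pagel's \eqn{\lambda} for a single trait
#' (intercept-only model), with mean and \eqn{\sigma^2} profiled out
#' analytically at each \eqn{\lambda}.  Significance is a likelihood-ratio
#' test against \eqn{\lambda = 0} on one chi-squared degree of freedom.
#'
#' @param tree Rooted tree with branch lengths.
#' @param x Named numeric trait vector.
#' @return A \code{"signal_estimate"}: \code{lambda}, \code{logL},
#'   \code{logL0}, \code{p.value}, \code{n}.
#' @export
pagel_lambda_signal <- function(tree, x) {
  validate_tree(tree)
  keep <- align_traits(tree, x)
  xv <- x[keep]
  if (stats::sd(xv) == 0) stop("degenerate trait: x is constant")
  cov <- phylo_covariance(tree, keep)
  offdiag <- cov$C[upper.tri(cov$C)]
  X <- matrix(1, length(xv), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(offdiag) == 0L || max(offdiag) <= 1e-12 * max(diag(cov$C))) {
    warning("star tree: likelihood is flat in lambda; reporting lambda = 0")
    f0 <- gls_profile(xv, X, model_covariance(cov, make_params("lambda", 0)))
    return(structure(list(lambda = 0, logL = f0$logL, logL0 = f0$logL,
                          p.value = 1, n = length(xv)),
                     class = "signal_estimate"))
  }
  eval_lam <- function(l)
    gls_profile(xv, X, model_covariance(cov, make_params("lambda", l)))
  opt <- profile_optimize(function(l) eval_lam(l)$logL, 0, 1)
  f1 <- eval_lam(opt$maximum)
  f0 <- eval_lam(0)
  lrt <- max(0, 2 * (f1$logL - f0$logL))
  structure(list(lambda = opt$maximum, logL = f1$logL, logL0 = f0$logL,
                 p.value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n = length(xv)),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat("Pagel's lambda signal: lambda =", signif(x$lambda, 4),
      " n =", x$n, "\n  logL =", signif(x$logL, 6),
      " logL(0) =", signif(x$logL0, 6),
      " LRT P =", format(x$p.value, digits = 3), "\n")
  invisible(x)
}

#' Phylogenetic paired t-test
#'
#' Tests whether two traits measured on the same tips differ in mean, with
#' the paired differences modeled as Brownian motion scaled by Pagel's
#' \eqn{\lambda}.  The mean difference is the GLS intercept; the t statistic
#' uses \eqn{n - 2} degrees of freedom (mean and variance estimated).  A
#' likelihood-ratio alternative is available.
#'
#' @param tree Rooted tree with branch lengths.
#' @param x1,x2 Named numeric traits on a common tip set.
#' @param method \code{"t"} (default) or \code{"lrt"}.
#' @return List with \code{mu_d}, \code{se}, \code{t}, \code{p.value},
#'   \code{lambda}, \code{n}.
#' @export
phylo_paired_ttest <- function(tree, x1, x2, method = c("t", "lrt")) {
  method <- match.arg(method)
  validate_tree(tree)
  keep <- align_traits(tree, x1, x2)
  d <- x1[keep] - x2[keep]
  if (stats::sd(d) == 0 && d[1] != 0)
    stop("zero-variance differences: paired t-test undefined")
  if (all(d == 0))
    return(list(mu_d = 0, se = 0, t = 0, p.value = 1, lambda = 0,
                n = length(d)))
  cov <- phylo_covariance(tree, keep)
  X <- matrix(1, length(d), 1)
  eval_lam <- function(l)
    gls_profile(d, X, model_covariance(cov, make_params("lambda", l)))
  opt <- profile_optimize(function(l) eval_lam(l)$logL, 0, 1)
  f <- eval_lam(opt$maximum)
  n <- length(d)
  s2 <- f$rss / (n - 1)
  se <- sqrt(s2 * f$cov_unit[1, 1])
  tval <- f$beta / se
  if (method == "t") {
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    ## LRT: free mean vs mean fixed at zero, same lambda profile
    eval0 <- function(l) {
      V0 <- model_covariance(cov, make_params("lambda", l))
      U <- chol_pd(V0)
      dt <- forwardsolve(t(U), d)
      s2_ml <- sum(dt^2) / n
      -0.5 * (n * log(2 * pi) + n * log(s2_ml) + n + 2 * sum(log(diag(U))))
    }
    l0 <- profile_optimize(eval0, 0, 1)$objective
    p <- stats::pchisq(max(0, 2 * (f$logL - l0)), 1, lower.tail = FALSE)
  }
  list(mu_d = unname(f$beta), se = unname(se), t = unname(tval),
       p.value = unname(p), lambda = opt$maximum, n = n)
}

#' Benjamini-Hochberg adjustment within a declared family
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]) with input
#' validation; family membership is decided by the caller.  Output order
#' matches input order.
#'
#' @param p Numeric vector of P values in (0, 1].
#' @return Adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("all P values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
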