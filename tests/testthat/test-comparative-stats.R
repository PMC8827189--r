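# PGLS under four models, Pagel's lambda signal, paired t-test, grouped BH.

test_that("PGLS with lambda forced to zero reduces to OLS", {
  ## ultrametric tree: lambda = 0 gives equal tip variances, hence OLS
  tr <- gen_tree(25, seed = 14)
  sim <- simulate_traits(tr, matrix(c(1, .5, .5, 1), 2), seed = 2,
                         trait_names = c("x", "y"))
  y <- stats::setNames(sim$y, sim$tip)
  x <- stats::setNames(sim$x, sim$tip)
  f0 <- pgls(tr, y, x, model = "lambda", fixed_param = 0)
  ols <- stats::lm(sim$y ~ sim$x)
  expect_equal(unname(f0$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-8)
})

test_that("PGLS coefficients match the closed-form GLS solution", {
  t4 <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  y <- stats::setNames(c(1.2, 0.7, -0.4, 2.5), c("A", "B", "C", "D"))
  x <- stats::setNames(c(0.1, 0.5, -1.0, 1.3), c("A", "B", "C", "D"))
  X <- cbind(1, x)
  cv <- phylo_covariance(t4)
  cases <- list(
    list(model = "BM", fixed = NULL,
         params = list(model = "BM", sigma2 = 1)),
    list(model = "lambda", fixed = 0.6,
         params = list(model = "lambda", sigma2 = 1, lambda = 0.6)),
    list(model = "OU", fixed = 1.3,
         params = list(model = "OU", sigma2 = 1, alpha = 1.3)),
    list(model = "EB", fixed = -0.8,
         params = list(model = "EB", sigma2 = 1, r = -0.8)))
  for (cs in cases) {
    V <- model_covariance(cv, cs$params)
    beta_direct <- solve(t(X) %*% solve(V) %*% X,
                         t(X) %*% solve(V) %*% y)
    fit <- pgls(t4, y, x, model = cs$model, fixed_param = cs$fixed)
    expect_equal(unname(fit$coefficients), drop(beta_direct),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("reported logL equals direct multivariate-normal evaluation", {
  tr <- rand_tree(20, seed = 31)
  sim <- simulate_traits(tr, matrix(c(1, .4, .4, 1), 2), seed = 4,
                         trait_names = c("x", "y"))
  y <- stats::setNames(sim$y, sim$tip)
  x <- stats::setNames(sim$x, sim$tip)
  cv <- phylo_covariance(tr)
  for (model in c("BM", "lambda", "OU", "EB")) {
    fit <- pgls(tr, y, x, model = model)
    theta <- switch(model, BM = NULL, lambda = fit$param[["lambda"]],
                    OU = fit$param[["alpha"]], EB = fit$param[["r"]])
    pl <- list(model = model, sigma2 = fit$sigma2)
    if (model == "lambda") pl$lambda <- theta
    if (model == "OU") pl$alpha <- theta
    if (model == "EB") pl$r <- theta
    V <- model_covariance(cv, pl)
    mu <- drop(cbind(1, x[rownames(V)]) %*% fit$coefficients)
    expect_equal(fit$logL, direct_mvn_loglik(y[rownames(V)], mu, V),
                 tolerance = 1e-6)
  }
})

test_that("AIC ranking is invariant to affine rescaling of the response", {
  tr <- rand_tree(40, seed = 77)
  sim <- simulate_traits(tr, matrix(c(1, .6, .6, 1), 2), seed = 6,
                         trait_names = c("x", "y"))
  y <- stats::setNames(sim$y, sim$tip)
  x <- stats::setNames(sim$x, sim$tip)
  models <- c("BM", "lambda", "OU", "EB")
  aic1 <- vapply(models, function(m) pgls(tr, y, x, model = m)$AIC,
                 numeric(1))
  aic2 <- vapply(models, function(m)
    pgls(tr, 3 + 10 * y, x, model = m)$AIC, numeric(1))
  expect_equal(order(aic1), order(aic2))
  ## slopes rescale accordingly
  f1 <- pgls(tr, y, x, model = "BM")
  f2 <- pgls(tr, 3 + 10 * y, x, model = "BM")
  expect_equal(unname(f2$coefficients[2]), 10 * unname(f1$coefficients[2]),
               tolerance = 1e-8)
})

test_that("multiple-predictor PGLS supports a binary covariate", {
  tr <- rand_tree(60, seed = 91)
  sim <- simulate_traits(tr, matrix(c(1, .5, .5, 1), 2), seed = 8,
                         trait_names = c("x", "y"))
  y <- stats::setNames(sim$y, sim$tip)
  dom <- stats::setNames(as.numeric(seq_along(sim$tip) %% 2), sim$tip)
  X <- cbind(x = stats::setNames(sim$x, sim$tip), domain = dom)
  fit <- pgls(tr, y, X, model = "lambda")
  expect_length(fit$coefficients, 3L)
  expect_named(fit$coefficients, c("(Intercept)", "x", "domain"))
  expect_true(all(fit$p > 0 & fit$p <= 1))
  expect_error(pgls(tr, y, cbind(x = X[, 1], x2 = 2 * X[, 1]),
                    model = "BM"), "singular design")
})

test_that("PGLS agrees with nlme::gls under corPagel on the same data", {
  ## ultrametric tree so nlme's correlation parameterization matches the
  ## covariance one; white noise added to pull lambda into the interior
  tr <- gen_tree(50, seed = 101)
  sim <- simulate_traits(tr, matrix(c(1, .6, .6, 1.2), 2), seed = 10,
                         trait_names = c("x", "y"))
  set.seed(11)
  sim$y <- sim$y + stats::rnorm(50, 0, 0.5)
  dat <- data.frame(sim, row.names = sim$tip)
  fit <- pgls(tr, stats::setNames(sim$y, sim$tip),
              stats::setNames(sim$x, sim$tip), model = "lambda")
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corPagel(0.8, tr, form = ~tip),
                   method = "ML")
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 0.02)
  expect_equal(unname(fit$param[["lambda"]]),
               unname(ref$modelStruct$corStruct[1]), tolerance = 0.05)
})

test_that("lambda signal recovers structure and matches phytools", {
  tr <- gen_tree(64, seed = 40)
  ## white noise pulls the optimum into the interior of [0, 1] (phytools
  ## allows lambda slightly above 1, where the cap would differ)
  set.seed(13)
  x <- stats::setNames(
    simulate_traits(tr, diag(2), seed = 12)$trait1 + rnorm(64, 0, 0.4),
    tr$tip.label)
  sig <- pagel_lambda_signal(tr, x)
  ps <- phytools::phylosig(tr, x, method = "lambda", test = TRUE)
  expect_equal(sig$lambda, ps$lambda, tolerance = 0.01)
  expect_equal(sig$logL, ps$logL, tolerance = 1e-4)
  ## grid search agrees with the continuous optimum
  grid <- seq(0, 1, by = 0.005)
  cv <- phylo_covariance(tr)
  ll <- vapply(grid, function(l) gctherm:::gls_profile(
    x[cv$tips], matrix(1, length(x)), model_covariance(cv,
      list(model = "lambda", sigma2 = 1, lambda = l)))$logL, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - sig$lambda), 0.01)
  expect_error(pagel_lambda_signal(tr, x * 0 + 5), "constant")
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  xs <- stats::setNames(rnorm(5), star$tip.label)
  expect_warning(s0 <- pagel_lambda_signal(star, xs), "star tree")
  expect_equal(s0$lambda, 0)
})

test_that("phylogenetic paired t-test is calibrated and powered", {
  tr <- gen_tree(60, seed = 50)
  x2 <- stats::setNames(rep(1, 60), tr$tip.label)
  res <- phylo_paired_ttest(tr, x2, x2)
  expect_equal(res$t, 0)
  expect_equal(res$p.value, 1)
  ## planted offset much larger than Brownian noise: always detected
  hits <- vapply(1:20, function(s) {
    d <- simulate_traits(tr, diag(c(0.25, 1)), seed = 300 + s)$trait1
    x1 <- stats::setNames(d + 10, tr$tip.label)
    x0 <- stats::setNames(rep(0, 60), tr$tip.label)
    phylo_paired_ttest(tr, x1, x0)$p.value
  }, numeric(1))
  expect_true(all(hits < 1e-3))
  ## null calibration: ~5% rejections
  p0 <- vapply(1:200, function(s) {
    d <- simulate_traits(tr, diag(c(1, 1)), seed = 4000 + s)$trait1
    x1 <- stats::setNames(d, tr$tip.label)
    x0 <- stats::setNames(rep(0, 60), tr$tip.label)
    phylo_paired_ttest(tr, x1, x0)$p.value
  }, numeric(1))
  expect_gt(mean(p0 < 0.05), 0.01)
  expect_lt(mean(p0 < 0.05), 0.10)
})

test_that("BH adjustment reproduces the published adjusted families", {
  ## the two worked family examples
  bact_tmax <- c(7.1e-4, 0.002, 0.003, 1.7e-4, 2.2e-16, 1.2e-6, 2.2e-16,
                 2.2e-16)
  expect_equal(bh_adjust(bact_tmax)[1], 9.4e-4, tolerance = 0.01)
  arch_tmax <- c(0.115, 0.183, 0.321, 0.025, 1.8e-11, 1.9e-5, 3.9e-11,
                 2.2e-16)
  expect_equal(bh_adjust(arch_tmax)[1], 0.153, tolerance = 0.01)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "must lie")
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie")
  ## sorted monotonicity and the step-up definition on a worked family
  p <- c(0.001, 0.04, 0.2, 0.03, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  m <- length(p)
  ps <- sort(p)
  manual <- rev(cummin(rev(ps * m / seq_len(m))))
  expect_equal(sort(adj), pmin(manual, 1))

  ## every printed adjusted cell follows from its (domain x temperature)
  ## family of eight GC indexes; printed inputs/outputs carry only 1-2
  ## significant figures, which bounds the achievable agreement
  tab <- published_pgls_table()
  tab$recomputed <- bh_adjust_grouped(tab$p, paste(tab$domain, tab$temp))
  expect_true(all(abs(tab$recomputed - tab$p_bh) / tab$p_bh < 0.25))
  two_sf <- abs(tab$recomputed - tab$p_bh) / tab$p_bh < 0.05
  expect_gt(mean(two_sf), 0.8)
})
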