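# Levy-jump simulation, Monte-Carlo likelihood, posteriors, calibration,
# and the jump-change Spearman correlation.

test_that("Levy simulation obeys its moment laws", {
  ## lambda_J = 0: pure Brownian tip covariance
  tr <- rand_tree(5, seed = 2)
  X <- vapply(1:8000, function(s)
    simulate_levy(tr, 1, 0, 0, mu0 = 0, seed = s)$tips, numeric(5))
  C <- phylo_covariance(tr)$C
  expect_lt(norm(stats::cov(t(X)) - C, "F") / norm(C, "F"), 0.06)

  ## single branch: var = s2 t + lambda t sJ2 (law of total variance)
  t2 <- read_newick("(A:2,B:2);")
  v <- vapply(1:10000, function(s)
    simulate_levy(t2, 0.5, 1.5, 4, seed = 10000 + s)$tips[["A"]],
    numeric(1))
  expect_equal(stats::var(v), 0.5 * 2 + 1.5 * 2 * 4,
               tolerance = 0.05 * 13)

  ## total jump count matches the Poisson mean over the whole tree
  tr2 <- rand_tree(10, seed = 3)
  TL <- sum(tr2$edge.length)
  nj <- vapply(1:10000, function(s)
    sum(simulate_levy(tr2, 1, 0.8, 1, seed = 20000 + s)$truth$n_jumps),
    numeric(1))
  expect_equal(mean(nj), 0.8 * TL, tolerance = 0.03 * 0.8 * TL)

  ## determinism
  expect_identical(simulate_levy(tr2, 1, 1, 2, seed = 5),
                   simulate_levy(tr2, 1, 1, 2, seed = 5))
})

test_that("Monte-Carlo likelihood hits its exact anchors", {
  tr <- rand_tree(6, seed = 7)
  y <- simulate_levy(tr, 1, 0.5, 4, seed = 1)$tips
  C <- phylo_covariance(tr)$C[names(y), names(y)]
  ## no-jump parameters collapse to the closed-form Brownian density
  for (p0 in list(list(sigma2 = 1.3, lambda_j = 0, sigmaj2 = 5, mu0 = .2),
                  list(sigma2 = 1.3, lambda_j = 2, sigmaj2 = 0, mu0 = .2))) {
    ml <- mc_loglik(tr, y, p0, M = 200, seed = 3)
    expect_equal(ml$logL, direct_mvn_loglik(y, p0$mu0, p0$sigma2 * C),
                 tolerance = 1e-10)
    expect_equal(ml$se, 0)
  }

  ## 3-tip tree: truncated exact enumeration within 3 MC standard errors
  t3 <- read_newick("(A:1,(B:0.5,C:0.5):0.5);")
  y3 <- stats::setNames(c(0.3, 2.1, 1.7), c("A", "B", "C"))
  params <- list(sigma2 = 1, lambda_j = 0.3, sigmaj2 = 4, mu0 = 0.5)
  exact <- enum_jump_loglik(t3, y3, params, kmax = 2)
  ml <- mc_loglik(t3, y3, params, M = 4000, seed = 9)
  expect_lt(abs(ml$logL - exact), 3 * ml$se + 0.02)

  ## MC standard error shrinks like 1/sqrt(M)
  se_by_M <- vapply(c(100, 1000, 10000), function(M)
    mc_loglik(t3, y3, params, M = M, seed = 11)$se, numeric(1))
  expect_gt(se_by_M[1] / se_by_M[3], 5)
  expect_lt(se_by_M[1] / se_by_M[3], 30)
})

test_that("branch posteriors localize planted jumps and are reproducible", {
  tr <- gen_tree(40, seed = 33)
  Z <- gctherm:::branch_indicators(tr)
  sizes <- colSums(Z)
  b <- which(tr$edge[, 2] > 40 & sizes >= 5 & sizes <= 12)[1]
  base <- simulate_levy(tr, 1, 0, 0, mu0 = 0, seed = 101)$tips
  y <- base + 8 * Z[, b]
  params <- list(sigma2 = 1, lambda_j = 0.3, sigmaj2 = 64, mu0 = 0)
  pp <- suppressWarnings(branch_jump_posteriors(tr, y, params, M = 800,
                                                seed = 5))
  expect_equal(pp$branch[which.max(pp$pp)], tr$edge[b, 2])
  expect_gt(max(pp$pp), 0.8)
  expect_true(all(pp$pp >= 0 & pp$pp <= 1))
  ## bitwise reproducibility under a fixed seed
  pp2 <- suppressWarnings(branch_jump_posteriors(tr, y, params, M = 800,
                                                 seed = 5))
  expect_identical(pp$pp, pp2$pp)

  ## pp vector sums to the posterior expected number of jumped branches
  prep <- gctherm:::jump_prep(tr)
  ml <- mc_loglik(prep, y[rownames(prep$C)], params, M = 800, seed = 5)
  w <- exp(ml$ld - max(ml$ld)); w <- w / sum(w)
  expect_equal(sum(pp$pp), sum(w * rowSums(ml$K > 0)), tolerance = 1e-9)

  ## with no jump signal the posterior stays near the Poisson prior
  pp0 <- suppressWarnings(branch_jump_posteriors(
    tr, base, list(sigma2 = 1, lambda_j = 0.2, sigmaj2 = 1e-8, mu0 = 0),
    M = 500, seed = 6))
  prior <- 1 - exp(-0.2 * pp0$length)
  expect_lt(abs(mean(pp0$pp) - mean(prior)) / mean(prior), 0.5)
})

test_that("threshold calibration produces a proper precision-recall curve", {
  tr <- gen_tree(30, seed = 44)
  params <- list(sigma2 = 1, lambda_j = 0.5, sigmaj2 = 25, mu0 = 0)
  ct <- calibrate_threshold(tr, params, n_sims = 6,
                            pp_grid = c(0, 0.25, 0.5, 0.75, 0.9, 1 + 1e-9),
                            seed = 3, M = 300)
  cv <- ct$curve
  expect_equal(cv$recall[1], 1)                  # threshold 0 calls all
  last <- nrow(cv)
  expect_equal(cv$TP[last] + cv$FP[last], 0)     # threshold > 1 calls none
  expect_true(is.na(cv$precision[last]))
  ## cleaned precision is nonincreasing in recall (ties in recall ordered
  ## by descending threshold)
  ord <- order(cv$recall, -cv$threshold)
  expect_true(all(diff(cv$precision_clean[ord]) <= 1e-12))
  ## no-jump parameters make recall undefined
  expect_error(
    calibrate_threshold(tr, list(sigma2 = 1, lambda_j = 1e-9,
                                 sigmaj2 = 1, mu0 = 0),
                        n_sims = 2, seed = 1, M = 200),
    "recall undefined")
})

test_that("jump-change correlations use ancestral contrasts and exact P", {
  ## strictly monotone changes give rho = 1 at the smallest exact P
  tr <- gen_tree(24, seed = 55)
  sim <- simulate_traits(tr, matrix(c(1, .9, .9, 1), 2), seed = 3,
                         trait_names = c("x", "y"))
  x <- stats::setNames(sim$x, sim$tip); yv <- stats::setNames(sim$y, sim$tip)
  branches <- tr$edge[c(2, 5, 9, 13, 17, 21), 2]
  jc <- jump_change_correlation(tr, x, yv, branches)
  expect_equal(jc$n, 6L)
  expect_true(abs(jc$rho) <= 1)
  ## a perfectly monotone pair of change vectors
  sp1 <- spearman_perm(1:7, c(2, 4, 6, 8, 10, 12, 14))
  expect_equal(sp1$rho, 1)
  expect_equal(sp1$p.value, 2 / factorial(7))

  ## exact permutation distribution matches cor.test's exact P (tie-free)
  set.seed(21)
  for (rep in 1:5) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    expect_equal(spearman_perm(a, b)$p.value,
                 stats::cor.test(a, b, method = "spearman",
                                 exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  ## the t-approximation reproduces the published significance pairs
  r1 <- 0.209; n1 <- 108
  t1 <- r1 * sqrt((n1 - 2) / (1 - r1^2))
  expect_equal(2 * stats::pt(-t1, n1 - 2), 0.030, tolerance = 0.01)
  r2 <- 0.280; n2 <- 86
  t2 <- r2 * sqrt((n2 - 2) / (1 - r2^2))
  expect_equal(2 * stats::pt(-t2, n2 - 2), 0.009, tolerance = 0.01)

  expect_error(jump_change_correlation(tr, x, yv, branches[1:3]),
               "at least 5")
})
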