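# Sister-pair rank contrasts and the subsampling sensitivity analysis.

#' Extract phylogenetically independent rank pairs
#'
#' Walks the tree in postorder (smallest clades first) and, at each internal
#' node whose descendant tips are all still unused and carry exactly two
#' distinct temperature ranks, forms one contrast: the tips of each rank are
#' pooled (trait values averaged, representing their shared internal node)
#' and all tips of the clade are marked used, so the returned pairs occupy
#' pairwise-disjoint clades and are phylogenetically independent.  Clades
#' exposing three or more ranks never pair at that node but may contribute
#' pairs within sub-clades.
#'
#' @param tree Rooted tree with branch lengths.
#' @param ranks Named integer vector (codes 1-4) per tip.
#' @param values Named numeric vector (e.g. a GC index) per tip.
#' @return A data.frame with one row per pair: pooled member labels, ranks,
#'   pooled values, and \code{diff} = value(high rank) - value(low rank).
#' @export
extract_rank_pairs <- function(tree, ranks, values) {
  validate_tree(tree)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(ranks)), all(tips %in% names(values)))
  if (!all(ranks[tips] %in% 1:4)) stop("ranks must be codes 1-4")
  n <- length(tips)
  edge <- stats::na.omit(reorder(tree, "postorder")$edge)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  used <- rep(FALSE, n)
  out <- list()
  post_parents <- unique(edge[, 1])            # children-first order
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (v in post_parents) {
    dt <- desc[[v]]
    if (any(used[dt])) next
    rk <- ranks[tips[dt]]
    ur <- sort(unique(rk))
    if (length(ur) != 2L) next
    lo <- dt[rk == ur[1]]; hi <- dt[rk == ur[2]]
    out[[length(out) + 1L]] <- data.frame(
      high_members = paste(tips[hi], collapse = ","),
      low_members  = paste(tips[lo], collapse = ","),
      high_rank = ur[2], low_rank = ur[1],
      high_value = mean(values[tips[hi]]),
      low_value  = mean(values[tips[lo]]),
      stringsAsFactors = FALSE)
    used[dt] <- TRUE
  }
  if (!length(out))
    return(data.frame(high_members = character(), low_members = character(),
                      high_rank = integer(), low_rank = integer(),
                      high_value = numeric(), low_value = numeric(),
                      diff = numeric()))
  res <- do.call(rbind, out)
  res$diff <- res$high_value - res$low_value
  res
}

#' Wilcoxon signed-rank test with exact tail enumeration
#'
#' Two-sided signed-rank test of paired differences.  Zero differences are
#' dropped and tied absolute values receive averaged ranks.  For \eqn{n \le}
#' \code{exact_max} the null distribution of the positive-rank sum is
#' computed exactly over all \eqn{2^n} sign assignments (a shifted-polynomial
#' convolution, so ties are handled exactly); above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param d Numeric vector of differences.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with \code{W} (positive-rank sum), \code{p.value},
#'   \code{n} (nonzero differences) and \code{method}.
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 20L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ir <- as.integer(round(2 * r))             # half-ranks doubled to ints
    tot <- sum(ir)
    f <- c(1, numeric(tot))                    # f[s+1] = P(2W = s), unnormed
    for (k in ir) f <- (f + c(numeric(k), f[seq_len(tot + 1L - k)])) / 2
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(s2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = W, p.value = p, n = n, method = method)
}

#' Subsampling sensitivity analysis of PGLS correlations
#'
#' Repeatedly draws \code{m} tips without replacement, reruns the PGLS
#' regression for every requested (response, predictor) trait pair on the
#' induced subtree covariance, and tallies how often the slope is
#' significantly negative, nonsignificant, or significantly positive at
#' level \code{alpha}.  Rounds use counter-based seeds keyed on
#' \code{(seed, round)}, so any single round is individually reproducible
#' and independent of how many rounds run.
#'
#' @param tree Rooted tree with branch lengths.
#' @param traits Data.frame with a \code{tip} column and named trait
#'   columns.
#' @param trait_pairs List of length-2 character vectors
#'   \code{c(response, predictor)}.
#' @param m Subsample size per round.
#' @param rounds Number of resampling rounds.
#' @param alpha Significance level for the tally.
#' @param model Trait-evolution model passed to the PGLS fitter.
#' @param seed Master seed.
#' @return A \code{"resample_tally"}: per-pair counts
#'   (\code{neg_sig}, \code{nonsig}, \code{pos_sig}) summing to
#'   \code{rounds}.
#' @export
resample_pgls <- function(tree, traits, trait_pairs, m = 155L,
                          rounds = 1000L, alpha = 0.05, model = "BM",
                          seed = 1L) {
  validate_tree(tree)
  stopifnot(is.data.frame(traits), "tip" %in% names(traits))
  tips <- intersect(tree$tip.label, traits$tip)
  n <- length(tips)
  if (m > n) stop("m exceeds the number of usable tips")
  if (m < 10L) stop("m too small for PGLS")
  rownames(traits) <- traits$tip
  Cfull <- phylo_covariance(tree, tips)$C
  pair_names <- vapply(trait_pairs, paste, character(1), collapse = "-")
  tally <- matrix(0L, length(trait_pairs), 3L,
                  dimnames = list(pair_names,
                                  c("neg_sig", "nonsig", "pos_sig")))
  for (i in seq_len(rounds)) {
    sub <- with_seed(derive_seed(seed, i), sample(tips, m))
    cov <- structure(list(C = Cfull[sub, sub], tips = sub),
                     class = "phylo_cov")
    for (j in seq_along(trait_pairs)) {
      yv <- traits[sub, trait_pairs[[j]][1]]
      xv <- traits[sub, trait_pairs[[j]][2]]
      ok <- !is.na(yv) & !is.na(xv)
      X <- cbind("(Intercept)" = 1, x = xv[ok])
      covj <- structure(list(C = Cfull[sub[ok], sub[ok]], tips = sub[ok]),
                        class = "phylo_cov")
      fit <- pgls_fit_cov(covj, yv[ok], X, model)
      cls <- if (fit$p[2] >= alpha) 2L else if (fit$coefficients[2] < 0) 1L
             else 3L
      tally[j, cls] <- tally[j, cls] + 1L
    }
  }
  structure(list(tally = as.data.frame(tally), rounds = rounds, m = m,
                 alpha = alpha, model = model, seed = seed),
            class = "resample_tally")
}

#' @export
print.resample_tally <- function(x, ...) {
  cat("PGLS resampling tally: m =", x$m, ", rounds =", x$rounds,
      ", alpha =", x$alpha, ", model =", x$model, "\n")
  print(x$tally)
  invisible(x)
}
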