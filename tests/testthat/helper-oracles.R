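# Independent oracles used across the suite.  Each one deliberately avoids
# the package's own code path for the quantity it checks.

## Shared root-to-MRCA path length by explicit ancestry enumeration.
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent_of <- integer(n + tree$Nnode)
  len_of <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    len_of[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1L
  ancestry <- function(v) {          # nodes from v up to root
    out <- v
    while (v != root) { v <- parent_of[v]; out <- c(out, v) }
    out
  }
  depth <- function(v) {             # root-to-node distance
    s <- 0
    while (v != root) { s <- s + len_of[v]; v <- parent_of[v] }
    s
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n) {
    common <- intersect(ancestry(i), ancestry(j))
    mrca <- common[which.max(vapply(common, depth, numeric(1)))]
    C[i, j] <- C[j, i] <- depth(mrca)
  }
  C
}

## Exact two-sided signed-rank P by enumerating all 2^n sign assignments.
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- signs %*% r
  p_le <- mean(W_all <= W_obs + 1e-12)
  p_ge <- mean(W_all >= W_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

## Fourfold-degeneracy of a codon decided by translating all four
## third-position variants (bacterial genetic code).
translation_fourfold <- function(codon) {
  gc11 <- Biostrings::getGeneticCode("11")
  aa <- vapply(c("A", "C", "G", "T"), function(b)
    unname(gc11[paste0(substr(codon, 1, 2), b)]), character(1))
  length(unique(aa)) == 1L && !any(aa == "*")
}

## GC_4 oracle over a vector of CDS, via translation_fourfold.
oracle_fourfold_gc <- function(cds_vec) {
  thirds <- character(0)
  for (cds in cds_vec) {
    L <- nchar(cds)
    starts <- seq(1L, L - 3L, by = 3L)
    codons <- substring(cds, starts, starts + 2L)
    keep <- vapply(codons, translation_fourfold, logical(1))
    thirds <- c(thirds, substring(codons[keep], 3L, 3L))
  }
  gcn <- sum(thirds %in% c("G", "C"))
  100 * gcn / length(thirds)
}

## Raw 16-dinucleotide counter by direct substring inspection.
oracle_dinuc_counts <- function(s) {
  s <- toupper(s)
  out <- stats::setNames(integer(16),
    as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  for (i in seq_len(nchar(s) - 1L)) {
    d <- substr(s, i, i + 1L)
    if (d %in% names(out)) out[d] <- out[d] + 1L
  }
  out
}

## Exact Levy-jump marginal likelihood on a tiny tree by truncated
## enumeration of per-branch jump counts (k_b in 0..kmax).
enum_jump_loglik <- function(tree, y, params, kmax = 2L) {
  C <- ape::vcv.phylo(tree)[names(y), names(y)]
  Z <- gctherm:::branch_indicators(tree)[names(y), , drop = FALSE]
  lens <- tree$edge.length
  B <- length(lens)
  grids <- rep(list(0:kmax), B)
  combos <- as.matrix(expand.grid(grids))
  ll <- apply(combos, 1, function(k) {
    V <- params$sigma2 * C
    for (b in which(k > 0))
      V <- V + params$sigmaj2 * k[b] * tcrossprod(Z[, b])
    lpois <- sum(stats::dpois(k, params$lambda_j * lens, log = TRUE))
    mvn <- -0.5 * (length(y) * log(2 * pi) +
                   as.numeric(determinant(V)$modulus) +
                   drop(t(y - params$mu0) %*% solve(V) %*% (y - params$mu0)))
    lpois + mvn
  })
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}

## Direct multivariate-normal log-density (solve/determinant path, no
## Cholesky reuse from the package).
direct_mvn_loglik <- function(y, mu, V) {
  -0.5 * (length(y) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
          drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}

rand_tree <- function(n, seed, polytomy = FALSE) {
  set.seed(seed)
  tr <- ape::rtree(n)
  if (polytomy) tr <- ape::di2multi(tr, tol = 0.3)
  tr
}
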