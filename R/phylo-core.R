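#' Read a Newick tree
#'
#' Parses a rooted Newick string (or a file containing one) into an
#' \code{ape} \code{"phylo"} object, enforcing the invariants every
#' downstream comparative analysis relies on: unique tip labels, branch
#' lengths on all non-root edges, and all branch lengths non-negative.
#'
#' @param text A Newick string, or the path of a file holding one.
#' @return A \code{"phylo"} tree.
#' @seealso [write_newick()], [phylo_covariance()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- if (file.exists(text) && !grepl(";", text, fixed = TRUE)) {
    tryCatch(ape::read.tree(text), error = function(e) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick input: ", substr(text, 1, 60))
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param tree A \code{"phylo"} tree.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop("duplicate tip label: '", dup, "'")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("missing branch length in tree (all non-root edges need one)")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  invisible(tree)
}

#' Phylogenetic variance-covariance structure
#'
#' Builds the matrix of shared root-to-tip path lengths \eqn{C}: the diagonal
#' holds total root-to-tip distances and \eqn{C_{ij}} the root-to-MRCA path
#' length of tips \eqn{i,j}.  This is the coordinate system for all PGLS and
#' trait-model covariance math.
#'
#' @param tree A rooted \code{"phylo"} tree with branch lengths.
#' @param tips Optional character vector: a subset of tip labels.  Shared
#'   path lengths are unaffected by subsetting, so the result equals the
#'   corresponding submatrix of the full-tree \eqn{C}.
#' @return An object of class \code{"phylo_cov"}: a list with \code{C}
#'   (symmetric PSD matrix) and \code{tips} (row/column order).
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  if (!is.null(tips)) {
    unknown <- setdiff(tips, rownames(C))
    if (length(unknown))
      stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
    C <- C[tips, tips, drop = FALSE]
  }
  structure(list(C = C, tips = rownames(C)), class = "phylo_cov")
}

#' Trait-evolution model covariance
#'
#' Transforms a phylogenetic covariance structure into the tip covariance
#' matrix implied by one of four trait-evolution models:
#' \describe{
#'   \item{BM}{\eqn{V = \sigma^2 C} (Brownian motion).}
#'   \item{lambda}{Pagel's lambda: off-diagonal entries multiplied by
#'     \eqn{\lambda \in [0,1]}, diagonal untouched.}
#'   \item{OU}{Ornstein-Uhlenbeck with the ancestral state estimated at the
#'     root ("fixed root"): \eqn{V_{ij} = \sigma^2/(2\alpha)\,
#'     (1 - e^{-2\alpha t_{ij}})\, e^{-\alpha (T_i + T_j - 2 t_{ij})}} with
#'     \eqn{t_{ij} = C_{ij}} and \eqn{T_i = C_{ii}}.}
#'   \item{EB}{Early burst: \eqn{V_{ij} = \sigma^2 (e^{r t_{ij}} - 1)/r},
#'     with the Brownian limit \eqn{\sigma^2 t_{ij}} as \eqn{r \to 0}.}
#' }
#'
#' @param cov A \code{"phylo_cov"} object from [phylo_covariance()].
#' @param params A list with \code{model} (one of \code{"BM"},
#'   \code{"lambda"}, \code{"OU"}, \code{"EB"}), \code{sigma2}, and the model
#'   parameter where applicable (\code{lambda}, \code{alpha} or \code{r}).
#' @return A symmetric positive-definite matrix (tip order as in \code{cov}).
#' @export
model_covariance <- function(cov, params) {
  stopifnot(inherits(cov, "phylo_cov"))
  C <- cov$C
  model <- match.arg(params$model, c("BM", "lambda", "OU", "EB"))
  s2 <- params$sigma2 %||% 1
  stopifnot(s2 >= 0)
  V <- switch(model,
    BM = s2 * C,
    lambda = {
      lam <- params$lambda
      stopifnot(!is.null(lam), lam >= 0, lam <= 1)
      Vl <- s2 * lam * C
      diag(Vl) <- s2 * diag(C)
      Vl
    },
    OU = {
      a <- params$alpha
      stopifnot(!is.null(a), a > 0)
      Ti <- diag(C)
      D <- outer(Ti, Ti, "+") - 2 * C          # patristic distances
      s2 / (2 * a) * (1 - exp(-2 * a * C)) * exp(-a * D)
    },
    EB = {
      r <- params$r
      stopifnot(!is.null(r))
      if (abs(r) < 1e-8) s2 * C * (1 + r * C / 2) else s2 * expm1(r * C) / r
    })
  dimnames(V) <- dimnames(C)
  V
}

#' Simulate correlated traits under bivariate Brownian motion
#'
#' Draws tip values for two traits co-evolving by Brownian motion with
#' evolutionary rate matrix \code{Sigma} (per unit branch length), i.e. the
#' tip vector is exactly multivariate normal with covariance
#' \eqn{\Sigma \otimes C}.
#'
#' @param tree A rooted tree with branch lengths.
#' @param Sigma 2x2 symmetric PSD evolutionary covariance.
#' @param roots Length-2 root states.
#' @param seed Integer seed; the draw is a pure function of it.
#' @param trait_names Column names of the output.
#' @return A data.frame with columns \code{tip} and the two traits.
#' @export
simulate_traits <- function(tree, Sigma, roots = c(0, 0), seed = 1L,
                            trait_names = c("trait1", "trait2")) {
  stopifnot(is.matrix(Sigma), all(dim(Sigma) == 2L),
            isTRUE(all.equal(Sigma, t(Sigma))))
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("Sigma is not positive semidefinite")
  Ls <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  C <- phylo_covariance(tree)$C
  Uc <- chol_pd(C, "phylogenetic covariance")
  n <- nrow(C)
  Z <- with_seed(seed, matrix(stats::rnorm(2L * n), n, 2L))
  X <- t(Uc) %*% Z %*% Ls
  X <- sweep(X, 2L, roots, "+")
  out <- data.frame(tip = rownames(C), X[, 1L], X[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("tip", trait_names)
  out
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Generalized-least-squares (maximum-likelihood) estimates of internal-node
#' states under Brownian motion.  The root estimate equals the GLS mean of
#' the tip values; any other node \eqn{v} is the conditional expectation
#' \eqn{\hat a_v = \hat\mu + c_v^\top C^{-1} (x - \hat\mu)} where
#' \eqn{c_{v,i}} is the shared root-path length of node \eqn{v} and tip
#' \eqn{i}.
#'
#' @param tree A rooted tree with branch lengths.
#' @param x Named numeric vector of tip values covering every tip.
#' @return Numeric vector of estimates for internal nodes, named by ape node
#'   number (\code{n+1 ... n+Nnode}).
#' @export
ancestral_states <- function(tree, x) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(x)))
    stop("x must provide a value for every tip")
  x <- x[tree$tip.label]
  depth <- ape::node.depth.edgelength(tree)
  if (max(depth) <= 0) stop("degenerate tree: zero total depth")
  C <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  U <- chol_pd(C, "phylogenetic covariance")
  Cinv_x <- backsolve(U, forwardsolve(t(U), x))
  Cinv_1 <- backsolve(U, forwardsolve(t(U), rep(1, n)))
  mu <- sum(Cinv_x) / sum(Cinv_1)
  w <- backsolve(U, forwardsolve(t(U), x - mu))   # C^{-1}(x - mu)
  ## shared depth of internal node v and tip i: depth of their MRCA
  M <- ape::mrca(tree, full = TRUE)
  nodes <- (n + 1L):(n + tree$Nnode)
  est <- vapply(nodes, function(v) {
    cv <- depth[M[v, seq_len(n)]]
    mu + sum(cv * w)
  }, numeric(1))
  names(est) <- as.character(nodes)
  est
}
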