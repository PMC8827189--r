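# Published regression P-value families shipped with the package, and the
# grouped BH convenience wrapper used to reproduce their adjusted columns.

#' Published PGLS P-value table
#'
#' The printed Brownian-motion PGLS results (slope, P, adjusted P) for the
#' eight GC indexes against three growth-temperature indexes in the
#' 681-bacteria / 155-archaea dataset, as shipped in
#' \code{inst/extdata/pgls_printed_pvalues.tsv}.  The adjusted column is
#' reproducible from the P column with BH families of the eight GC indexes
#' within each (domain, temperature index) pair; printed values carry
#' 1-2 significant figures (including the 2.2e-16 floor convention), which
#' bounds how closely the recomputation can match.
#'
#' @return Data.frame: domain, temp, gc_index, slope, p, p_bh.
#' @export
published_pgls_table <- function() {
  path <- system.file("extdata", "pgls_printed_pvalues.tsv",
                      package = "gctherm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Grouped Benjamini-Hochberg adjustment
#'
#' Applies [bh_adjust()] independently within each level of \code{group},
#' preserving input order.  The family grouping that reproduces the
#' published adjusted columns is (domain x temperature index), i.e. m = 8
#' GC indexes per family.
#'
#' @param p P values in (0, 1].
#' @param group Family labels, one per P value.
#' @return Adjusted values in input order.
#' @export
bh_adjust_grouped <- function(p, group) {
  stopifnot(length(p) == length(group))
  out <- numeric(length(p))
  for (g in unique(group)) {
    i <- group == g
    out[i] <- bh_adjust(p[i])
  }
  out
}
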