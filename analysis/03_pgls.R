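#!/usr/bin/env Rscript
# PGLS of GC on Topt under the four trait-evolution models, with and
# without the planted outlier clade, plus BH adjustment of the published
# P-value families (domain x temperature index, m = 8 GC indexes).

suppressMessages(library(gctherm))
tr <- read_newick("results/synthetic/tree.nwk")
traits <- read.delim("results/synthetic/traits.tsv")
truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
y <- setNames(traits$GC, traits$tip)
x <- setNames(traits$Topt, traits$tip)

fit_row <- function(tree, yy, xx, model, label) {
  f <- pgls(tree, yy, xx, model = model)
  data.frame(dataset = label, model = model, n = f$n,
             slope = f$coefficients[2], se = f$se[2], t = f$t[2],
             p = f$p[2],
             param = if (is.null(f$param)) NA else unname(f$param),
             logL = f$logL, AIC = f$AIC)
}
models <- c("BM", "lambda", "OU", "EB")
full <- do.call(rbind, lapply(models, function(m)
  fit_row(tr, y, x, m, "full")))
keep <- setdiff(tr$tip.label, truth$outlier_tips)
sub <- ape::keep.tip(tr, keep)
part <- do.call(rbind, lapply(models, function(m)
  fit_row(sub, y[keep], x[keep], m, "outlier_excluded")))
tab <- rbind(full, part)
tab$p_bh <- bh_adjust_grouped(tab$p, tab$dataset)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(format(tab, digits = 4), "results/tables/pgls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab[, c("dataset", "model", "slope", "p", "p_bh", "AIC")],
      digits = 3)
cat("\nExcluding the planted high-GC low-Topt clade raises the slope",
    sprintf("(BM: %.4f -> %.4f), the halophile-exclusion pattern.\n",
            full$slope[1], part$slope[1]))

pub <- published_pgls_table()
pub$p_bh_recomputed <- bh_adjust_grouped(pub$p, paste(pub$domain, pub$temp))
write.table(format(pub, digits = 3), "results/tables/published_bh.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Recomputed BH columns for the published table written to",
    "results/tables/published_bh.tsv;",
    sprintf("max relative deviation from print: %.1f%%.\n",
            100 * max(abs(pub$p_bh_recomputed - pub$p_bh) / pub$p_bh)))
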