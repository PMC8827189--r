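#!/usr/bin/env Rscript
# Phylogenetic signal of the simulated traits: both Topt and GC evolve by
# Brownian motion on the tree, so Pagel's lambda should sit near 1 with
# tiny likelihood-ratio P values (the pattern the real growth-temperature
# and GC data show).

suppressMessages(library(gctherm))
tr <- read_newick("results/synthetic/tree.nwk")
traits <- read.delim("results/synthetic/traits.tsv")

rows <- lapply(c("Topt", "GC"), function(v) {
  x <- setNames(traits[[v]], traits$tip)
  s <- pagel_lambda_signal(tr, x)
  data.frame(trait = v, n = s$n, lambda = s$lambda, logL = s$logL,
             logL0 = s$logL0, p = s$p.value)
})
tab <- do.call(rbind, rows)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(format(tab, digits = 4), "results/tables/signal.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 4)
cat("Both traits carry strong phylogenetic signal (lambda ~ 1), so",
    "non-phylogenetic regression would be miscalibrated here.\n")
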