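#!/usr/bin/env Rscript
# Build the synthetic study inputs with known truth: an ultrametric
# 300-tip tree, co-evolving (Topt, GC) traits with discrete GC jumps and a
# planted high-GC low-Topt outlier clade, three toy annotated genomes, and
# a gene presence/absence matrix.  Everything downstream reads from
# results/synthetic/.

suppressMessages(library(gctherm))
seed <- 20260901L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tr <- gen_tree(300, seed = seed)
writeLines(write_newick(tr), file.path(out, "tree.nwk"))

## a handful of large GC jumps (sd 20 GC points, ~2 evolutionary SD at
## unit depth) -- the regime where discrete shifts are distinguishable
## from Brownian drift
gt <- gen_traits(tr,
                 jumps = list(trait = "GC", lambda_j = 0.1, sigmaj2 = 400),
                 outlier = list(size = 25, offset = 15), seed = seed)
write.table(gt$traits, file.path(out, "traits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- list(
  Sigma = gt$truth$Sigma, roots = gt$truth$roots,
  outlier_tips = gt$truth$outlier_tips,
  jump_branches = gt$truth$jumps$branch[gt$truth$jumps$n_jumps > 0],
  seed = seed)
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

profiles <- do.call(rbind, lapply(1:3, function(i) {
  gg <- gen_genome(file.path(out, "genomes"),
                   genome_id = sprintf("synthG%02d", i),
                   n_cds = 120, gc4 = 45 + 10 * i, gcnon = 30 + 5 * i,
                   n_plasmids = i - 1, seed = seed + i)
  pr <- compute_profile(read_annotated_genome(gg$fasta, gg$gff))
  as.data.frame(pr)
}))
write.table(profiles, file.path(out, "composition_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gp <- gen_presence_matrix(150, n_core = 28, n_accessory = 400, n_mid = 60,
                          seed = seed)
write.table(gp$matrix, file.path(out, "presence_matrix.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)

cs <- core_accessory_sets(gp$matrix)
cat("Simulated:", length(tr$tip.label), "tips;",
    length(gt$truth$outlier_tips), "outlier-clade tips;",
    sum(gt$truth$jumps$n_jumps), "true GC jumps;",
    nrow(profiles), "genomes profiled;",
    length(cs$core), "core and", length(cs$accessory),
    "accessory families recovered from the presence matrix.\n")
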