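#!/usr/bin/env Rscript
# Levy-jump analysis of the GC trait.  Model comparison (Brownian vs
# Brownian + compound-Poisson jumps) runs on the full 300-tip dataset.
# Branch-level work -- posterior jump probabilities, precision-recall
# threshold calibration, and the correlation between GC changes and Topt
# changes on called branches -- runs on the largest clade of 60-150 tips:
# the likelihood is marginalized by importance sampling from the Poisson
# prior, whose effective sample size degrades on very large trees, so
# branch-level inference is only trustworthy at clade scale here.

suppressMessages(library(gctherm))
seed <- 20260906L
tr <- read_newick("results/synthetic/tree.nwk")
traits <- read.delim("results/synthetic/traits.tsv")
truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
gc <- setNames(traits$GC, traits$tip)
topt <- setNames(traits$Topt, traits$tip)
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

## ---- full-tree model comparison -----------------------------------------
fit_full <- fit_jump_model(tr, gc, M = 200, seed = seed)
cat(sprintf("Full tree AIC: jumps %.1f vs Brownian %.1f -> %s\n",
            fit_full$AIC, fit_full$bm$AIC,
            if (fit_full$AIC < fit_full$bm$AIC) "jump model preferred"
            else "Brownian preferred"))

## ---- branch-level inference on the largest mid-sized clade --------------
n <- length(tr$tip.label)
clade_sizes <- vapply((n + 1L):(n + tr$Nnode), function(v)
  length(gctherm:::tip_descendants(tr, v)), integer(1))
pick <- which(clade_sizes >= 50 & clade_sizes <= 100)
pick <- pick[which.max(clade_sizes[pick])]
kept <- tr$tip.label[gctherm:::tip_descendants(tr, n + pick)]
sub <- ape::keep.tip(tr, kept)
cat(sprintf("Branch-level analysis on a %d-tip clade.\n", length(kept)))

## map full-tree jump truth onto subtree branches via tip sets
true_sets <- lapply(truth$jump_branches, function(b)
  sort(intersect(tr$tip.label[gctherm:::tip_descendants(tr, b)], kept)))
true_sets <- true_sets[vapply(true_sets, length, 1L) > 0]
Zs <- gctherm:::branch_indicators(sub)
sub_sets <- lapply(seq_len(ncol(Zs)), function(b)
  sort(rownames(Zs)[Zs[, b] == 1]))
true_branch <- vapply(sub_sets, function(s)
  any(vapply(true_sets, identical, logical(1), s)), logical(1))
cat(sprintf("%d true jump branch(es) fall inside the clade.\n",
            sum(true_branch)))

fit <- fit_jump_model(sub, gc[kept], M = 200, seed = seed + 1L)
print(fit)
pp <- suppressWarnings(branch_jump_posteriors(sub, gc[kept], fit,
                                              M = 2000, seed = seed + 2L))
pp$true_jump <- true_branch
write.table(format(pp, digits = 4), "results/tables/jump_posteriors.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

expected_jumps <- fit$params$lambda_j * sum(sub$edge.length)
if (expected_jumps >= 0.5) {
  ct <- calibrate_threshold(sub, fit, n_sims = 8, seed = seed + 3L,
                            M = 400, target_precision = 0.85)
  write.table(format(ct$curve, digits = 4),
              "results/tables/jump_pr_curve.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  thr <- if (is.na(ct$threshold)) {
    cat("No threshold reaches 85% precision on this clade;",
        "using the best-precision threshold instead.\n")
    ct$curve$threshold[which.max(ct$curve$precision_clean)]
  } else ct$threshold
} else {
  cat("Fitted jump intensity is effectively zero;",
      "skipping precision-recall calibration and calling at pp >= 0.5.\n")
  thr <- 0.5
}
called <- pp$branch[pp$pp >= thr]
cat(sprintf("Threshold %.2f calls %d branch(es), %d truly jumped.\n",
            thr, length(called), sum(pp$true_jump[pp$pp >= thr])))

## ---- jump-change correlation -------------------------------------------
## fall back to the highest-pp branches when strict calls are fewer than
## the minimum the correlation needs
use <- if (length(called) >= 5) called else
  pp$branch[order(pp$pp, decreasing = TRUE)][1:8]
jc <- jump_change_correlation(sub, gc[kept], topt[kept], use)
res <- data.frame(n = jc$n, rho = jc$rho, p = jc$p.value, threshold = thr,
                  strict_calls = length(called))
write.table(format(res, digits = 4),
            "results/tables/jump_change_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "GC and Topt changes on the %d examined branches: Spearman rho = %.3f (two-sided P = %.3g).\n",
  jc$n, jc$rho, jc$p.value))
cat("Note: the generator plants GC jumps independently of Topt, so only",
    "the background evolutionary correlation (0.5) can surface here --",
    "unlike the real data, where jump-accompanying temperature shifts are",
    "the signal of interest.\n")
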