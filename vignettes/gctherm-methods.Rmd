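---
title: "Methods: phylogenetic comparative analysis of GC content and growth temperature"
author: "gctherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of GC content and growth temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the statistical problem

Whether prokaryotic genomic GC content rises with growth temperature has
been debated for decades.  Structural RNA genes (tRNA, 5S/16S/23S rRNA)
clearly gain GC with temperature — paired stems must stay folded — but for
genomic DNA the signal is weak and earlier studies disagreed.  Two
statistical facts drive the disagreement: (i) both GC content and growth
temperature carry very strong phylogenetic signal, so species are far from
independent observations, and (ii) the effective sample size after
accounting for shared ancestry is much smaller than the species count, so
studies of ~100 lineages are underpowered.

`gctherm` implements the full analysis toolchain for this problem:
composition indexes from annotated genomes, phylogenetic signal, PGLS
regression under four trait-evolution models, sister-pair rank contrasts,
subsampling sensitivity, Lévy-jump detection, and spline-based
nonlinearity — together with a synthetic-data module that generates every
input with known truth, so the whole chain is testable without any
external database.

# Composition indexes

For an annotated genome (FASTA + GFF3), `compute_profile()` reports GC
percentages for: the whole genome (`GC_w`); concatenated, strand-corrected
protein-coding sequence (`GC_p`); fourfold-degenerate third codon
positions (`GC_4`); DNA covered by no annotated feature on either strand
(`GC_non`); and each structural RNA class (`GC_tRNA`, `GC_5S`, `GC_16S`,
`GC_23S`), plus chromosome-only and plasmid-only variants.  Conventions,
chosen once and applied everywhere:

* Coordinates are 1-based closed (the GFF3 convention); conversion happens
  only at the parser boundary.
* GC is computed excluding ambiguity codes from numerator and denominator;
  an empty effective length is reported as a missing value, never 0.
* A codon's third position counts toward `GC_4` iff its first two bases
  place it in one of the eight fourfold families of translation table 11
  (CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN).  The final codon of each CDS
  is treated as the stop and excluded; CDSs with length not divisible by
  three, internal stops, or ambiguity in the first two codon positions are
  skipped and counted.
* `GC_non` uses set semantics: a position covered by any feature is
  excluded exactly once, so `GC_non` plus length-weighted feature GC
  reconstitutes `GC_w`.
* Dinucleotides are counted on the given strand (windows containing
  ambiguity are skipped) and pooled into the ten reverse-complement
  classes AA(TT), AC(GT), AG(CT), AT, CA(TG), CC(GG), CG, GA(TC), GC, TA —
  equal to double-strand counting up to edge effects.

Growth-temperature ranks follow the half-open intervals: Topt < 20 °C
(rank 1), 20–45 (2), 45–80 (3), ≥ 80 (4).

# PGLS and phylogenetic signal

All regressions assume the response's residuals follow a Gaussian process
along the rooted, branch-length-bearing tree.  With `C` the matrix of
shared root-to-tip path lengths, the four residual-covariance models are

* **BM**: `V = σ² C`;
* **Pagel's λ**: off-diagonal entries multiplied by λ ∈ [0, 1];
* **OU (fixed root)**: `V_ij = σ²/(2α) (1 − e^{−2α t_ij}) e^{−α d_ij}`
  with `t_ij` the shared path and `d_ij` the patristic distance — the
  root state is estimated, not stationary;
* **EB**: `V_ij = σ² (e^{r t_ij} − 1)/r`, with the Brownian limit as
  `r → 0` (a series expansion is used below |r| = 1e-8).

Coefficients and σ² are profiled analytically at each candidate model
parameter; the scalar parameter (λ in [0,1], log α in [−10,10], r in
[−10,1]) is maximized by a 5-point grid with one golden-section refinement
in the best bracket.  Slope standard errors use the GLS coefficient
covariance with residual variance on `n − p` degrees of freedom; AIC
counts all free parameters (coefficients, σ², plus the model parameter
when estimated), so fits are comparable across models on the same data.
λ is capped at 1: values slightly above 1 can raise the likelihood on some
trees, but the capped parameterization keeps λ interpretable as a signal
proportion (this is why boundary fits can differ from implementations
that allow λ > 1).

Phylogenetic signal is the intercept-only λ fit, with a likelihood-ratio
test against λ = 0 on one χ² degree of freedom.  The phylogenetic paired
t-test models the per-tip difference of two traits with the λ model,
estimates its mean by GLS, and uses `n − 2` degrees of freedom (mean and
variance estimated) with variance `RSS/(n − 1)`; a likelihood-ratio
variant is available behind `method = "lrt"`.

Numerical care: all solves go through Cholesky factorization.  Duplicated
rows in `C` (zero-length terminal branches) get a single logged jitter of
`1e-10 · mean(diag)`; any remaining non-positive-definiteness is an error,
never a silent regularization.

## Multiple testing

`bh_adjust()` wraps the standard Benjamini–Hochberg step-up.  The family
grouping that reproduces the published adjusted columns of the shipped
regression table is (domain × temperature index), i.e. the eight GC
indexes form one family of m = 8.  Printed inputs and outputs carry only
1–2 significant figures (including the conventional 2.2e-16 floor), which
bounds the achievable agreement at roughly 25% relative for
one-significant-figure cells; nothing in the package ever floors a P value
it computes.  Note the step-up operator is not idempotent — re-adjusting
adjusted values changes them — so adjusted values are never fed back in.

# Sister-pair contrasts and resampling

`extract_rank_pairs()` walks the tree in postorder (smallest clades
first).  An internal node yields a contrast iff all its descendant tips
are unused and carry exactly two distinct ranks; each rank's tips are
pooled by averaging (representing their shared internal node) and the
clade's tips are marked used, making the returned pairs disjoint and
phylogenetically independent.  Clades exposing three or more ranks never
pair at that node but may contribute pairs within sub-clades; ties are
broken by traversal order.

`wilcoxon_signed_rank()` drops zero differences, averages tied ranks, and
computes the exact two-sided tail by enumerating all 2^n sign assignments
(a shifted-polynomial convolution with ranks doubled to integers, so tied
half-ranks stay exact) for n ≤ 20; beyond that a normal approximation with
tie correction and continuity correction is used.

`resample_pgls()` draws m tips without replacement per round, reruns the
requested PGLS regressions on the induced covariance submatrix, and
tallies significantly negative / nonsignificant / significantly positive
slopes.  Round r uses a seed derived from (master seed, r), so individual
rounds are reproducible and adding rounds never reshuffles earlier ones.
Power in this design saturates quickly: with evolutionary correlation 0.6
the positive-significant fraction is ~1 even at m = 40 on a 300-tip tree,
so the package's own sensitivity demonstrations use correlation 0.3,
the partial-power regime in which a correlation detectable in the full
sample is routinely lost in subsamples — the regime the real data occupy.

# Lévy-jump model

The jump model adds a compound Poisson process to Brownian motion: a
branch of length t contributes a `N(0, σ²t)` increment plus
`K ~ Poisson(λ_J t)` jumps, each `N(0, σ_J²)` (zero-mean Gaussian jump
sizes; heavier-tailed size families are out of scope).  Conditional on the
per-branch jump counts `k`, tip values are multivariate normal with
covariance `σ²C + σ_J² Σ_b k_b Z_b Z_bᵀ`, `Z_b` the indicator of tips
below branch b.

The marginal likelihood is estimated by importance sampling from the
Poisson prior: M count configurations are drawn by pushing one fixed
uniform matrix through the Poisson quantile function (common random
numbers — counts vary smoothly as λ_J moves during optimization, and the
same draws serve every parameter evaluation), per-branch counts are capped
at 10, duplicate configurations are collapsed before factorization, and
the four parameters (σ², λ_J, σ_J², μ₀) are maximized by Nelder–Mead from
two starting points.  AIC compares the jump fit (4 parameters) with the
closed-form Brownian fit (2: σ², μ₀).

Branch posteriors are self-normalized importance estimates
`pp_b = Σ_m w_m 1{k_b ≥ 1}` with weights proportional to the Gaussian data
density.  The estimator is honest about its own degeneracy: the effective
sample size `1/Σw²` is attached to every posterior, with a warning below
50.  On large trees with several true jumps the prior rarely proposes the
right configuration and the ESS collapses toward 1 — the main desk-scale
limitation of estimating this model by prior importance sampling rather
than expectation–maximization, and the reason the workflow does
branch-level inference at clade scale (≤ ~100 tips) while model
comparison runs on the full tree.

`calibrate_threshold()` simulates datasets under the fitted parameters,
scores calls against the simulation truth at each threshold, and reports
the precision–recall curve (with the standard monotone interpolation,
under which precision is nonincreasing in recall) plus the smallest
threshold reaching a requested precision.  `jump_change_correlation()`
takes the called branches, computes each trait's change as the
Brownian-GLS ancestral estimate at the child minus the parent (observed
values at tips), and correlates the signed changes by Spearman's rank
correlation — exact permutation P for n ≤ 10 (blockwise enumeration of all
n! orders), t-approximation otherwise.

# Nonlinearity

`fit_gamm()` regresses a GC index on Topt with a penalized cubic
regression spline (10 knots at quantiles, second-derivative penalty) plus
a genus random intercept, estimated by REML through the mixed-model
representation (`mgcv::gamm`; when a fixed smoothing parameter is
requested the equivalent `gam` random-effect-smooth form is used, since
`gamm` cannot fix a per-term smoothing parameter).  The effective degrees
of freedom of the smooth measure nonlinearity: 1 is a straight line, and
the penalty-to-infinity limit collapses the fit to edf ≈ 1 regardless of
data.  The P value for the smooth is the usual Wald-type approximation on
penalized coefficients and is reported as approximate.

# Synthetic data: what it emulates, and what it does not

`gen_tree()` draws a conditioned birth–death tree (default pure birth)
rescaled to unit depth.  `gen_traits()` evolves (Topt, GC) by bivariate
Brownian motion; defaults give tip standard deviations of 15 °C and 10 GC
points at unit depth with evolutionary correlation 0.5 — spreads matching
the curated growth-temperature databases (Topt roughly 5–105 °C around a
mesophilic center of 35 °C; GC roughly 30–70%) and a positive
co-evolution of the size the comparative analyses report.  Options plant
discrete jumps on either trait (via the Lévy simulator, truth recorded)
and a constant GC offset on the lowest-mean-Topt clade of a requested
size, emulating the halophilic-archaea pattern of high GC at moderate
growth temperature.  `gen_genome()` assembles toy replicons from
fourfold-family codons (third positions Bernoulli at the GC_4 target, so
no internal stops by construction), intergenic spacers at the GC_non
target, and RNA genes at their targets, on alternating strands, and emits
FASTA/GFF3 plus a truth profile computed from the generator's own
segments — never through the annotation parser, so round-trips are a real
check.  All generators are pure functions of (config, seed) with
per-component derived sub-streams.

What the generator does **not** emulate: codon-usage and amino-acid
composition biases, sequence evolution along the tree, horizontal gene
transfer, annotation error, and any mechanistic link between jumps in GC
and shifts in Topt (planted jumps are independent of the co-trait).
Passing tests therefore demonstrate that the estimators recover what they
claim from data satisfying their assumptions — not that the biological
conclusions transfer to any particular real dataset.

# Problem sizes and open choices

The validation suite runs at sizes chosen to exercise each estimator's
asymptotic behaviour while staying desk-scale: PGLS calibration uses a
300-tip tree with 200 trait replicates; λ-signal recovery 128 tips × 100
replicates; jump model selection 48-tip trees, M = 150 importance draws,
16 replicates per scenario (with five planted jumps of standard deviation
5 in the jump arm); planted-jump localization 30 replicates at M = 600;
spline edf 400 observations over 50 genera with 15–30 replicates; and the
resampling curve averages 10–12 trait realizations × 30 rounds at each
m ∈ {40, 80, 150}.

Open choices resolved here, for the record: input trees are taken as
authoritative (no re-rooting or rescaling); the OU variant estimates the
root state ("fixed root"); GC_p includes stop codons while GC_4 excludes
them; the BH family grouping for the replicon and core/accessory analyses
is caller-configurable because the printed tables do not pin it down; and
the paired t-test uses the t reference by default with the LRT behind a
flag, since reference implementations differ on this convention.
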