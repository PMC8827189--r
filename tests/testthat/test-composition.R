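# GC indexes, dinucleotide classes, temperature ranks, core/accessory sets.

test_that("GC fraction handles ambiguity and degenerate input", {
  expect_equal(gc_fraction("GGCC"), 100)
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(gc_fraction("ATGCN"), 50)
  expect_true(is.na(gc_fraction("NNNN")))
  expect_true(is.na(gc_fraction("")))
  ## strand symmetry on random sequences
  for (seed in 1:5) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_equal(gc_fraction(s), gc_fraction(rc))
  }
})

test_that("fourfold-site GC agrees with the translation oracle", {
  expect_equal(fourfold_site_gc("ATGGCTGCAGCGTAA"), 100 / 3,
               ignore_attr = TRUE)
  expect_equal(fourfold_site_gc(paste0(strrep("GGG", 5), "TAA")), 100,
               ignore_attr = TRUE)
  ## skipping rules
  expect_message(
    out <- fourfold_site_gc(c("ATGGC", "ATGTAAGGGTAA", "ATGGGGTAA")),
    "skipped 2")
  expect_equal(attr(out, "skipped"), 2L)
  ## invariant to CDS order
  set.seed(1)
  cds <- vapply(1:20, function(i)
    gctherm:::random_cds(30, 55, seed = i), character(1))
  expect_equal(as.numeric(fourfold_site_gc(cds)),
               as.numeric(fourfold_site_gc(rev(cds))))
  ## 100 random valid CDS vs translating every third-position variant
  cds100 <- vapply(1:100, function(i)
    gctherm:::random_cds(25, runif(1, 20, 80), seed = 1000 + i),
    character(1))
  expect_equal(as.numeric(fourfold_site_gc(cds100)),
               oracle_fourfold_gc(cds100), tolerance = 1e-12)
})

test_that("dinucleotide classes pool reverse complements and sum to one", {
  f <- dinucleotide_class_freqs("AGAG")
  expect_equal(unname(f["AG(CT)"]), 2 / 3)
  expect_equal(unname(f["GA(TC)"]), 1 / 3)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(unname(dinucleotide_class_freqs("AT")["AT"]), 1)
  ## random 1 kb sequence vs an independent raw counter
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
             collapse = "")
  raw <- oracle_dinuc_counts(s)
  mine <- dinucleotide_class_freqs(s)
  pool <- c("AA(TT)" = raw[["AA"]] + raw[["TT"]],
            "AC(GT)" = raw[["AC"]] + raw[["GT"]],
            "AG(CT)" = raw[["AG"]] + raw[["CT"]],
            "AT" = raw[["AT"]],
            "CA(TG)" = raw[["CA"]] + raw[["TG"]],
            "CC(GG)" = raw[["CC"]] + raw[["GG"]],
            "CG" = raw[["CG"]],
            "GA(TC)" = raw[["GA"]] + raw[["TC"]],
            "GC" = raw[["GC"]], "TA" = raw[["TA"]])
  expect_equal(mine, pool / sum(pool))
  ## ambiguity windows are skipped, not counted
  expect_equal(sum(dinucleotide_class_freqs("ANAT") * 2), 1 * 2)
})

test_that("composition profile covers all indexes and missingness", {
  g0 <- annotated_genome("mini", c(chr = "ATGC"))
  pr0 <- compute_profile(g0)
  expect_equal(pr0$GC_w, 50)
  expect_equal(pr0$GC_non, 50)
  expect_true(is.na(pr0$GC_p))
  expect_true("GC_p" %in% attr(pr0, "missing_flags"))

  ## minus-strand CDS: GC_p equals the GC of the segment (strand symmetric)
  seqv <- paste0("TTACGCAGCCAT", "AAAAAA")   # revcomp(ATGGCTGCGTAA) + tail
  g1 <- annotated_genome("minus", c(chr = seqv),
    features = data.frame(replicon = "chr", type = "CDS", start = 1L,
                          end = 12L, strand = "-",
                          stringsAsFactors = FALSE))
  pr1 <- compute_profile(g1)
  expect_equal(pr1$GC_p, gc_fraction(substr(seqv, 1, 12)))
  ## GC_non over uncovered positions only
  expect_equal(pr1$GC_non, gc_fraction("AAAAAA"))

  ## length-weighted reconstitution of GC_w from covered + uncovered parts
  d <- tempfile()
  gg <- gen_genome(d, n_cds = 20, seed = 5, n_trna = 2)
  pr <- compute_profile(gg$genome)
  reps <- gg$genome$replicons
  feats <- gg$genome$features
  cov_len <- sum(feats$end - feats$start + 1)
  tot_len <- sum(Biostrings::width(reps))
  cov_gc <- sum(vapply(seq_len(nrow(feats)), function(i)
    sum(gctherm:::acgt_counts(gctherm:::feature_seq(gg$genome,
                                                    feats[i, ]))[c("G", "C")]),
    numeric(1)))
  gcw_recon <- 100 * (cov_gc + pr$GC_non / 100 * (tot_len - cov_len)) /
    tot_len
  expect_equal(pr$GC_w, gcw_recon, tolerance = 1e-9)

  ## feature beyond replicon end is rejected
  expect_error(annotated_genome("bad", c(chr = "ATGC"),
    features = data.frame(replicon = "chr", type = "CDS", start = 2L,
                          end = 9L, strand = "+")),
    "out of replicon bounds")
})

test_that("genomes round-trip through FASTA/GFF3 identically", {
  d <- tempfile()
  gg <- gen_genome(d, n_cds = 30, gc4 = 65, gcnon = 35, seed = 9,
                   n_plasmids = 1)
  ge <- read_annotated_genome(gg$fasta, gg$gff)
  expect_equal(as.character(ge$replicons), as.character(gg$genome$replicons))
  expect_equal(unname(ge$classes[grepl("plasmid", names(ge$classes))]),
               "plasmid")
  pr_file <- compute_profile(ge)
  pr_mem <- compute_profile(gg$genome)
  for (col in c("GC_w", "GC_p", "GC_4", "GC_non", "GC_tRNA", "GC_16S"))
    expect_equal(pr_file[[col]], pr_mem[[col]], tolerance = 1e-12)
})

test_that("temperature ranks follow the half-open Topt intervals", {
  expect_equal(classify_topt(c(19.9, 20, 44.9, 45, 79.9, 80, 103)),
               c(1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(classify_topt(NA_real_))
})

test_that("core/accessory partition respects thresholds and monotonicity", {
  m <- matrix(0L, 100, 3,
              dimnames = list(NULL, c("everywhere", "four", "five")))
  m[, "everywhere"] <- 1L
  m[1:4, "four"] <- 1L
  m[1:5, "five"] <- 1L
  cs <- core_accessory_sets(m)
  expect_equal(cs$core, "everywhere")
  expect_equal(cs$accessory, "four")           # 5/100 is not < 0.05

  gp <- gen_presence_matrix(100, n_core = 30, n_accessory = 500, seed = 3)
  rec <- core_accessory_sets(gp$matrix, accessory_fraction = 0.05)
  expect_setequal(rec$core, gp$truth$core)
  expect_setequal(rec$accessory, gp$truth$accessory)

  a5 <- core_accessory_sets(gp$matrix, accessory_fraction = 0.05)$accessory
  a10 <- core_accessory_sets(gp$matrix, accessory_fraction = 0.10)$accessory
  expect_true(all(a5 %in% a10))
  expect_error(core_accessory_sets(matrix(2, 2, 2)), "binary")
})
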