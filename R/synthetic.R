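# Synthetic-data generators: every input the pipeline consumes, with known
# truth, emulating the products of the curated growth-temperature and
# genome databases the analyses were designed around.  Every generator is a
# pure function of (config, seed); sub-streams are keyed per component so
# adding one output never perturbs another.

#' Simulate an ultrametric birth-death tree
#'
#' Conditioned birth-death tree with exactly \code{n_tips} surviving tips,
#' rescaled to unit root-to-tip depth.  Deterministic per seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates.
#' @param seed Integer seed.
#' @return A \code{"phylo"} tree of depth 1 with tips \code{t1..tn}.
#' @export
gen_tree <- function(n_tips, birth = 1, death = 0, seed = 1L) {
  stopifnot(n_tips >= 2L, birth > 0, death >= 0)
  tr <- with_seed(derive_seed(seed, 1L),
                  ape::rphylo(n_tips, birth = birth, death = death))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  validate_tree(tr)
  tr
}

#' Simulate co-evolving growth temperature and GC content
#'
#' Bivariate Brownian motion of (Topt, GC) along the tree with evolutionary
#' covariance \code{Sigma} per unit branch length, optionally with discrete
#' Levy jumps on either trait and a constant GC offset planted on one
#' low-temperature clade (the high-GC outlier pattern halophilic archaea
#' show).  Raw Brownian values are affinely mapped into plausible units
#' (Topt around \code{topt_center}, GC around \code{gc_center}, both
#' recorded), and rank categories are derived with [classify_topt()].
#'
#' @param tree A \code{"phylo"} tree.
#' @param Sigma 2x2 evolutionary covariance of (Topt, GC); the default
#'   gives tip standard deviations of 15 C and 10 GC points at unit depth
#'   with evolutionary correlation 0.5.
#' @param roots Raw root states.
#' @param jumps Optional list(trait = "Topt" or "GC", lambda_j, sigmaj2):
#'   adds a compound-Poisson jump component to one trait.
#' @param outlier Optional list(size, offset): plants \code{offset} GC
#'   points on the lowest-mean-Topt clade of about \code{size} tips.
#' @param topt_center,gc_center Centers of the affine unit maps.
#' @param seed Integer seed.
#' @return List with \code{traits} (data.frame tip, Topt, GC, rank) and
#'   \code{truth} (Sigma, roots, maps, jump record, outlier tips).
#' @export
gen_traits <- function(tree, Sigma = NULL, roots = c(0, 0), jumps = NULL,
                       outlier = NULL, topt_center = 35, gc_center = 50,
                       seed = 1L) {
  validate_tree(tree)
  if (is.null(Sigma)) {
    sdT <- 15; sdG <- 10; rho <- 0.5
    Sigma <- matrix(c(sdT^2, rho * sdT * sdG, rho * sdT * sdG, sdG^2), 2)
  }
  base <- simulate_traits(tree, Sigma, roots, seed = derive_seed(seed, 2L),
                          trait_names = c("Topt_raw", "GC_raw"))
  topt <- stats::setNames(base$Topt_raw, base$tip)
  gc <- stats::setNames(base$GC_raw, base$tip)
  jump_truth <- NULL
  if (!is.null(jumps)) {
    stopifnot(jumps$trait %in% c("Topt", "GC"))
    jl <- simulate_levy(tree, sigma2 = 0, lambda_j = jumps$lambda_j,
                        sigmaj2 = jumps$sigmaj2, mu0 = 0,
                        seed = derive_seed(seed, 3L))
    if (jumps$trait == "Topt") topt <- topt + jl$tips[names(topt)]
    else gc <- gc + jl$tips[names(gc)]
    jump_truth <- jl$truth
  }
  outlier_tips <- character(0)
  if (!is.null(outlier)) {
    n <- length(tree$tip.label)
    sizes <- vapply((n + 1L):(n + tree$Nnode), function(v)
      length(tip_descendants(tree, v)), integer(1))
    cand <- which(sizes >= outlier$size / 2 & sizes <= outlier$size * 1.5)
    if (!length(cand)) stop("no clade near the requested outlier size")
    mean_topt <- vapply(cand, function(i)
      mean(topt[tree$tip.label[tip_descendants(tree, n + i)]]), numeric(1))
    pick <- cand[which.min(mean_topt)]
    outlier_tips <- tree$tip.label[tip_descendants(tree, n + pick)]
    gc[outlier_tips] <- gc[outlier_tips] + outlier$offset
  }
  topt_c <- topt + topt_center
  gc_c <- gc + gc_center
  traits <- data.frame(tip = tree$tip.label,
                       Topt = unname(topt_c[tree$tip.label]),
                       GC = unname(gc_c[tree$tip.label]),
                       stringsAsFactors = FALSE)
  traits$rank <- classify_topt(traits$Topt)
  list(traits = traits,
       truth = list(Sigma = Sigma, roots = roots,
                    topt_map = c(shift = topt_center, scale = 1),
                    gc_map = c(shift = gc_center, scale = 1),
                    jumps = jump_truth, outlier_tips = outlier_tips))
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ch <- edge[edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

random_gc_seq <- function(len, gc, seed) {
  with_seed(seed, {
    is_gc <- stats::runif(len) < gc / 100
    b <- character(len)
    b[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
    b[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
    paste(b, collapse = "")
  })
}

## CDS built from fourfold-degenerate codon families only (never stop
## codons), third positions Bernoulli(gc4/100) in {G,C} vs {A,T}; ATG
## start, TAA stop.
random_cds <- function(n_codons, gc4, seed) {
  with_seed(seed, {
    pre <- sample(FOURFOLD_PREFIXES, n_codons, replace = TRUE)
    is_gc <- stats::runif(n_codons) < gc4 / 100
    third <- ifelse(is_gc, sample(c("G", "C"), n_codons, replace = TRUE),
                    sample(c("A", "T"), n_codons, replace = TRUE))
    paste0("ATG", paste0(pre, third, collapse = ""), "TAA")
  })
}

#' Generate a toy annotated genome with known composition
#'
#' Builds one chromosome (and optionally plasmids) of alternating
#' intergenic spacers and features: protein-coding genes whose
#' fourfold-degenerate third positions hit a target GC_4, spacers hitting a
#' target GC_non, and tRNA/5S/16S/23S genes with target GC, on alternating
#' strands.  Writes FASTA and GFF3 (\code{##gff-version 3}, rRNA typed via
#' \code{product=} attributes) and returns the generation-truth
#' composition alongside.
#'
#' @param out_dir Directory for output files.
#' @param genome_id Genome identifier (file stem and FASTA names).
#' @param n_cds CDS count on the chromosome.
#' @param cds_len_codons Codons per CDS (internal codons; >= 20 so targets
#'   are reachable).
#' @param gc4,gcnon,gc_trna,gc_5s,gc_16s,gc_23s Target percentages.
#' @param n_trna,n_5s,n_16s,n_23s RNA gene counts.
#' @param spacer_len Intergenic spacer length.
#' @param n_plasmids Plasmid count.
#' @param plasmid_gc_offset Added to gc4/gcnon targets on plasmids.
#' @param plasmid_n_cds CDS per plasmid.
#' @param seed Integer seed.
#' @return List with \code{fasta}, \code{gff} (paths), \code{genome}
#'   (the in-memory \code{"annotated_genome"}), and \code{truth}
#'   (realized GC values computed from the generator's own segments).
#' @export
gen_genome <- function(out_dir, genome_id = "synthetic_genome",
                       n_cds = 100L, cds_len_codons = 100L,
                       gc4 = 60, gcnon = 40, gc_trna = 55, gc_5s = 55,
                       gc_16s = 55, gc_23s = 55,
                       n_trna = 10L, n_5s = 1L, n_16s = 1L, n_23s = 1L,
                       spacer_len = 150L, n_plasmids = 0L,
                       plasmid_gc_offset = -5, plasmid_n_cds = 20L,
                       seed = 1L) {
  stopifnot(cds_len_codons >= 20L, n_cds >= 1L)
  if (any(c(gc4, gcnon, gc_trna, gc_5s, gc_16s, gc_23s) < 0) ||
      any(c(gc4, gcnon, gc_trna, gc_5s, gc_16s, gc_23s) > 100))
    stop("GC targets must be percentages in [0, 100]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rna_lens <- c(tRNA = 76L, rRNA_5S = 120L, rRNA_16S = 1500L,
                rRNA_23S = 2900L)

  build_replicon <- function(rep_name, n_cds_r, gc4_r, gcnon_r, rna_counts,
                             comp_key) {
    segs <- character(0); feats <- list(); pos <- 1L; fidx <- 0L
    cds_coding <- character(0)               # coding-strand CDS, bookkeeping
    spacers <- character(0)
    rna_seqs <- list(tRNA = character(0), rRNA_5S = character(0),
                     rRNA_16S = character(0), rRNA_23S = character(0))
    add_spacer <- function() {
      s <- random_gc_seq(spacer_len, gcnon_r,
                         derive_seed(seed, comp_key, 9000L + fidx))
      segs[[length(segs) + 1L]] <<- s
      spacers[[length(spacers) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_feature <- function(type, s, strand) {
      if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      segs[[length(segs) + 1L]] <<- s
      feats[[length(feats) + 1L]] <<- data.frame(
        replicon = rep_name, type = type, start = pos,
        end = pos + nchar(s) - 1L, strand = strand,
        stringsAsFactors = FALSE)
      pos <<- pos + nchar(s)
    }
    add_spacer()
    strands <- rep(c("+", "-"), length.out = n_cds_r)
    for (i in seq_len(n_cds_r)) {
      fidx <- fidx + 1L
      cds <- random_cds(cds_len_codons, gc4_r,
                        derive_seed(seed, comp_key, i))
      cds_coding <- c(cds_coding, cds)
      add_feature("CDS", cds, strands[i])
      add_spacer()
    }
    rna_targets <- c(tRNA = gc_trna, rRNA_5S = gc_5s, rRNA_16S = gc_16s,
                     rRNA_23S = gc_23s)
    for (ty in names(rna_counts)) {
      cnt <- rna_counts[[ty]]
      for (j in seq_len(cnt)) {
        fidx <- fidx + 1L
        s <- random_gc_seq(rna_lens[[ty]], rna_targets[[ty]],
                           derive_seed(seed, comp_key, 5000L + fidx))
        rna_seqs[[ty]] <- c(rna_seqs[[ty]], s)
        add_feature(ty, s, if (j %% 2L == 0L) "-" else "+")
      }
    }
    list(seq = paste(segs, collapse = ""),
         features = do.call(rbind, feats),
         cds = cds_coding, spacers = spacers, rna = rna_seqs)
  }

  chrom <- build_replicon(paste0(genome_id, "_chr"), n_cds, gc4, gcnon,
                          list(tRNA = n_trna, rRNA_5S = n_5s,
                               rRNA_16S = n_16s, rRNA_23S = n_23s), 1L)
  reps <- stats::setNames(chrom$seq, paste0(genome_id, "_chr"))
  feats <- chrom$features
  plasmid_parts <- list()
  if (n_plasmids > 0L) {
    for (p in seq_len(n_plasmids)) {
      pl <- build_replicon(paste0(genome_id, "_plasmid", p), plasmid_n_cds,
                           gc4 + plasmid_gc_offset,
                           gcnon + plasmid_gc_offset,
                           list(), 10L + p)
      reps <- c(reps, stats::setNames(pl$seq,
                                      paste0(genome_id, "_plasmid", p)))
      feats <- rbind(feats, pl$features)
      plasmid_parts[[p]] <- pl
    }
  }
  genome <- annotated_genome(genome_id, reps, features = feats)
  fasta <- file.path(out_dir, paste0(genome_id, ".fasta"))
  gff <- file.path(out_dir, paste0(genome_id, ".gff3"))
  Biostrings::writeXStringSet(genome$replicons, fasta, width = 70L)
  write_gff3(feats, gff)

  ## generation truth from the builder's own segment bookkeeping -- never
  ## through the annotation parser, so round trips are a real check.
  parts <- c(list(chrom), plasmid_parts)
  all_cds <- unlist(lapply(parts, `[[`, "cds"))
  all_spacers <- unlist(lapply(parts, `[[`, "spacers"))
  thirds <- vapply(all_cds, function(cds) {
    body <- substr(cds, 4L, nchar(cds) - 3L)   # internal fourfold codons
    paste(substring(body, seq(3L, nchar(body), 3L),
                    seq(3L, nchar(body), 3L)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  rna_truth <- lapply(c("tRNA", "rRNA_5S", "rRNA_16S", "rRNA_23S"),
                      function(ty) {
    s <- unlist(lapply(parts, function(p) p$rna[[ty]]))
    if (length(s)) gc_fraction(paste(s, collapse = "")) else NA_real_
  })
  names(rna_truth) <- c("GC_tRNA", "GC_5S", "GC_16S", "GC_23S")
  truth <- c(list(
    GC_w = gc_fraction(paste(unname(reps), collapse = "")),
    GC_p = gc_fraction(paste(all_cds, collapse = "")),
    GC_4 = gc_fraction(paste(thirds, collapse = "")),
    GC_non = gc_fraction(paste(all_spacers, collapse = ""))),
    rna_truth)
  list(fasta = fasta, gff = gff, genome = genome, truth = truth)
}

write_gff3 <- function(features, path) {
  products <- c(rRNA_5S = "5S ribosomal RNA", rRNA_16S = "16S ribosomal RNA",
                rRNA_23S = "23S ribosomal RNA")
  gff_type <- function(ty) switch(ty, CDS = "CDS", tRNA = "tRNA",
                                  other_RNA = "ncRNA", "rRNA")
  lines <- vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    attrs <- paste0("ID=feat", i)
    if (f$type %in% names(products))
      attrs <- paste0(attrs, ";product=", products[[f$type]])
    paste(f$replicon, "gctherm_synth", gff_type(f$type), f$start, f$end,
          ".", f$strand, if (f$type == "CDS") "0" else ".", attrs,
          sep = "\t")
  }, character(1))
  writeLines(c("##gff-version 3", lines), path)
}

#' Generate a gene presence/absence matrix with planted structure
#'
#' Core families present in every genome, accessory families each present
#' in fewer than \code{accessory_max_frac} of genomes, and optional
#' mid-frequency families in between.
#'
#' @param n_genomes Number of genomes (rows).
#' @param n_core,n_accessory,n_mid Family counts per stratum.
#' @param accessory_max_frac Upper bound on accessory presence fraction.
#' @param seed Integer seed.
#' @return List with \code{matrix} (binary, genomes x families) and
#'   \code{truth} (planted family names per stratum).
#' @export
gen_presence_matrix <- function(n_genomes, n_core = 30L,
                                n_accessory = 500L, n_mid = 50L,
                                accessory_max_frac = 0.04, seed = 1L) {
  stopifnot(n_genomes >= 5L)
  max_k <- max(1L, floor(accessory_max_frac * n_genomes))
  with_seed(derive_seed(seed, 4L), {
    cols <- list()
    fam <- character(0)
    for (i in seq_len(n_core)) {
      cols[[length(cols) + 1L]] <- rep(1L, n_genomes)
      fam <- c(fam, sprintf("core%03d", i))
    }
    for (i in seq_len(n_mid)) {
      pr <- stats::runif(1, 0.2, 0.9)
      cols[[length(cols) + 1L]] <- stats::rbinom(n_genomes, 1L, pr)
      fam <- c(fam, sprintf("mid%03d", i))
    }
    for (i in seq_len(n_accessory)) {
      k <- sample.int(max_k, 1L)
      v <- integer(n_genomes)
      v[sample.int(n_genomes, k)] <- 1L
      cols[[length(cols) + 1L]] <- v
      fam <- c(fam, sprintf("acc%04d", i))
    }
    m <- do.call(cbind, cols)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genomes)), fam)
    list(matrix = m,
         truth = list(core = fam[startsWith(fam, "core")],
                      mid = fam[startsWith(fam, "mid")],
                      accessory = fam[startsWith(fam, "acc")]))
  })
}
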