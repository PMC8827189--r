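# Genome composition indexes: GC content of the whole genome, protein-coding
# sequence, fourfold-degenerate third codon positions, unannotated DNA and
# structural RNA genes, plus reverse-complement-pooled dinucleotide
# frequencies.  Coordinates are 1-based closed (GFF3 convention), converted
# once at the parser boundary.

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA_5S", "rRNA_16S", "rRNA_23S",
                   "other_RNA")

## Codon families whose third position is fourfold degenerate under
## translation table 11: first two bases CT, GT, TC, CC, AC, GC, CG, GG.
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' GC percentage of a nucleotide sequence
#'
#' \eqn{100 (G + C) / (A + C + G + T)}; ambiguity codes are excluded from
#' both numerator and denominator.  An empty effective length yields
#' \code{NA} (a missing value, not zero).
#'
#' @param seq A character string or \code{Biostrings} XString/XStringSet.
#' @return GC percentage in [0, 100], or \code{NA_real_}.
#' @export
gc_fraction <- function(seq) {
  counts <- acgt_counts(seq)
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

acgt_counts <- function(seq) {
  if (is.character(seq)) {
    seq <- paste(toupper(seq), collapse = "")
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    c(A = sum(v == "A"), C = sum(v == "C"),
      G = sum(v == "G"), T = sum(v == "T"))
  } else {
    if (inherits(seq, "XString")) seq <- Biostrings::DNAStringSet(seq)
    f <- colSums(Biostrings::letterFrequency(seq, c("A", "C", "G", "T")))
    c(A = f[["A"]], C = f[["C"]], G = f[["G"]], T = f[["T"]])
  }
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Loads replicon sequences (\code{Biostrings}) and features
#' (\code{rtracklayer}), mapping GFF3 types onto the internal feature
#' vocabulary: \code{CDS} and \code{tRNA} directly; \code{rRNA} by its
#' \code{product} attribute (\code{5S}/\code{16S}/\code{23S}); any other
#' RNA type to \code{other_RNA}.  Container rows (\code{gene},
#' \code{region}, \code{exon}) are dropped.  Replicons whose names contain
#' \code{"plasmid"} (case-insensitive) are classed as plasmids unless
#' \code{replicon_classes} overrides.
#'
#' @param fasta Path to a FASTA file of replicon sequences.
#' @param gff Path to a GFF3 file of features.
#' @param genome_id Identifier for the genome (defaults to the FASTA
#'   basename).
#' @param replicon_classes Optional named character vector
#'   (\code{"chromosome"}/\code{"plasmid"}) keyed by replicon name.
#' @return An \code{"annotated_genome"}: list with \code{id},
#'   \code{replicons} (DNAStringSet), \code{classes}, and \code{features}
#'   (data.frame: replicon, type, start, end, strand; 1-based closed).
#' @export
read_annotated_genome <- function(fasta, gff, genome_id = NULL,
                                  replicon_classes = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  type <- as.character(gr$type)
  keep <- !(type %in% c("gene", "region", "exon", "chromosome", "contig"))
  gr <- gr[keep]; type <- type[keep]
  prod <- if (!is.null(gr$product)) as.character(gr$product)
          else rep(NA_character_, length(gr))
  map_type <- function(ty, pr) {
    if (ty == "CDS") return("CDS")
    if (ty == "tRNA") return("tRNA")
    if (ty == "rRNA") {
      if (!is.na(pr) && grepl("5S", pr)) return("rRNA_5S")
      if (!is.na(pr) && grepl("16S", pr)) return("rRNA_16S")
      if (!is.na(pr) && grepl("23S", pr)) return("rRNA_23S")
      return("other_RNA")
    }
    "other_RNA"
  }
  feats <- data.frame(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    type = mapply(map_type, type, prod, USE.NAMES = FALSE),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  classes <- ifelse(grepl("plasmid", names(seqs), ignore.case = TRUE),
                    "plasmid", "chromosome")
  names(classes) <- names(seqs)
  if (!is.null(replicon_classes))
    classes[names(replicon_classes)] <- replicon_classes
  annotated_genome(genome_id %||% sub("\\.[^.]*$", "", basename(fasta)),
                   seqs, classes, feats)
}

#' Construct an annotated genome object
#'
#' @param id Genome identifier.
#' @param replicons Named \code{DNAStringSet} (or named character vector).
#' @param classes Named character vector, \code{"chromosome"} or
#'   \code{"plasmid"} per replicon.
#' @param features Data.frame with columns replicon, type, start, end,
#'   strand (1-based closed coordinates).
#' @return An \code{"annotated_genome"}.
#' @export
annotated_genome <- function(id, replicons, classes = NULL,
                             features = NULL) {
  if (is.character(replicons))
    replicons <- Biostrings::DNAStringSet(replicons)
  stopifnot(length(replicons) >= 1L, !is.null(names(replicons)))
  if (is.null(classes)) {
    classes <- ifelse(grepl("plasmid", names(replicons),
                            ignore.case = TRUE), "plasmid", "chromosome")
    names(classes) <- names(replicons)
  }
  if (is.null(features))
    features <- data.frame(replicon = character(), type = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  stopifnot(all(features$type %in% FEATURE_TYPES),
            all(features$replicon %in% names(replicons)))
  lens <- Biostrings::width(replicons)[match(features$replicon,
                                             names(replicons))]
  bad <- features$start < 1 | features$start > features$end |
         features$end > lens
  if (any(bad))
    stop("feature out of replicon bounds: ",
         features$replicon[bad][1], ":", features$start[bad][1], "-",
         features$end[bad][1])
  structure(list(id = id, replicons = replicons, classes = classes,
                 features = features), class = "annotated_genome")
}

feature_seq <- function(genome, row) {
  s <- Biostrings::subseq(genome$replicons[[row$replicon]],
                          row$start, row$end)
  if (row$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

feature_seqs <- function(genome, types) {
  f <- genome$features[genome$features$type %in% types, , drop = FALSE]
  if (!nrow(f)) return(Biostrings::DNAStringSet())
  Biostrings::DNAStringSet(lapply(seq_len(nrow(f)), function(i)
    feature_seq(genome, f[i, ])))
}

#' GC content at fourfold-degenerate third codon positions
#'
#' Over all codons except the final (stop) codon of each coding sequence, a
#' third position is counted iff the first two bases place the codon in a
#' fourfold-degenerate family under translation table 11 (families CTN,
#' GTN, TCN, CCN, ACN, GCN, CGN, GGN).  Coding sequences whose length is
#' not divisible by 3, that contain internal stop codons, or that carry
#' ambiguity in the first two positions of any codon are skipped (count
#' reported via the \code{"skipped"} attribute and a message).
#'
#' @param cds_sequences Character vector or \code{DNAStringSet} of CDS
#'   given in reading frame on the coding strand.
#' @return GC percentage of counted third positions (\code{NA} if none),
#'   with attribute \code{skipped}.
#' @export
fourfold_site_gc <- function(cds_sequences) {
  if (length(cds_sequences) == 0L) return(NA_real_)
  s <- toupper(as.character(cds_sequences))
  thirds <- character(0)
  skipped <- 0L
  for (cds in s) {
    L <- nchar(cds)
    if (L < 6L || L %% 3L != 0L) { skipped <- skipped + 1L; next }
    starts <- seq(1L, L - 3L, by = 3L)         # all codons but the last
    codons <- substring(cds, starts, starts + 2L)
    if (any(codons[-1] %in% STOP_CODONS)) { skipped <- skipped + 1L; next }
    pre <- substring(codons, 1L, 2L)
    if (any(!strsplit(paste(pre, collapse = ""), "")[[1]] %in%
            c("A", "C", "G", "T"))) { skipped <- skipped + 1L; next }
    ff <- pre %in% FOURFOLD_PREFIXES
    thirds <- c(thirds, substring(codons[ff], 3L, 3L))
  }
  if (skipped > 0L)
    message("gctherm: skipped ", skipped, " CDS in fourfold-site GC")
  out <- if (length(thirds)) gc_fraction(paste(thirds, collapse = ""))
         else NA_real_
  attr(out, "skipped") <- skipped
  out
}

#' Dinucleotide reverse-complement class frequencies
#'
#' Counts overlapping dinucleotides on the given strand of every replicon
#' (no wraparound; windows containing ambiguity are not counted) and pools
#' the 16 dinucleotides into the 10 reverse-complement classes AA(TT),
#' AC(GT), AG(CT), AT, CA(TG), CC(GG), CG, GA(TC), GC, TA — equivalent to
#' double-strand counting up to edge effects.
#'
#' @param x An \code{"annotated_genome"}, \code{DNAStringSet}, or character
#'   vector of sequences.
#' @return Named numeric vector of 10 frequencies summing to 1 (all
#'   \code{NA} when no countable window exists).
#' @export
dinucleotide_class_freqs <- function(x) {
  seqs <- if (inherits(x, "annotated_genome")) x$replicons
          else if (is.character(x)) Biostrings::DNAStringSet(toupper(x))
          else x
  counts <- colSums(Biostrings::dinucleotideFrequency(seqs))
  classes <- list(
    "AA(TT)" = c("AA", "TT"), "AC(GT)" = c("AC", "GT"),
    "AG(CT)" = c("AG", "CT"), "AT" = "AT",
    "CA(TG)" = c("CA", "TG"), "CC(GG)" = c("CC", "GG"),
    "CG" = "CG", "GA(TC)" = c("GA", "TC"), "GC" = "GC", "TA" = "TA")
  pooled <- vapply(classes, function(k) sum(counts[k]), numeric(1))
  tot <- sum(pooled)
  if (tot == 0) return(stats::setNames(rep(NA_real_, 10), names(classes)))
  pooled / tot
}

#' Growth-temperature rank category
#'
#' Maps an optimal growth temperature (Celsius) onto rank codes:
#' 1 psychrophile/psychrotrophile (Topt < 20), 2 mesophile (20 <= Topt <
#' 45), 3 thermophile (45 <= Topt < 80), 4 hyperthermophile (Topt >= 80).
#'
#' @param topt Numeric vector of optimal growth temperatures.
#' @return Integer rank codes 1-4.
#' @export
classify_topt <- function(topt) {
  stopifnot(all(is.finite(topt)))
  findInterval(topt, c(20, 45, 80)) + 1L
}

#' Core and accessory gene families from a presence/absence matrix
#'
#' Core families are present in at least \code{core_fraction} of genomes;
#' accessory families in strictly less than \code{accessory_fraction}.
#' The two sets are disjoint whenever
#' \code{accessory_fraction <= core_fraction}.
#'
#' @param presence Binary genome x family matrix (families as columns).
#' @param core_fraction Presence fraction defining core (default 1).
#' @param accessory_fraction Presence fraction bounding accessory
#'   (default 0.05).
#' @return List with \code{core} and \code{accessory} family names.
#' @export
core_accessory_sets <- function(presence, core_fraction = 1.0,
                                accessory_fraction = 0.05) {
  presence <- as.matrix(presence)
  if (!length(presence)) stop("empty presence/absence matrix")
  if (!all(presence %in% c(0, 1))) stop("matrix must be binary 0/1")
  frac <- colMeans(presence)
  fam <- colnames(presence) %||% as.character(seq_len(ncol(presence)))
  list(core = fam[frac >= core_fraction],
       accessory = fam[frac < accessory_fraction])
}

#' Composition profile of an annotated genome
#'
#' Computes every GC index analyzed downstream: \code{GC_w} over all
#' replicons; \code{GC_p} over strand-corrected concatenated CDS;
#' \code{GC_4} per [fourfold_site_gc()]; \code{GC_non} over positions
#' covered by no feature of any type on either strand (set semantics);
#' \code{GC_tRNA}/\code{GC_5S}/\code{GC_16S}/\code{GC_23S} over the
#' concatenated RNA genes of each class; plus chromosome-only and
#' plasmid-only variants of the four genomic indexes.  Missing annotations
#' yield \code{NA} with a flag, never zero.
#'
#' @param genome An \code{"annotated_genome"}.
#' @param translation_table Genetic code id (11, bacterial/archaeal; fixed).
#' @return A \code{"composition_profile"}: one-row data.frame of
#'   percentages with a \code{missing_flags} attribute.
#' @export
compute_profile <- function(genome, translation_table = 11L) {
  stopifnot(inherits(genome, "annotated_genome"),
            translation_table == 11L)
  reps <- genome$replicons
  feats <- genome$features
  idx_class <- function(cls) names(reps)[genome$classes == cls]
  gc_set <- function(repnames) {
    if (!length(repnames)) return(NA_real_)
    gc_fraction(reps[repnames])
  }
  cds_of <- function(repnames) {
    f <- feats[feats$type == "CDS" & feats$replicon %in% repnames, ,
               drop = FALSE]
    if (!nrow(f)) return(Biostrings::DNAStringSet())
    Biostrings::DNAStringSet(lapply(seq_len(nrow(f)), function(i)
      feature_seq(genome, f[i, ])))
  }
  gc_p_of <- function(repnames) {
    cds <- cds_of(repnames)
    if (!length(cds)) return(NA_real_)
    gc_fraction(cds)
  }
  gc_4_of <- function(repnames) {
    cds <- cds_of(repnames)
    if (!length(cds)) return(NA_real_)
    as.numeric(fourfold_site_gc(cds))
  }
  gc_non_of <- function(repnames) {
    pieces <- lapply(repnames, function(rn) {
      L <- Biostrings::width(reps[rn])
      f <- feats[feats$replicon == rn, , drop = FALSE]
      cov <- if (nrow(f))
        IRanges::reduce(IRanges::IRanges(f$start, f$end))
      else IRanges::IRanges()
      gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), cov)
      if (!length(gaps)) return(NULL)
      Biostrings::extractAt(reps[[rn]], gaps)
    })
    pieces <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
    if (is.null(pieces) || !length(pieces)) return(NA_real_)
    gc_fraction(pieces)
  }
  rna_gc <- function(type) {
    s <- feature_seqs(genome, type)
    if (!length(s)) return(NA_real_)
    gc_fraction(s)
  }
  chrom <- idx_class("chromosome"); plas <- idx_class("plasmid")
  out <- data.frame(
    genome = genome$id,
    GC_w = gc_set(names(reps)),
    GC_p = gc_p_of(names(reps)),
    GC_4 = gc_4_of(names(reps)),
    GC_non = gc_non_of(names(reps)),
    GC_tRNA = rna_gc("tRNA"),
    GC_5S = rna_gc("rRNA_5S"),
    GC_16S = rna_gc("rRNA_16S"),
    GC_23S = rna_gc("rRNA_23S"),
    GC_w_chromosome = gc_set(chrom),
    GC_p_chromosome = gc_p_of(chrom),
    GC_4_chromosome = gc_4_of(chrom),
    GC_non_chromosome = gc_non_of(chrom),
    GC_w_plasmid = gc_set(plas),
    GC_p_plasmid = gc_p_of(plas),
    GC_4_plasmid = gc_4_of(plas),
    GC_non_plasmid = gc_non_of(plas),
    stringsAsFactors = FALSE)
  flags <- names(out)[vapply(out, function(v) is.numeric(v) && is.na(v),
                             logical(1))]
  attr(out, "missing_flags") <- flags
  class(out) <- c("composition_profile", "data.frame")
  out
}
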