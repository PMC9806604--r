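#' Default motif classes for telomere / satellite read classification
#'
#' The four diagnostic exact motifs: five tandem copies of each strand of the
#' plant telomeric repeat unit, and the two 23-nt centromeric 178-bp satellite
#' motifs Cen1 and Cen2. Reads containing `TEL_C` or `TEL_G` are taken to
#' originate from terminal telomeric arrays (internal perfect stretches of
#' five or more repeats being rare), while `CEN1`/`CEN2` reads report on the
#' 178-bp satellite repeats used as heterochromatic reference.
#'
#' @return named character vector of motif sequences.
#' @examples
#' default_motif_classes()
#' @export
default_motif_classes <- function() {
  c(TEL_C = strrep("CCCTAAA", 5L),
    TEL_G = strrep("TTTAGGG", 5L),
    CEN1  = "TTGGCTTTGTATCTTCTAACAAG",
    CEN2  = "CATATTTGACTCCAAAACACTAA")
}

#' Count exact overlapping occurrences of a motif in a sequence
#'
#' Occurrences are counted at every start position, overlaps included: a
#' perfect tandem array of `n` copies of a 7-bp repeat contains `n - 4`
#' overlapping copies of the 35-bp five-repeat motif (two for six repeats,
#' three for seven, and so on). Matching is exact and literal; a position
#' containing `N` -- in the sequence or in the motif -- never matches.
#'
#' @param sequence subject nucleotide string (possibly empty); uppercase
#'   `ACGTN` alphabet.
#' @param motif non-empty motif string, same alphabet.
#' @return non-negative integer count of overlapping occurrences.
#' @examples
#' count_overlapping(strrep("CCCTAAA", 6), strrep("CCCTAAA", 5)) # 2
#' @export
count_overlapping <- function(sequence, motif) {
  sequence <- validate_dna(sequence, "sequence", allow_empty = TRUE)
  motif <- validate_dna(motif, "motif")
  if (nchar(sequence) < nchar(motif)) return(0L)
  if (grepl("N", motif, fixed = TRUE)) return(0L)
  Biostrings::countPattern(Biostrings::DNAString(motif),
                           Biostrings::DNAString(sequence), fixed = TRUE)
}

#' Classify a read by the motif classes it contains
#'
#' A read belongs to a class if that class's motif occurs at least once in
#' the literal read string (no reverse-complement expansion: C-strand- and
#' G-strand-derived telomeric reads are deliberately distinct classes).
#' Multiplicity is ignored -- a read counts once per class however many
#' occurrences it holds. A read may belong to several classes.
#'
#' @param read_sequence read nucleotide string (length >= 1).
#' @param classes named character vector of motif sequences
#'   (default [default_motif_classes()]).
#' @return character vector of matching class names (possibly empty).
#' @examples
#' classify_read(strrep("TTTAGGG", 10)) # "TEL_G"
#' @export
classify_read <- function(read_sequence, classes = default_motif_classes()) {
  read_sequence <- validate_dna(read_sequence, "read_sequence")
  stopifnot(length(classes) >= 1L, !is.null(names(classes)))
  hit <- vapply(classes, function(m) count_overlapping(read_sequence, m) > 0L,
                logical(1))
  names(classes)[hit]
}

#' Classify a set of reads into motif classes (vectorised)
#'
#' @param reads `DNAStringSet` (or FASTQ path) of reads.
#' @param classes named character vector of motif sequences.
#' @return logical matrix, one row per read and one column per class;
#'   `TRUE` where the class motif occurs at least once in the read.
#' @export
classify_reads <- function(reads, classes = default_motif_classes()) {
  reads <- read_reads(reads)
  stopifnot(length(classes) >= 1L, !is.null(names(classes)))
  hits <- vapply(classes, function(m) {
    m <- validate_dna(m, "motif")
    if (grepl("N", m, fixed = TRUE)) return(rep(FALSE, length(reads)))
    Biostrings::vcountPattern(Biostrings::DNAString(m), reads,
                              fixed = TRUE) >= 1L
  }, logical(length(reads)))
  if (length(reads) == 1L) hits <- matrix(hits, nrow = 1L,
                                          dimnames = list(NULL, names(classes)))
  hits
}

#' Locate maximal terminal telomeric arrays for masking
#'
#' Scans inwards from both ends of every chromosome and records the maximal
#' terminal run that is a perfect periodic repetition of a telomeric unit
#' (any cyclic rotation of `CCCTAAA` or `TTTAGGG`), with zero mismatches.
#' These terminal arrays are the telomere mask used by
#' [count_internal_motifs()]: anything beyond them, subtelomeric ITSs
#' included, counts as internal.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param units character vector of repeat units to try (both telomeric
#'   strands by default).
#' @param min_run_bp minimum run length in bp for a terminal run to be
#'   reported (default one full unit, 7 bp).
#' @param max_scan_bp how far from each terminus to scan (default 50 kb).
#' @return `GRanges` of terminal telomeric arrays (possibly empty).
#' @export
find_telomere_mask <- function(genome, units = c("CCCTAAA", "TTTAGGG"),
                               min_run_bp = 7L, max_scan_bp = 50000L) {
  genome <- read_genome(genome)
  rots <- unique(unlist(lapply(units, function(u) {
    n <- nchar(u)
    vapply(seq_len(n), function(i) {
      paste0(substr(u, i, n), substr(u, 1, i - 1L))
    }, character(1))
  })))
  run_len <- function(chars) {
    # longest prefix of chars equal to a periodic extension of any rotation
    best <- 0L
    for (r in rots) {
      rv <- strsplit(r, "")[[1]]
      per <- rep_len(rv, length(chars))
      mis <- which(chars != per)
      len <- if (length(mis)) mis[1] - 1L else length(chars)
      if (len > best) best <- len
    }
    best
  }
  out <- list()
  for (nm in names(genome)) {
    L <- length(genome[[nm]])
    w <- min(L, max_scan_bp)
    left <- strsplit(as.character(Biostrings::subseq(genome[[nm]], 1L, w)),
                     "")[[1]]
    right <- rev(strsplit(as.character(
      Biostrings::subseq(genome[[nm]], L - w + 1L, L)), "")[[1]])
    rots_fwd <- rots
    lrun <- run_len(left)
    # right end: scan the reversed suffix against reversed rotations
    rots_rev <- unique(vapply(rots, function(r) {
      paste(rev(strsplit(r, "")[[1]]), collapse = "")
    }, character(1)))
    rots <- rots_rev
    rrun <- run_len(right)
    rots <- rots_fwd
    iv <- list()
    if (lrun >= min_run_bp) iv <- c(iv, list(c(1L, lrun)))
    if (rrun >= min_run_bp) iv <- c(iv, list(c(L - rrun + 1L, L)))
    if (length(iv)) {
      m <- do.call(rbind, iv)
      out[[nm]] <- GenomicRanges::GRanges(
        nm, IRanges::IRanges(start = m[, 1], end = m[, 2]))
    }
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges())
  }
  unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
}

#' Count motif occurrences at internal (non-telomeric) chromosomal loci
#'
#' Counts exact overlapping occurrences of `motif` across all chromosomes,
#' keeping only occurrences whose start position lies outside every masked
#' terminal telomeric array. An occurrence straddling a mask boundary is
#' internal if and only if its start is unmasked. With an empty mask this is
#' the plain whole-genome overlapping census.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param motif motif string (e.g. `default_motif_classes()[["TEL_C"]]`).
#' @param telomere_mask `GRanges` of terminal arrays (e.g. from
#'   [find_telomere_mask()]), or `NULL` for no masking.
#' @return non-negative integer: total internal overlapping occurrences.
#' @export
count_internal_motifs <- function(genome, motif, telomere_mask = NULL) {
  genome <- read_genome(genome)
  motif <- validate_dna(motif, "motif")
  if (!is.null(telomere_mask)) {
    stopifnot(methods::is(telomere_mask, "GRanges"))
    mn <- as.character(GenomicRanges::seqnames(telomere_mask))
    if (!all(mn %in% names(genome))) {
      stop("telomere_mask names chromosomes absent from the genome")
    }
    L <- setNames(Biostrings::width(genome), names(genome))
    if (any(GenomicRanges::start(telomere_mask) < 1L) ||
        any(GenomicRanges::end(telomere_mask) > L[mn])) {
      stop("telomere_mask interval out of chromosome bounds")
    }
  }
  if (grepl("N", motif, fixed = TRUE)) return(0L)
  total <- 0L
  for (nm in names(genome)) {
    starts <- BiocGenerics::start(
      Biostrings::matchPattern(Biostrings::DNAString(motif), genome[[nm]],
                               fixed = TRUE))
    if (!length(starts)) next
    if (!is.null(telomere_mask)) {
      msk <- telomere_mask[as.character(GenomicRanges::seqnames(telomere_mask)) == nm]
      if (length(msk)) {
        keep <- rep(TRUE, length(starts))
        for (i in seq_along(msk)) {
          keep <- keep & !(starts >= GenomicRanges::start(msk)[i] &
                             starts <= GenomicRanges::end(msk)[i])
        }
        starts <- starts[keep]
      }
    }
    total <- total + length(starts)
  }
  total
}

#' Expected number of overlapping telomeric motifs at intact telomeres
#'
#' The simple length-based approximation `(telomere_length_bp /
#' repeat_length_bp) * n_chromosome_ends`, i.e. the number of repeat units
#' per terminal array times the number of chromosome ends. For Arabidopsis
#' Col-0 (3,750-bp telomeres, 7-bp unit, 10 ends) this gives about 5,350
#' overlapping five-repeat motifs genome-wide. The approximation ignores the
#' per-array edge correction of minus four motifs (a 35-bp window cannot
#' start in the last four units of an array), which would lower the estimate
#' by `4 * n_chromosome_ends`.
#'
#' @param telomere_length_bp telomere tract length per chromosome end (bp).
#' @param repeat_length_bp repeat unit length (bp), 7 for plant telomeres.
#' @param n_chromosome_ends number of chromosome ends (2 per chromosome).
#' @return positive number (not rounded).
#' @examples
#' expected_telomeric_motifs(3750, 7, 10) # ~5357, "about 5,350"
#' @export
expected_telomeric_motifs <- function(telomere_length_bp, repeat_length_bp,
                                      n_chromosome_ends) {
  if (!is.numeric(telomere_length_bp) || telomere_length_bp <= 0 ||
      !is.numeric(repeat_length_bp) || repeat_length_bp <= 0 ||
      repeat_length_bp != as.integer(repeat_length_bp) ||
      !is.numeric(n_chromosome_ends) || n_chromosome_ends <= 0 ||
      n_chromosome_ends != as.integer(n_chromosome_ends)) {
    stop("all arguments must be positive (repeat length and end count integral)")
  }
  (telomere_length_bp / repeat_length_bp) * n_chromosome_ends
}

#' Percentage of motif-classified reads attributable to ITSs
#'
#' Given the number of internal (ITS) occurrences of the diagnostic motif
#' and the number of telomeric occurrences, returns the expected percentage
#' of motif-containing reads that originate from ITSs rather than telomeres:
#' `100 * internal / (internal + telomeric)`. With 109 internal and ~5,350
#' telomeric occurrences this is ~2%, the contamination bound that justifies
#' treating five-repeat reads as telomeric.
#'
#' @param internal_count internal occurrences (>= 0).
#' @param telomeric_count telomeric occurrences (> 0).
#' @return percentage in `[0, 100)`.
#' @examples
#' its_contamination_percent(109, 5350) # ~2
#' @export
its_contamination_percent <- function(internal_count, telomeric_count) {
  if (!is.numeric(internal_count) || internal_count < 0) {
    stop("'internal_count' must be >= 0")
  }
  if (!is.numeric(telomeric_count) || telomeric_count <= 0) {
    stop("'telomeric_count' must be > 0")
  }
  (internal_count * 100) / (internal_count + telomeric_count)
}
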