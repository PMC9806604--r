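#' Per-sample mapping summary
#'
#' Holds the tallies the enrichment stage normalises by: total reads, reads
#' mapping to the genome, and reads mapping to a unique position (the RMUS
#' numerator). Enforces `0 <= unique <= mapping <= total`.
#'
#' @param sample_id identifier.
#' @param total_reads,mapping_reads counts.
#' @param unique_mapping_reads count, or `NA` when uniqueness evidence is
#'   unavailable.
#' @param source `"internal"` (exact mapper) or `"sam"` (ingested
#'   alignments).
#' @return object of class `mapping_summary`.
#' @export
mapping_summary <- function(sample_id, total_reads, mapping_reads,
                            unique_mapping_reads,
                            source = c("internal", "sam")) {
  source <- match.arg(source)
  total_reads <- as.integer(total_reads)
  mapping_reads <- as.integer(mapping_reads)
  unique_mapping_reads <- as.integer(unique_mapping_reads)
  stopifnot(total_reads >= 0, mapping_reads >= 0,
            mapping_reads <= total_reads)
  if (!is.na(unique_mapping_reads)) {
    stopifnot(unique_mapping_reads >= 0,
              unique_mapping_reads <= mapping_reads)
  }
  structure(list(sample_id = sample_id, total_reads = total_reads,
                 mapping_reads = mapping_reads,
                 unique_mapping_reads = unique_mapping_reads,
                 source = source),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("mapping_summary [%s] %s: total %d, mapping %d, unique %s\n",
              x$source, x$sample_id, x$total_reads, x$mapping_reads,
              ifelse(is.na(x$unique_mapping_reads), "NA",
                     x$unique_mapping_reads)))
  invisible(x)
}

#' Map reads by exact full-length matching against a genome
#'
#' A read maps if its sequence, or its reverse complement, occurs as an
#' exact substring of the genome; it maps uniquely if the total occurrence
#' count across both strands is exactly one. No indels, clipping or
#' mismatches: designed for the error-free synthetic reads, where it makes
#' uniqueness an exact, oracle-checkable quantity. Palindromic reads (equal
#' to their reverse complement) are counted once per genomic occurrence.
#'
#' @param reads `DNAStringSet` or FASTQ path.
#' @param genome `DNAStringSet` or FASTA path.
#' @param sample_id identifier for the summary.
#' @return list with `summary` (a [mapping_summary()]) and `per_read`
#'   (data.frame: `id`, `occurrences`, `mapped`, `unique`).
#' @export
map_reads_exact <- function(reads, genome, sample_id = "sample") {
  reads <- read_reads(reads)
  genome <- read_genome(genome)
  if (!length(genome)) stop("'genome' is empty")
  n <- length(reads)
  if (n == 0L) {
    warning("empty read set: mapping summary is all zeros")
    return(list(summary = mapping_summary(sample_id, 0L, 0L, 0L, "internal"),
                per_read = data.frame(id = character(0),
                                      occurrences = integer(0),
                                      mapped = logical(0),
                                      unique = logical(0))))
  }
  wid <- Biostrings::width(reads)
  has_n <- any(Biostrings::vcountPattern("N", reads, fixed = TRUE) > 0)
  rc <- Biostrings::reverseComplement(reads)
  if (length(unique(wid)) == 1L && !has_n) {
    occ_f <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(reads), genome))
    occ_r <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rc), genome))
  } else {
    count_one <- function(x) {
      sum(vapply(seq_along(genome), function(ci) {
        Biostrings::countPattern(x, genome[[ci]], fixed = TRUE)
      }, integer(1)))
    }
    occ_f <- vapply(seq_len(n), function(i) count_one(reads[[i]]), integer(1))
    occ_r <- vapply(seq_len(n), function(i) count_one(rc[[i]]), integer(1))
  }
  pal <- as.character(reads) == as.character(rc)
  occ <- as.integer(occ_f + ifelse(pal, 0L, occ_r))
  mapped <- occ >= 1L
  ids <- names(reads) %||% as.character(seq_len(n))
  list(summary = mapping_summary(sample_id, n, sum(mapped), sum(occ == 1L),
                                 "internal"),
       per_read = data.frame(id = ids, occurrences = occ, mapped = mapped,
                             unique = occ == 1L))
}

#' Summarise mapping and uniqueness from a SAM/BAM file
#'
#' Counts primary records only: secondary (0x100) and supplementary (0x800)
#' records are never counted as reads. `total_reads` is all primary
#' records, `mapping_reads` the primary non-unmapped (0x4) ones. Uniqueness
#' follows the chosen dialect: `"nh"` takes `NH:i:1` as uniquely mapping and
#' falls back to the MAPQ rule (with a warning) when NH tags are absent;
#' `"mapq"` takes MAPQ >= `mapq_threshold`. The dialect must be explicit
#' because short-read aligners encode "maps once" differently (Bowtie2, for
#' instance, reports one alignment per read with multiplicity folded into
#' MAPQ).
#'
#' @param file path to a SAM or BAM file (SAM is converted in a temporary
#'   directory; a missing header is an error).
#' @param unique_rule `"nh"` or `"mapq"`.
#' @param mapq_threshold MAPQ cutoff for the MAPQ rule (default 10).
#' @param sample_id identifier; defaults to the file name.
#' @return a [mapping_summary()] with `source = "sam"`.
#' @export
ingest_alignments <- function(file, unique_rule = c("nh", "mapq"),
                              mapq_threshold = 10L, sample_id = NULL) {
  unique_rule <- match.arg(unique_rule)
  stopifnot(file.exists(file))
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(file))
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    first <- readLines(file, n = 1L)
    if (!length(first) || !startsWith(first, "@")) {
      stop(sprintf("'%s' has no SAM header", file))
    }
    bam <- tryCatch(
      Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop(sprintf(
        "cannot parse '%s' as SAM (missing or malformed header?): %s",
        file, conditionMessage(e))))
  }
  p <- Rsamtools::ScanBamParam(what = c("flag", "mapq"), tag = "NH")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  if (!length(flag)) {
    return(mapping_summary(sample_id, 0L, 0L, 0L, "sam"))
  }
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  total <- sum(primary)
  mapped_sel <- primary & !unmapped
  mapping <- sum(mapped_sel)
  nh <- b$tag$NH
  use_mapq <- unique_rule == "mapq"
  if (unique_rule == "nh") {
    if (is.null(nh) || anyNA(nh[mapped_sel])) {
      warning(sprintf(
        "NH tags absent or incomplete in '%s'; falling back to MAPQ >= %d rule",
        basename(file), mapq_threshold))
      use_mapq <- TRUE
    }
  }
  uniq <- if (use_mapq) {
    mq <- b$mapq
    sum(mapped_sel & !is.na(mq) & mq >= mapq_threshold)
  } else {
    sum(mapped_sel & nh == 1L)
  }
  mapping_summary(sample_id, total, mapping, uniq, "sam")
}

#' Fraction of mapping reads that map to unique sequences (RMUS)
#'
#' `unique_mapping_reads / mapping_reads`: the proxy for the single-copy vs
#' repetitive origin of a library. Euchromatic-mark IP libraries shift
#' toward single-copy sequence (RMUS above the matched input);
#' heterochromatic-mark libraries shift toward repeats (RMUS below input).
#'
#' @param summary a [mapping_summary()] with `mapping_reads > 0` and known
#'   uniqueness.
#' @return fraction in `[0, 1]`.
#' @export
compute_rmus <- function(summary) {
  stopifnot(inherits(summary, "mapping_summary"))
  if (summary$mapping_reads == 0L) {
    stop(sprintf("RMUS undefined for '%s': no mapping reads",
                 summary$sample_id))
  }
  if (is.na(summary$unique_mapping_reads)) {
    stop(sprintf("RMUS unavailable for '%s': uniqueness was not determined",
                 summary$sample_id))
  }
  summary$unique_mapping_reads / summary$mapping_reads
}
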