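#' @keywords internal
"%||%" <- function(a, b) if (is.null(a)) b else a

#' Validate and normalise a nucleotide string
#'
#' Accepts a length-1 character vector or a [Biostrings::DNAString] and
#' returns the plain uppercase character string. Any character outside the
#' `{A, C, G, T, N}` alphabet is rejected with an error naming the offending
#' character.
#'
#' @param x nucleotide string (character scalar or `DNAString`).
#' @param what label used in error messages.
#' @param allow_empty logical; is the empty string acceptable?
#' @return length-1 character string.
#' @keywords internal
validate_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single nucleotide string", what))
  }
  if (!nzchar(x)) {
    if (allow_empty) return(x)
    stop(sprintf("'%s' must be non-empty", what))
  }
  bad <- regmatches(x, regexpr("[^ACGTN]", x))
  if (length(bad) && nzchar(bad)) {
    stop(sprintf("invalid character '%s' in '%s': only A, C, G, T, N allowed (uppercase)",
                 bad, what))
  }
  x
}

#' Scoped RNG seeding
#'
#' Sets the RNG seed for the duration of the calling function and restores
#' the previous RNG state on exit. A `NULL` seed leaves the RNG untouched.
#' @keywords internal
local_seed_ <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed), .local_envir = envir)
  }
  invisible(seed)
}

#' Derive a stream of child seeds from one master seed
#'
#' Used by the pipeline drivers so that a single `--seed` controls every
#' stochastic stage while the stages remain independently reseedable.
#' All derived seeds fit in a 32-bit integer.
#'
#' @param seed master seed (integer scalar).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' Random nucleotide string at a given GC content
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#' Uses the current RNG state (seed it from the caller).
#'
#' @param n length in bases.
#' @param gc GC fraction in `[0, 1]`.
#' @return character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Read a genome FASTA (or pass through an in-memory genome)
#' @param genome `DNAStringSet` or path to a FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  stop("'genome' must be a DNAStringSet or the path to a FASTA file")
}

#' Read sequencing reads from FASTQ (or pass through)
#' @param reads `DNAStringSet` or path to a FASTQ file (4-line records,
#'   Phred+33 qualities accepted and ignored).
#' @return named `DNAStringSet`.
#' @export
read_reads <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(Biostrings::readDNAStringSet(reads, format = "fastq",
                                        with.qualities = FALSE))
  }
  stop("'reads' must be a DNAStringSet or the path to a FASTQ file")
}

#' Write reads to FASTQ with a constant quality string
#' @param reads named `DNAStringSet`.
#' @param path output file.
#' @param quality_char single quality character applied to every base
#'   (default "I", Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  quals <- Biostrings::BStringSet(strrep(quality_char, Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
#' @param p numeric vector of p-values (NA allowed).
#' @return character vector of "", "*", "**" or "***".
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}
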