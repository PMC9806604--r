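# Independent oracles: plain-character all-offset scans, no Biostrings.

# positions (1-based) of exact occurrences of `pattern` in `subject`,
# overlaps allowed; vectorised candidate filtering over every offset
oracle_positions <- function(subject, pattern) {
  s <- strsplit(subject, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  m <- length(p); n <- length(s)
  if (n < m || m == 0L) return(integer(0))
  cand <- which(s[seq_len(n - m + 1L)] == p[1L])
  j <- 2L
  while (j <= m && length(cand)) {
    cand <- cand[s[cand + j - 1L] == p[j]]
    j <- j + 1L
  }
  cand
}

oracle_count <- function(subject, pattern) length(oracle_positions(subject, pattern))

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# total occurrences of a read across both strands of a genome given as a
# named character vector of chromosome strings
oracle_genome_occurrences <- function(read, genome_strings) {
  rc <- oracle_revcomp(read)
  fwd <- sum(vapply(genome_strings, oracle_count, integer(1), pattern = read))
  if (rc == read) return(fwd)
  fwd + sum(vapply(genome_strings, oracle_count, integer(1), pattern = rc))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# small, quick genome spec for unit tests
tiny_spec <- function(seed = 1L, ...) {
  args <- list(n_chromosomes = 2L, chromosome_length_bp = 30000L,
               telomere_length_bp = 700L, its_count = 2L,
               satellite_block_count = 1L, satellite_repeats_per_block = 8L,
               min_feature_gap_bp = 150L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(genome_spec, args)
}
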