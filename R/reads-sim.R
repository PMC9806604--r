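#' Relative IP sampling weights per genomic compartment
#'
#' A mark profile assigns a non-negative relative immunoprecipitation weight
#' to each truth label. The input sample is always sampled uniformly
#' (weight 1 everywhere), so the recoverable parameter of the simulation is
#' exactly the enrichment ratio the pipeline estimates: a compartment with
#' weight `lambda` has expected IP/input frequency ratio close to `lambda`
#' (attenuated slightly by the renormalisation over total reads). With all
#' weights equal the IP and input samples are statistically identical (the
#' null profile).
#'
#' @param telomere,its,satellite,background non-negative weights.
#' @return named numeric of class `mark_profile`.
#' @examples
#' mark_profile()                  # null profile
#' mark_profile(satellite = 4)    # heterochromatic-like mark
#' @export
mark_profile <- function(telomere = 1, its = 1, satellite = 1,
                         background = 1) {
  p <- c(telomere = telomere, ITS = its, satellite = satellite,
         background = background)
  if (any(p < 0) || anyNA(p)) stop("mark-profile weights must be non-negative")
  if (all(p == 0)) stop("at least one mark-profile weight must be positive")
  structure(p, class = "mark_profile")
}

#' Simulate an input or IP read sample from a synthetic genome
#'
#' Read start positions are drawn with probability proportional to the mark
#' weight of the truth interval containing the start (uniform for
#' `role = "input"`), uniformly within the interval; each read comes from
#' either strand with probability 1/2 and is reverse-complemented
#' accordingly (which is how C-strand telomeric reads arise from the
#' right-end G-array and vice versa). Reads are single-end, uniform length
#' and error-free; read names encode the true origin
#' (`id|chrom|start0|strand|label`) for oracle checks via [read_origin()].
#'
#' @param genome named `DNAStringSet` from [build_genome()].
#' @param truth matching `genome_truth`.
#' @param profile [mark_profile()]; ignored for `role = "input"`.
#' @param role `"input"` or `"IP"`.
#' @param n_reads number of reads (>= 1).
#' @param read_length_bp read length; must not exceed the shortest
#'   chromosome.
#' @param seed RNG seed.
#' @return named `DNAStringSet` of reads, with attributes `role` and `seed`.
#' @export
simulate_sample <- function(genome, truth, profile = mark_profile(),
                            role = c("input", "IP"), n_reads,
                            read_length_bp = 100L, seed = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(truth, "genome_truth"), n_reads >= 1,
            read_length_bp >= 1)
  if (role == "IP") stopifnot(inherits(profile, "mark_profile"))
  chrlen <- setNames(Biostrings::width(genome), names(genome))
  if (read_length_bp > min(chrlen)) {
    stop("read_length_bp exceeds the shortest chromosome")
  }
  local_seed_(seed)
  iv <- truth$intervals
  ivc <- as.character(GenomicRanges::seqnames(iv))
  lo <- GenomicRanges::start(iv)
  hi <- pmin(GenomicRanges::end(iv), chrlen[ivc] - read_length_bp + 1L)
  vw <- pmax(0L, hi - lo + 1L)
  lam <- if (role == "input") rep(1, length(iv)) else
    unname(unclass(profile)[iv$label])
  if (anyNA(lam)) stop("profile lacks a weight for some truth label")
  w <- lam * vw
  if (sum(w) <= 0) stop("no interval has positive sampling weight")

  idx <- sample.int(length(iv), n_reads, replace = TRUE, prob = w)
  pos <- lo[idx] + as.integer(floor(stats::runif(n_reads) * vw[idx]))
  minus <- stats::runif(n_reads) < 0.5
  chrom <- ivc[idx]

  reads <- vector("list", length(genome))
  ord <- integer(0)
  for (ci in seq_along(genome)) {
    nm <- names(genome)[ci]
    sel <- which(chrom == nm)
    if (!length(sel)) next
    reads[[ci]] <- Biostrings::extractAt(
      genome[[nm]], IRanges::IRanges(pos[sel], width = read_length_bp))
    ord <- c(ord, sel)
  }
  out <- Biostrings::DNAStringSet(do.call(c, reads[!vapply(reads, is.null, logical(1))]))
  out <- out[order(ord)]
  if (any(minus)) {
    out[minus] <- Biostrings::reverseComplement(out[minus])
  }
  names(out) <- sprintf("%s_%07d|%s|%d|%s|%s", tolower(role),
                        seq_len(n_reads), chrom, pos - 1L,
                        ifelse(minus, "-", "+"), iv$label[idx])
  attr(out, "role") <- role
  attr(out, "seed") <- seed
  out
}

#' Parse true read origins from simulated read names
#'
#' @param reads named `DNAStringSet` from [simulate_sample()], or a
#'   character vector of such read names.
#' @return data.frame with columns `id`, `chrom`, `start0` (0-based),
#'   `strand`, `label`.
#' @export
read_origin <- function(reads) {
  nm <- if (is.character(reads)) reads else names(reads)
  parts <- strsplit(nm, "|", fixed = TRUE)
  if (any(lengths(parts) != 5L)) {
    stop("read names do not carry simulation origin fields")
  }
  m <- do.call(rbind, parts)
  data.frame(id = m[, 1], chrom = m[, 2], start0 = as.integer(m[, 3]),
             strand = m[, 4], label = m[, 5])
}
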