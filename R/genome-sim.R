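#' Specification of a synthetic genome with telomere/ITS/satellite architecture
#'
#' Describes the architecture the generator emulates: each chromosome starts
#' with a C-strand telomeric array (`CCCTAAA` repeats), ends with a G-strand
#' array (`TTTAGGG` repeats), and carries, embedded in single-copy
#' background, interstitial telomeric sequences (short perfect stretches
#' interspersed with degenerate ones) and blocks of tandem 178-bp satellite
#' monomers containing the Cen1/Cen2 motifs.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp length of each chromosome (bp).
#' @param telomere_length_bp terminal array length per end (bp, >= 35 so each
#'   array holds at least one overlapping 35-bp motif; default 3750, the
#'   Arabidopsis Col-0 estimate).
#' @param its_count number of ITS loci in the genome.
#' @param its_stretches_per_its perfect stretches per ITS (degenerate
#'   stretches sit between them).
#' @param its_mean_perfect_stretch_repeats mean repeats per perfect stretch
#'   (geometric, >= 1). The default of 1.5 mirrors real ITSs, whose perfect
#'   stretches are mostly one or two repeats: perfect runs of five or more
#'   repeats stay rare, so only a couple of percent of telomere-classified
#'   reads originate from ITSs -- the regime the classification scheme is
#'   built for.
#' @param its_degeneracy_rate per-base substitution probability within
#'   degenerate stretches.
#' @param satellite_block_count number of tandem satellite blocks.
#' @param satellite_repeats_per_block 178-bp monomers per block.
#' @param gc_background GC fraction of the single-copy background.
#' @param min_feature_gap_bp minimum single-copy gap separating repeat
#'   features from each other and from telomeres (keeps terminal arrays
#'   maximal and feature boundaries unambiguous).
#' @param seed RNG seed making the genome reproducible.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L,
                        chromosome_length_bp = 200000L,
                        telomere_length_bp = 3750L,
                        its_count = 6L,
                        its_stretches_per_its = 5L,
                        its_mean_perfect_stretch_repeats = 1.5,
                        its_degeneracy_rate = 0.1,
                        satellite_block_count = 4L,
                        satellite_repeats_per_block = 50L,
                        gc_background = 0.36,
                        min_feature_gap_bp = 200L,
                        seed = 1L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chromosome_length_bp = as.integer(chromosome_length_bp),
               telomere_length_bp = as.integer(telomere_length_bp),
               its_count = as.integer(its_count),
               its_stretches_per_its = as.integer(its_stretches_per_its),
               its_mean_perfect_stretch_repeats = its_mean_perfect_stretch_repeats,
               its_degeneracy_rate = its_degeneracy_rate,
               satellite_block_count = as.integer(satellite_block_count),
               satellite_repeats_per_block = as.integer(satellite_repeats_per_block),
               gc_background = gc_background,
               min_feature_gap_bp = as.integer(min_feature_gap_bp),
               seed = as.integer(seed))
  stopifnot(spec$n_chromosomes >= 1L,
            spec$telomere_length_bp >= 35L,
            spec$its_count >= 0L, spec$its_stretches_per_its >= 1L,
            spec$its_mean_perfect_stretch_repeats >= 1,
            spec$its_degeneracy_rate >= 0, spec$its_degeneracy_rate <= 1,
            spec$satellite_block_count >= 0L,
            spec$satellite_repeats_per_block >= 1L,
            spec$gc_background >= 0, spec$gc_background <= 1,
            spec$min_feature_gap_bp >= 0L)
  if (2L * spec$telomere_length_bp >= spec$chromosome_length_bp) {
    stop("chromosome_length_bp must exceed twice telomere_length_bp")
  }
  structure(spec, class = "genome_spec")
}

# one fixed 178-bp monomer is used everywhere: only the embedded Cen1/Cen2
# motifs matter to the pipeline, and a shared monomer makes satellite blocks
# genuinely repetitive genome-wide (as real centromeric satellite is)
satellite_env <- new.env(parent = emptyenv())

#' The fixed 178-bp satellite monomer
#'
#' A seeded random 178-bp sequence carrying the Cen1 motif at 0-based offset
#' 20 and the Cen2 motif at offset 100, each exactly once. Identical across
#' all genomes built by this package.
#'
#' @return character string of length 178.
#' @export
satellite_monomer <- function() {
  if (!is.null(satellite_env$monomer)) return(satellite_env$monomer)
  cls <- default_motif_classes()
  base <- withr::with_seed(178L, random_dna(178L, gc = 0.36))
  substr(base, 21L, 43L) <- cls[["CEN1"]]
  substr(base, 101L, 123L) <- cls[["CEN2"]]
  # the monomer must contain each motif exactly once, also across tandem
  # junctions; the fixed seed satisfies this (asserted here defensively)
  tandem <- strrep(base, 3L)
  stopifnot(count_overlapping(tandem, cls[["CEN1"]]) == 3L,
            count_overlapping(tandem, cls[["CEN2"]]) == 3L,
            count_overlapping(tandem, cls[["TEL_C"]]) == 0L,
            count_overlapping(tandem, cls[["TEL_G"]]) == 0L)
  satellite_env$monomer <- base
  base
}

# an ITS: perfect CCCTAAA stretches (geometric repeat counts) alternating
# with degenerate stretches in which each base mutates with prob `rate`
make_its <- function(spec) {
  m <- spec$its_mean_perfect_stretch_repeats
  k_perf <- spec$its_stretches_per_its
  draw_reps <- function() 1L + stats::rgeom(1L, prob = 1 / m)
  pieces <- character(0)
  for (i in seq_len(k_perf)) {
    pieces <- c(pieces, strrep("CCCTAAA", draw_reps()))
    if (i < k_perf) {
      deg <- strsplit(strrep("CCCTAAA", draw_reps()), "")[[1]]
      hit <- stats::runif(length(deg)) < spec$its_degeneracy_rate
      if (any(hit)) {
        deg[hit] <- vapply(deg[hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
      pieces <- c(pieces, paste(deg, collapse = ""))
    }
  }
  paste(pieces, collapse = "")
}

#' Build a synthetic genome with ground-truth annotation
#'
#' Assembles chromosomes deterministically from `spec$seed`: a C-strand
#' telomeric array on the left end, a G-strand array on the right end, ITSs
#' and tandem satellite blocks at random interior positions separated by at
#' least `min_feature_gap_bp` of single-copy background, and i.i.d.
#' background elsewhere. Telomere tracts whose length is not a multiple of
#' 7 end (left) or start (right) with a partial repeat so that the terminal
#' base pattern is exact.
#'
#' The returned truth records, for every interval, the number of overlapping
#' occurrences of each default motif class whose start falls in the interval
#' (computed by a full-chromosome scan at build time, so truth and sequence
#' are self-consistent by construction and re-scannable by tests).
#'
#' @param spec a [genome_spec()].
#' @return list with elements `genome` (named `DNAStringSet`) and `truth`
#'   (object of class `genome_truth`: `$intervals` is a `GRanges` covering
#'   each chromosome exactly, with `label` in
#'   telomere/ITS/satellite/background and one occurrence-count column per
#'   motif class; `$spec` echoes the input).
#' @examples
#' gs <- genome_spec(n_chromosomes = 1, chromosome_length_bp = 20000,
#'                   telomere_length_bp = 700, its_count = 1,
#'                   satellite_block_count = 1,
#'                   satellite_repeats_per_block = 5, seed = 7)
#' g <- build_genome(gs)
#' table(g$truth$intervals$label)
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  local_seed_(spec$seed)
  classes <- default_motif_classes()
  mono <- satellite_monomer()
  telL <- spec$telomere_length_bp

  # left telomere: starts at base 1 on a repeat boundary, may end mid-repeat;
  # right telomere: ends at the terminus, may start mid-repeat
  tel_left <- substr(strrep("CCCTAAA", ceiling(telL / 7) + 1L), 1L, telL)
  tg <- strrep("TTTAGGG", ceiling(telL / 7) + 1L)
  tel_right <- substr(tg, nchar(tg) - telL + 1L, nchar(tg))

  feats <- c(
    replicate(spec$its_count, list(label = "ITS", seq = make_its(spec)),
              simplify = FALSE),
    replicate(spec$satellite_block_count,
              list(label = "satellite",
                   seq = strrep(mono, spec$satellite_repeats_per_block)),
              simplify = FALSE))
  chrom_of <- if (length(feats)) {
    sample(rep_len(seq_len(spec$n_chromosomes), length(feats)))
  } else integer(0)

  seqs <- character(spec$n_chromosomes)
  iv_chrom <- character(0); iv_start <- integer(0); iv_end <- integer(0)
  iv_label <- character(0)
  for (ci in seq_len(spec$n_chromosomes)) {
    nm <- paste0("chr", ci)
    f <- feats[chrom_of == ci]
    if (length(f) > 1L) f <- f[sample(length(f))]
    flen <- vapply(f, function(x) nchar(x$seq), integer(1))
    interior <- spec$chromosome_length_bp - 2L * telL
    k <- length(f)
    spare <- interior - sum(flen) - (k + 1L) * spec$min_feature_gap_bp
    if (spare < 0L) {
      stop(sprintf("infeasible packing on %s: features + gaps exceed the interior by %d bp",
                   nm, -spare))
    }
    if (k > 0L) {
      cuts <- sort(stats::runif(k))
      add <- floor(diff(c(0, cuts, 1)) * spare)
      add[k + 1L] <- spare - sum(add[seq_len(k)])
    } else {
      add <- spare
    }
    gaps <- spec$min_feature_gap_bp + add

    pieces <- character(2L * k + 3L)
    labels <- character(2L * k + 3L)
    pieces[1L] <- tel_left; labels[1L] <- "telomere"
    pos <- 2L
    for (j in seq_len(k)) {
      pieces[pos] <- random_dna(gaps[j], spec$gc_background)
      labels[pos] <- "background"
      pieces[pos + 1L] <- f[[j]]$seq
      labels[pos + 1L] <- f[[j]]$label
      pos <- pos + 2L
    }
    pieces[pos] <- random_dna(gaps[k + 1L], spec$gc_background)
    labels[pos] <- "background"
    pieces[pos + 1L] <- tel_right; labels[pos + 1L] <- "telomere"

    keep <- nchar(pieces) > 0L
    pieces <- pieces[keep]; labels <- labels[keep]
    w <- nchar(pieces)
    ends <- cumsum(w)
    starts <- ends - w + 1L
    seqs[ci] <- paste(pieces, collapse = "")
    stopifnot(nchar(seqs[ci]) == spec$chromosome_length_bp)
    iv_chrom <- c(iv_chrom, rep(nm, length(pieces)))
    iv_start <- c(iv_start, starts); iv_end <- c(iv_end, ends)
    iv_label <- c(iv_label, labels)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(spec$n_chromosomes))

  iv <- GenomicRanges::GRanges(iv_chrom,
                               IRanges::IRanges(iv_start, iv_end),
                               label = iv_label)
  counts <- matrix(0L, nrow = length(iv), ncol = length(classes),
                   dimnames = list(NULL, paste0("n_", names(classes))))
  for (ki in seq_along(classes)) {
    for (nm in names(genome)) {
      starts <- BiocGenerics::start(
        Biostrings::matchPattern(Biostrings::DNAString(classes[[ki]]),
                                 genome[[nm]], fixed = TRUE))
      if (!length(starts)) next
      sel <- which(as.character(GenomicRanges::seqnames(iv)) == nm)
      hit_iv <- sel[findInterval(starts, GenomicRanges::start(iv)[sel])]
      tab <- table(hit_iv)
      counts[as.integer(names(tab)), ki] <-
        counts[as.integer(names(tab)), ki] + as.integer(tab)
    }
  }
  S4Vectors::mcols(iv) <- cbind(S4Vectors::mcols(iv),
                                S4Vectors::DataFrame(counts))
  truth <- structure(list(intervals = iv, spec = spec,
                          classes = classes),
                     class = "genome_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("genome_truth: %d chromosomes, %d intervals\n",
              x$spec$n_chromosomes, length(x$intervals)))
  print(table(x$intervals$label))
  invisible(x)
}

#' Extract the truth telomere mask (terminal arrays) from a genome truth
#' @param truth `genome_truth` object.
#' @return `GRanges` of telomere intervals.
#' @export
truth_telomere_mask <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  truth$intervals[truth$intervals$label == "telomere"]
}

#' Write a synthetic genome truth to BED + JSON
#'
#' The BED file carries the interval labels (0-based half-open, as BED
#' requires); the JSON carries the full truth: spec, motif classes and
#' per-interval occurrence counts (intervals serialised 0-based half-open).
#'
#' @param truth `genome_truth`.
#' @param bed_path,json_path output paths.
#' @return invisibly, the two paths.
#' @export
write_truth <- function(truth, bed_path, json_path) {
  stopifnot(inherits(truth, "genome_truth"))
  iv <- truth$intervals
  bed <- iv
  S4Vectors::mcols(bed) <- S4Vectors::DataFrame(name = iv$label)
  rtracklayer::export(bed, bed_path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(iv)),
                   start0 = GenomicRanges::start(iv) - 1L,
                   end = GenomicRanges::end(iv),
                   label = iv$label,
                   as.data.frame(S4Vectors::mcols(iv)[-1]),
                   check.names = FALSE)
  jsonlite::write_json(list(spec = unclass(truth$spec),
                            classes = as.list(truth$classes),
                            intervals = df),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = bed_path, json = json_path))
}

#' Read a genome truth back from its JSON serialisation
#' @param json_path path written by [write_truth()].
#' @return `genome_truth` object.
#' @export
read_truth <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  iv <- GenomicRanges::GRanges(x$intervals$chrom,
                               IRanges::IRanges(x$intervals$start0 + 1L,
                                                x$intervals$end))
  extra <- x$intervals[setdiff(names(x$intervals),
                               c("chrom", "start0", "end"))]
  S4Vectors::mcols(iv) <- S4Vectors::DataFrame(extra, check.names = FALSE)
  spec <- do.call(genome_spec, x$spec[setdiff(names(x$spec), character(0))])
  structure(list(intervals = iv, spec = spec,
                 classes = unlist(x$classes)),
            class = "genome_truth")
}
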