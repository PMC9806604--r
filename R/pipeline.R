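#' Configuration for a simulated multi-study ChIP-seq cohort
#'
#' Describes the study conditions of a synthetic cohort: one shared genome,
#' a set of marks (each a [mark_profile()]), and for every mark a number of
#' replicate studies, each contributing one input and one IP sample.
#'
#' @param genome a [genome_spec()].
#' @param marks named list of [mark_profile()] objects. The defaults pair a
#'   euchromatic-like mark that favours single-copy background with a
#'   heterochromatic-like mark that favours the repeat compartments.
#' @param n_studies replicate studies per mark (>= 1).
#' @param n_reads reads per sample.
#' @param read_length_bp read length.
#' @return object of class `simulate_config`.
#' @export
simulate_config <- function(genome = genome_spec(),
                            marks = list(
                              euchromatic_like = mark_profile(background = 3),
                              heterochromatic_like = mark_profile(its = 3,
                                                                  satellite = 3)),
                            n_studies = 4L, n_reads = 50000L,
                            read_length_bp = 100L) {
  stopifnot(inherits(genome, "genome_spec"),
            is.list(marks), length(marks) >= 1L, !is.null(names(marks)),
            all(vapply(marks, inherits, logical(1), "mark_profile")))
  n_studies <- as.integer(n_studies)
  if (n_studies < 1L) stop("n_studies must be at least 1")
  structure(list(genome = genome, marks = marks, n_studies = n_studies,
                 n_reads = as.integer(n_reads),
                 read_length_bp = as.integer(read_length_bp)),
            class = "simulate_config")
}

#' Simulate a full cohort to disk
#'
#' Writes the genome (FASTA, 70-column wrap), the truth annotation (BED +
#' JSON) and one input + one IP FASTQ per study and mark, then a
#' `manifest.json` listing every file with its MD5 checksum, the seeds used
#' and the sample metadata. Identical configuration and seed reproduce
#' byte-identical outputs.
#'
#' @param out_dir output directory (must be empty unless `force = TRUE`).
#' @param config a [simulate_config()].
#' @param seed master seed; the genome seed and one seed per sample are
#'   derived from it.
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest as a list.
#' @export
run_simulate <- function(out_dir, config = simulate_config(), seed = 1L,
                         force = FALSE) {
  stopifnot(inherits(config, "simulate_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)",
                 out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n_samples <- length(config$marks) * config$n_studies * 2L
  seeds <- derive_seeds(seed, 1L + n_samples)
  spec <- config$genome
  spec$seed <- seeds[1L]
  built <- build_genome(spec)
  fa <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(built$genome, fa, width = 70L)
  tr <- write_truth(built$truth, file.path(out_dir, "truth.bed"),
                    file.path(out_dir, "truth.json"))

  samples <- list(); si <- 1L
  for (mk in names(config$marks)) {
    for (st in seq_len(config$n_studies)) {
      study_id <- sprintf("%s_study%02d", mk, st)
      for (role in c("input", "IP")) {
        s <- seeds[1L + si]
        reads <- simulate_sample(built$genome, built$truth,
                                 profile = config$marks[[mk]],
                                 role = role, n_reads = config$n_reads,
                                 read_length_bp = config$read_length_bp,
                                 seed = s)
        f <- file.path(out_dir, sprintf("%s_%s.fastq", study_id, role))
        write_fastq(reads, f)
        samples[[si]] <- list(file = basename(f), study_id = study_id,
                              mark = mk, role = role, seed = s)
        si <- si + 1L
      }
    }
  }
  files <- c("genome.fasta", "truth.bed", "truth.json",
             vapply(samples, `[[`, character(1), "file"))
  manifest <- list(
    tool = "telomark", version = as.character(packageVersion("telomark")),
    seed = seed, genome_seed = seeds[1L],
    config = list(genome = unclass(config$genome),
                  marks = lapply(config$marks, function(p) as.list(unclass(p))),
                  n_studies = config$n_studies, n_reads = config$n_reads,
                  read_length_bp = config$read_length_bp),
    genome = "genome.fasta", truth_bed = "truth.bed",
    truth_json = "truth.json", samples = samples,
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Count every sample of a simulated cohort
#'
#' Reads the cohort manifest, counts motif-class reads per sample with
#' [count_sample()] and writes one TSV row per sample. `mapper = "exact"`
#' runs the internal exact mapper (supplying uniqueness and hence RMUS);
#' `mapper = "none"` declares every read as mapping, which is exact for the
#' error-free simulated reads and much faster when RMUS is not needed.
#'
#' @param sim_dir directory written by [run_simulate()].
#' @param out_file output TSV (default `counts.tsv` inside `sim_dir`).
#' @param mapper `"exact"` or `"none"`.
#' @param classes motif classes to count.
#' @param count_unmapped classify unmapped reads too (exact mapper only).
#' @return the counts data.frame, invisibly.
#' @export
run_count <- function(sim_dir, out_file = file.path(sim_dir, "counts.tsv"),
                      mapper = c("exact", "none"),
                      classes = default_motif_classes(),
                      count_unmapped = FALSE) {
  mapper <- match.arg(mapper)
  mf <- file.path(sim_dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("missing manifest: %s", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  fa <- file.path(sim_dir, manifest$genome)
  if (!file.exists(fa)) stop(sprintf("missing genome FASTA: %s", fa))
  genome <- if (mapper == "exact") read_genome(fa) else NULL
  cl <- lapply(manifest$samples, function(s) {
    f <- file.path(sim_dir, s$file)
    if (!file.exists(f)) stop(sprintf("missing FASTQ: %s", f))
    count_sample(f, genome = genome, study_id = s$study_id, mark = s$mark,
                 role = s$role, classes = classes, mapper = mapper,
                 count_unmapped = count_unmapped)
  })
  counts <- counts_table(cl)
  write_counts(counts, out_file)
  invisible(counts)
}

#' Enrichment and pooled-statistics stage
#'
#' Builds the per-study enrichment table, the pooled significance table
#' (each class vs genome and combined telomere vs satellite, per mark) and,
#' when RMUS values are available, the pooled input-vs-IP RMUS table.
#' Tables are written as TSV under `out_dir`.
#'
#' @param counts counts data.frame or path to a counts TSV.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @param scale,pseudocount,alpha_normality statistical options (see
#'   [pool_and_test()] and [enrichment_table()]).
#' @param paired_rmus pair RMUS values by study order.
#' @return list with `enrichment`, `pooled` and (possibly `NULL`) `rmus`
#'   data.frames.
#' @export
run_enrich <- function(counts, out_dir = NULL, scale = "log2",
                       pseudocount = FALSE, alpha_normality = 0.05,
                       paired_rmus = FALSE) {
  if (is.character(counts)) counts <- read_counts(counts)
  enr <- enrichment_table(counts, pseudocount = pseudocount)
  pooled <- pooled_table(enr, alpha_normality = alpha_normality,
                         scale = scale)
  rmus <- NULL
  if (any(!is.na(counts$rmus))) {
    rmus <- tryCatch(rmus_table(counts, paired = paired_rmus,
                                alpha_normality = alpha_normality),
                     error = function(e) { warning(conditionMessage(e)); NULL })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pooled, file.path(out_dir, "pooled.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(rmus)) {
      write.table(rmus, file.path(out_dir, "rmus.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  list(enrichment = enr, pooled = pooled, rmus = rmus)
}
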