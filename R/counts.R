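#' Per-sample tally of mapping and motif-class reads
#'
#' @param study_id study identifier (samples pair by study + mark).
#' @param mark histone-modification label (e.g. "H3K9me2").
#' @param role `"input"` or `"IP"`.
#' @param mapping a [mapping_summary()].
#' @param class_reads named integer vector, reads per motif class; each
#'   value must not exceed `mapping$mapping_reads`.
#' @return object of class `sample_counts`.
#' @export
sample_counts <- function(study_id, mark, role = c("input", "IP"),
                          mapping, class_reads) {
  role <- match.arg(role)
  stopifnot(inherits(mapping, "mapping_summary"),
            is.numeric(class_reads), !is.null(names(class_reads)))
  class_reads <- setNames(as.integer(class_reads), names(class_reads))
  if (any(class_reads > mapping$mapping_reads)) {
    stop("class read counts exceed the number of mapping reads")
  }
  structure(list(study_id = study_id, mark = mark, role = role,
                 mapping = mapping, class_reads = class_reads),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("sample_counts %s/%s [%s]: %d mapping reads; %s\n",
              x$study_id, x$mark, x$role, x$mapping$mapping_reads,
              paste(names(x$class_reads), x$class_reads, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Count motif-class reads in one sequencing sample
#'
#' Maps the reads (or accepts them as mapping) and tallies, among mapping
#' reads, how many contain each motif class. By default only mapping reads
#' are classified; `count_unmapped = TRUE` adds unmapped reads to the class
#' tallies, for reference genomes whose telomeres are incompletely
#' assembled. Reads matching several classes are counted in every class
#' they match (co-occurrence is rare and triggers a warning).
#'
#' @param reads `DNAStringSet` or FASTQ path.
#' @param genome `DNAStringSet` or FASTA path; required for
#'   `mapper = "exact"`.
#' @param study_id,mark,role passed to [sample_counts()].
#' @param classes named motif vector (default [default_motif_classes()]).
#' @param mapper `"exact"` runs [map_reads_exact()]; `"none"` declares every
#'   read as mapping (appropriate for error-free simulated reads, which are
#'   exact genome substrings by construction) and leaves uniqueness `NA`.
#' @param count_unmapped also classify unmapped reads (default off).
#' @param sample_id identifier for the mapping summary.
#' @return a [sample_counts()] object.
#' @export
count_sample <- function(reads, genome = NULL, study_id, mark,
                         role = c("input", "IP"),
                         classes = default_motif_classes(),
                         mapper = c("exact", "none"),
                         count_unmapped = FALSE, sample_id = NULL) {
  role <- match.arg(role)
  mapper <- match.arg(mapper)
  reads <- read_reads(reads)
  sample_id <- sample_id %||% sprintf("%s_%s_%s", study_id, mark, role)
  if (mapper == "exact") {
    if (is.null(genome)) stop("mapper = 'exact' requires a genome")
    mr <- map_reads_exact(reads, genome, sample_id = sample_id)
    summ <- mr$summary
    keep <- if (count_unmapped) rep(TRUE, length(reads)) else mr$per_read$mapped
  } else {
    summ <- mapping_summary(sample_id, length(reads), length(reads),
                            NA_integer_, "internal")
    keep <- rep(TRUE, length(reads))
  }
  if (!any(keep)) {
    warning(sprintf("sample '%s' has no reads to classify", sample_id))
    return(sample_counts(study_id, mark, role, summ,
                         setNames(integer(length(classes)), names(classes))))
  }
  hits <- classify_reads(reads[keep], classes)
  multi <- sum(rowSums(hits) > 1L)
  if (multi > 0L) {
    warning(sprintf("%d read(s) in '%s' matched multiple motif classes",
                    multi, sample_id))
  }
  sample_counts(study_id, mark, role, summ, colSums(hits))
}

#' Flatten sample_counts objects into one table row per sample
#'
#' @param counts_list list of [sample_counts()] objects.
#' @return data.frame with columns `study_id`, `mark`, `role`,
#'   `total_reads`, `mapping_reads`, `unique_mapping_reads`, `rmus`, then
#'   one column per motif class.
#' @export
counts_table <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L,
            all(vapply(counts_list, inherits, logical(1), "sample_counts")))
  rows <- lapply(counts_list, function(x) {
    rmus <- if (x$mapping$mapping_reads > 0L &&
                !is.na(x$mapping$unique_mapping_reads)) {
      compute_rmus(x$mapping)
    } else NA_real_
    cbind(data.frame(study_id = x$study_id, mark = x$mark, role = x$role,
                     total_reads = x$mapping$total_reads,
                     mapping_reads = x$mapping$mapping_reads,
                     unique_mapping_reads = x$mapping$unique_mapping_reads,
                     rmus = rmus),
          as.data.frame(as.list(x$class_reads)))
  })
  do.call(rbind, rows)
}

#' Write / read the per-sample counts table (TSV)
#' @param counts data.frame from [counts_table()].
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
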