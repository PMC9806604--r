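#' Frequency of a motif class within a sample
#'
#' The number of reads of the class divided by the total number of mapping
#' reads.
#'
#' @param counts a [sample_counts()] with `mapping_reads > 0`.
#' @param class_name motif class name present in `counts$class_reads`.
#' @param pseudocount add 0.5 to the class read count (used by the
#'   enrichment functions when enabled there).
#' @return frequency in `[0, 1]`.
#' @export
class_frequency <- function(counts, class_name, pseudocount = FALSE) {
  stopifnot(inherits(counts, "sample_counts"))
  if (!class_name %in% names(counts$class_reads)) {
    stop(sprintf("unknown motif class '%s'", class_name))
  }
  m <- counts$mapping$mapping_reads
  if (m == 0L) {
    stop(sprintf("frequency undefined for '%s': no mapping reads",
                 counts$mapping$sample_id))
  }
  k <- counts$class_reads[[class_name]] + if (pseudocount) 0.5 else 0
  k / m
}

#' Enrichment of a motif class relative to the whole genome
#'
#' The IP frequency of the class divided by the matched input frequency.
#' Both samples must belong to the same study and mark. A zero input (or
#' IP) class count leaves the ratio undefined; with `pseudocount = TRUE`
#' 0.5 reads are added to both class numerators instead.
#'
#' @param ip,input [sample_counts()] for the IP and input samples.
#' @param class_name motif class.
#' @param pseudocount logical.
#' @return positive enrichment ratio.
#' @export
enrichment_vs_genome <- function(ip, input, class_name,
                                 pseudocount = FALSE) {
  stopifnot(inherits(ip, "sample_counts"), inherits(input, "sample_counts"))
  if (ip$study_id != input$study_id || ip$mark != input$mark) {
    stop("IP and input samples must come from the same study and mark")
  }
  f_ip <- class_frequency(ip, class_name, pseudocount)
  f_in <- class_frequency(input, class_name, pseudocount)
  if (f_in == 0 || f_ip == 0) {
    stop(sprintf(
      "enrichment undefined for study '%s', class '%s': zero %s frequency (enable pseudocount to proceed)",
      ip$study_id, class_name, if (f_in == 0) "input" else "IP"))
  }
  f_ip / f_in
}

#' Telomere enrichment relative to the satellite repeats
#'
#' Divides the telomeric enrichment-vs-genome value by the satellite
#' (178-bp repeat) value, giving the enrichment of the mark at telomeres
#' with the heterochromatic satellite as reference.
#'
#' @param e_tel,e_sat positive enrichment-vs-genome ratios.
#' @return ratio `e_tel / e_sat`.
#' @export
enrichment_tel_vs_sat <- function(e_tel, e_sat) {
  if (!is.numeric(e_tel) || !is.numeric(e_sat) || anyNA(c(e_tel, e_sat)) ||
      any(c(e_tel, e_sat) <= 0)) {
    stop("both enrichment components must be defined and positive")
  }
  e_tel / e_sat
}

# combined class counts (e.g. TEL = TEL_C + TEL_G) from a counts-table row
.combined_freq <- function(row, cls, pseudocount) {
  (sum(as.numeric(row[cls])) + if (pseudocount) 0.5 else 0) /
    row$mapping_reads
}

#' Per-study enrichment table from a counts table
#'
#' Pairs the input and IP rows of every (study, mark), computes per-class
#' frequencies and enrichment-vs-genome ratios, and attaches the per-study
#' telomere-vs-satellite ratio computed from the combined telomeric
#' (`TEL_C + TEL_G`) and combined satellite (`CEN1 + CEN2`) read counts.
#' Undefined ratios (zero counts without pseudocount) are reported as `NA`
#' with a warning, never as silent zeros.
#'
#' @param counts data.frame from [counts_table()] / [read_counts()].
#' @param classes motif class names (columns of `counts`).
#' @param tel_classes,sat_classes class names combined for the
#'   telomere-vs-satellite ratio.
#' @param pseudocount logical; add 0.5 reads to class numerators.
#' @return data.frame with columns `study_id`, `mark`, `class`, `f_input`,
#'   `f_ip`, `E_genome`, `E_tel_vs_sat` (the last constant within a study
#'   and mark).
#' @export
enrichment_table <- function(counts,
                             classes = names(default_motif_classes()),
                             tel_classes = c("TEL_C", "TEL_G"),
                             sat_classes = c("CEN1", "CEN2"),
                             pseudocount = FALSE) {
  stopifnot(all(classes %in% names(counts)),
            all(c(tel_classes, sat_classes) %in% classes))
  keys <- unique(counts[, c("study_id", "mark")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$study_id[i]; mk <- keys$mark[i]
    sub <- counts[counts$study_id == sid & counts$mark == mk, ]
    ip <- sub[sub$role == "IP", ]; inp <- sub[sub$role == "input", ]
    if (nrow(ip) != 1L || nrow(inp) != 1L) {
      warning(sprintf("study '%s' mark '%s' lacks a matched input/IP pair; skipped",
                      sid, mk))
      next
    }
    if (ip$mapping_reads == 0L || inp$mapping_reads == 0L) {
      warning(sprintf("study '%s' mark '%s' has a sample with no mapping reads; skipped",
                      sid, mk))
      next
    }
    f_in <- vapply(classes, function(cl)
      (inp[[cl]] + if (pseudocount) 0.5 else 0) / inp$mapping_reads,
      numeric(1))
    f_ip <- vapply(classes, function(cl)
      (ip[[cl]] + if (pseudocount) 0.5 else 0) / ip$mapping_reads,
      numeric(1))
    e <- ifelse(f_in > 0 & f_ip > 0, f_ip / f_in, NA_real_)
    if (anyNA(e)) {
      warning(sprintf(
        "study '%s' mark '%s': enrichment undefined (zero class counts) for %s",
        sid, mk, paste(classes[is.na(e)], collapse = ", ")))
    }
    ft_in <- .combined_freq(inp, tel_classes, pseudocount)
    ft_ip <- .combined_freq(ip, tel_classes, pseudocount)
    fs_in <- .combined_freq(inp, sat_classes, pseudocount)
    fs_ip <- .combined_freq(ip, sat_classes, pseudocount)
    ets <- if (ft_in > 0 && ft_ip > 0 && fs_in > 0 && fs_ip > 0) {
      enrichment_tel_vs_sat(ft_ip / ft_in, fs_ip / fs_in)
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      study_id = sid, mark = mk, class = classes,
      f_input = unname(f_in), f_ip = unname(f_ip), E_genome = unname(e),
      E_tel_vs_sat = ets, row.names = NULL)
  }
  if (!length(out)) {
    stop("no study has a usable matched input/IP pair")
  }
  do.call(rbind, out)
}
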