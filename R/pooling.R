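#' Pool enrichment values across studies and test against a null ratio
#'
#' Mean and SEM are reported on the original ratio scale (for bar plots
#' with standard-error bars); the test operates on log2 ratios by default,
#' because ratios are multiplicative and right-skewed. Test selection is
#' normality-gated: a Shapiro-Wilk test at `alpha_normality` decides
#' between a one-sample Student's t test (normal) and a Wilcoxon
#' signed-rank test (non-normal; zero differences from the null are
#' excluded, the signed-rank convention). With fewer than three values only
#' descriptive statistics are reported; with every value identical to the
#' null the p-value is 1 and no test is run.
#'
#' @param values positive enrichment ratios, one per study.
#' @param null_value null ratio (1 for enrichment ratios).
#' @param alpha_normality significance level of the normality gate.
#' @param scale `"log2"` (test log2 ratios against `log2(null_value)`) or
#'   `"linear"` (test raw ratios against `null_value`).
#' @param comparison optional label stored in the result.
#' @return object of class `pooled_result`: `n`, `values`, `mean`, `sem`,
#'   `shapiro_p`, `test_used` ("t", "wilcoxon" or "none"), `p_value`,
#'   `null_value`, `scale`, `comparison`.
#' @examples
#' pool_and_test(c(1.8, 2.2, 2.0, 1.9, 2.4), null_value = 1)
#' @export
pool_and_test <- function(values, null_value = 1, alpha_normality = 0.05,
                          scale = c("log2", "linear"), comparison = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values),
            null_value > 0)
  n <- length(values)
  res <- list(comparison = comparison, n = n, values = values,
              mean = mean(values),
              sem = if (n > 1L) sd(values) / sqrt(n) else NA_real_,
              shapiro_p = NA_real_, test_used = "none",
              p_value = NA_real_, null_value = null_value, scale = scale)
  class(res) <- "pooled_result"
  if (n < 3L) return(res)  # too few studies to gate or test

  if (scale == "log2") {
    if (any(values <= 0)) {
      stop("non-positive ratios under log2 scale; enable the pseudocount upstream")
    }
    x <- log2(values); null0 <- log2(null_value)
  } else {
    x <- values; null0 <- null_value
  }
  if (all(x == null0)) {  # degenerate: every study exactly at the null
    res$p_value <- 1
    return(res)
  }
  if (sd(x) == 0) {
    # identical values off the null: Shapiro-Wilk is undefined, gate to the
    # rank test, which handles the degenerate sample exactly
    res$test_used <- "wilcoxon"
    res$p_value <- suppressWarnings(
      wilcox.test(x, mu = null0, exact = FALSE)$p.value)
    return(res)
  }
  res$shapiro_p <- shapiro.test(x)$p.value
  if (res$shapiro_p >= alpha_normality) {
    res$test_used <- "t"
    res$p_value <- t.test(x, mu = null0)$p.value
  } else {
    res$test_used <- "wilcoxon"
    res$p_value <- suppressWarnings(
      wilcox.test(x, mu = null0)$p.value)
  }
  res
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "pooled_result%s: n = %d, mean = %.4g, sem = %.3g, test = %s, p = %.4g %s\n",
    if (is.null(x$comparison)) "" else sprintf(" [%s]", x$comparison),
    x$n, x$mean, x$sem, x$test_used,
    if (is.na(x$p_value)) NA else x$p_value,
    if (is.na(x$p_value)) "" else significance_stars(x$p_value)))
  invisible(x)
}

#' Compare pooled RMUS values between input and IP samples
#'
#' Pools RMUS (fraction of reads mapping to unique sequences) across
#' studies for the input and IP groups and tests whether the IP libraries
#' shifted toward or away from single-copy sequence. Normality-gated:
#' if the Shapiro-Wilk test accepts normality (of both groups, or of the
#' paired differences), a Student's t test is used (two-sample with pooled
#' variance, or paired); otherwise a two-sample Kolmogorov-Smirnov test
#' (unpaired) or a Wilcoxon signed-rank test (paired). Group medians and
#' quartiles are reported for box-plot output.
#'
#' @param input_values,ip_values RMUS fractions per study (each n >= 3).
#' @param paired logical; if `TRUE` the vectors must be equal-length with
#'   matched study order.
#' @param alpha_normality significance level of the normality gate.
#' @return object of class `pooled_result` with extra fields
#'   `group_stats` (medians/quartiles per group) and `mean_difference`
#'   (mean IP minus mean input).
#' @export
compare_rmus <- function(input_values, ip_values, paired = FALSE,
                         alpha_normality = 0.05) {
  stopifnot(is.numeric(input_values), is.numeric(ip_values),
            length(input_values) >= 3L, length(ip_values) >= 3L,
            !anyNA(input_values), !anyNA(ip_values))
  if (paired && length(input_values) != length(ip_values)) {
    stop("paired comparison requires equally many input and IP values")
  }
  qs <- function(v) setNames(quantile(v, c(0.25, 0.5, 0.75)),
                             c("q25", "median", "q75"))
  res <- list(comparison = "RMUS input vs IP",
              n = c(input = length(input_values), ip = length(ip_values)),
              values = list(input = input_values, ip = ip_values),
              mean = c(input = mean(input_values), ip = mean(ip_values)),
              sem = c(input = sd(input_values) / sqrt(length(input_values)),
                      ip = sd(ip_values) / sqrt(length(ip_values))),
              mean_difference = mean(ip_values) - mean(input_values),
              group_stats = rbind(input = qs(input_values),
                                  ip = qs(ip_values)),
              shapiro_p = NA_real_, test_used = "none",
              p_value = NA_real_, null_value = 0, scale = "linear",
              paired = paired)
  class(res) <- "pooled_result"

  safe_shapiro <- function(v) {
    if (sd(v) == 0) return(0)  # degenerate sample: treat as non-normal
    shapiro.test(v)$p.value
  }
  if (paired) {
    d <- ip_values - input_values
    if (all(d == 0)) { res$p_value <- 1; return(res) }
    res$shapiro_p <- safe_shapiro(d)
    if (res$shapiro_p >= alpha_normality) {
      res$test_used <- "t"
      res$p_value <- t.test(ip_values, input_values, paired = TRUE)$p.value
    } else {
      res$test_used <- "wilcoxon"
      res$p_value <- suppressWarnings(
        wilcox.test(ip_values, input_values, paired = TRUE)$p.value)
    }
  } else {
    if (identical(sort(input_values), sort(ip_values)) &&
        sd(c(input_values, ip_values)) == 0) {
      res$p_value <- 1; return(res)
    }
    sp <- c(safe_shapiro(input_values), safe_shapiro(ip_values))
    res$shapiro_p <- min(sp)
    if (all(sp >= alpha_normality)) {
      res$test_used <- "t"
      res$p_value <- t.test(ip_values, input_values,
                            var.equal = TRUE)$p.value
    } else {
      res$test_used <- "ks"
      res$p_value <- suppressWarnings(
        ks.test(input_values, ip_values)$p.value)
    }
  }
  res
}

#' Pooled significance table across marks
#'
#' For every mark, pools the per-study enrichment values of each motif
#' class against the null ratio 1, pools the combined telomere-vs-satellite
#' ratios likewise, and formats one row per comparison with significance
#' stars at 0.05 / 0.01 / 0.001.
#'
#' @param enrich data.frame from [enrichment_table()].
#' @param alpha_normality,scale passed to [pool_and_test()].
#' @return data.frame: `mark`, `comparison`, `n`, `mean`, `sem`,
#'   `shapiro_p`, `test_used`, `p_value`, `stars`.
#' @export
pooled_table <- function(enrich, alpha_normality = 0.05, scale = "log2") {
  rows <- list()
  add <- function(mark, comparison, values) {
    values <- values[!is.na(values)]
    if (length(values) < 2L) {
      warning(sprintf("mark '%s', comparison '%s': fewer than 2 studies; descriptive only",
                      mark, comparison))
    }
    if (!length(values)) return()
    pr <- pool_and_test(values, null_value = 1,
                        alpha_normality = alpha_normality, scale = scale,
                        comparison = comparison)
    rows[[length(rows) + 1L]] <<- data.frame(
      mark = mark, comparison = comparison, n = pr$n, mean = pr$mean,
      sem = pr$sem, shapiro_p = pr$shapiro_p, test_used = pr$test_used,
      p_value = pr$p_value, stars = significance_stars(pr$p_value))
  }
  for (mk in unique(enrich$mark)) {
    sub <- enrich[enrich$mark == mk, ]
    for (cl in unique(sub$class)) {
      add(mk, paste0(cl, "_vs_genome"), sub$E_genome[sub$class == cl])
    }
    ets <- sub[!duplicated(sub$study_id), "E_tel_vs_sat"]
    add(mk, "TEL_vs_SAT", ets)
  }
  if (!length(rows)) stop("no poolable comparisons")
  do.call(rbind, rows)
}

#' Pooled RMUS comparison table across marks
#'
#' @param counts data.frame from [counts_table()]; needs non-`NA` `rmus`.
#' @param paired,alpha_normality passed to [compare_rmus()].
#' @return data.frame: `mark`, `n_input`, `n_ip`, `mean_input`, `mean_ip`,
#'   `mean_difference`, `shapiro_p`, `test_used`, `p_value`, `stars`.
#' @export
rmus_table <- function(counts, paired = FALSE, alpha_normality = 0.05) {
  rows <- list()
  for (mk in unique(counts$mark)) {
    sub <- counts[counts$mark == mk & !is.na(counts$rmus), ]
    iv <- sub$rmus[sub$role == "input"]
    pv <- sub$rmus[sub$role == "IP"]
    if (length(iv) < 3L || length(pv) < 3L) {
      warning(sprintf("mark '%s': fewer than 3 RMUS values per group; skipped", mk))
      next
    }
    pr <- compare_rmus(iv, pv, paired = paired,
                       alpha_normality = alpha_normality)
    rows[[length(rows) + 1L]] <- data.frame(
      mark = mk, n_input = length(iv), n_ip = length(pv),
      mean_input = pr$mean[["input"]], mean_ip = pr$mean[["ip"]],
      mean_difference = pr$mean_difference, shapiro_p = pr$shapiro_p,
      test_used = pr$test_used, p_value = pr$p_value,
      stars = significance_stars(pr$p_value))
  }
  if (!length(rows)) stop("no mark has enough RMUS values to compare")
  do.call(rbind, rows)
}
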