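# Study-level orchestration: assemble per-parameter reliability tables,
# correlation tables and pre/post treatment comparisons in the layout of a
# clinical validation study.

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Reliability study over several videographic parameters
#'
#' Computes, for each parameter, the ICC appropriate to the design --
#' ICC(1,1) for test-retest (occasions nested in a single rater), ICC(2,k)
#' for inter-rater -- with its confidence interval and category, and for
#' test-retest designs the SDd, MDC95 and (for log10-transformed
#' parameters) MDC%.
#'
#' @param measurements named list of subjects x occasions (or x raters)
#'   numeric matrices, one per parameter; all the same dimension, no
#'   missing cells.
#' @param design `"test_retest"` or `"inter_rater"`.
#' @param log10_transform logical (recycled over parameters): log10 the
#'   measurements first (standard for amplitude-like, right-skewed
#'   parameters). MDC% is reported only for log10-transformed parameters,
#'   where it has its percent-of-baseline meaning.
#' @param conf_level confidence level.
#' @return a data frame of class `reliability_study`, one row per
#'   parameter: `icc`, `ci_low`, `ci_high`, `category`, `sdd`, `mdc95`,
#'   `mdc_percent`. The full `reliability_result` objects are attached as
#'   attribute `"results"`.
#' @export
run_reliability_study <- function(measurements,
                                  design = c("test_retest", "inter_rater"),
                                  log10_transform = FALSE,
                                  conf_level = 0.95) {
  design <- match.arg(design)
  check_that(is.list(measurements) && length(measurements) >= 1L &&
               !is.null(names(measurements)),
             "'measurements' must be a named list of matrices")
  log10_transform <- rep_len(log10_transform, length(measurements))
  results <- vector("list", length(measurements))
  rows <- vector("list", length(measurements))
  for (i in seq_along(measurements)) {
    m <- check_measurement_matrix(measurements[[i]])
    check_that(ncol(m) >= 2L,
               "parameter '%s': need >= 2 occasions/raters",
               names(measurements)[i])
    if (log10_transform[i]) {
      check_that(all(m > 0),
                 "parameter '%s': log10 transform requires positive values",
                 names(measurements)[i])
      m <- log10(m)
    }
    res <- if (design == "test_retest") icc_oneway_single(m, conf_level)
           else icc_twoway_average(m, conf_level)
    mdcp <- if (!is.na(res$sdd) && log10_transform[i])
      mdc_percent(res$sdd) else NA_real_
    results[[i]] <- res
    rows[[i]] <- data.frame(parameter = names(measurements)[i],
                            icc = res$icc, ci_low = res$ci_low,
                            ci_high = res$ci_high, category = res$category,
                            sdd = res$sdd, mdc95 = res$mdc95,
                            mdc_percent = mdcp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- stats::setNames(results, names(measurements))
  attr(out, "design") <- design
  class(out) <- c("reliability_study", "data.frame")
  out
}

#' @export
print.reliability_study <- function(x, digits = 3, ...) {
  cat(sprintf("Reliability study (%s), %d parameter(s)\n",
              attr(x, "design"), nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Correlation of videographic parameters with clinical scores
#'
#' Spearman rank correlation of each (log10) videographic parameter with
#' each clinical rating column, with the usual two-level significance
#' flags (* p < 0.05, ** p < 0.01). A constant column makes that pair
#' undefined (reported as NA), not an error.
#'
#' @param cohort data frame (e.g. from [generate_cohort()]).
#' @param metric_cols names of videographic parameter columns.
#' @param score_cols names of clinical score columns.
#' @param log10_metrics log10-transform the metric columns first.
#' @return data frame of class `correlation_study`: one row per
#'   (metric, score) pair with `rho`, `p_value`, `signif`, `n`.
#' @export
run_correlation_study <- function(cohort, metric_cols, score_cols,
                                  log10_metrics = TRUE) {
  check_that(is.data.frame(cohort), "'cohort' must be a data frame")
  check_that(all(c(metric_cols, score_cols) %in% names(cohort)),
             "missing columns in cohort table")
  check_that(nrow(cohort) >= 3L, "need >= 3 patients")
  rows <- list()
  for (mc in metric_cols) {
    v <- cohort[[mc]]
    if (log10_metrics) {
      check_that(all(v > 0), "metric '%s' must be positive for log10", mc)
      v <- log10(v)
    }
    for (sc in score_cols) {
      s <- cohort[[sc]]
      ok <- is.finite(v) & is.finite(s)
      res <- if (sum(ok) >= 3L && length(unique(v[ok])) > 1L &&
                   length(unique(s[ok])) > 1L) {
        spearman_rho(v[ok], s[ok])
      } else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mc, score = sc,
        rho = res$rho %||% NA_real_,
        p_value = res$p_value %||% NA_real_,
        signif = if (is.null(res)) "" else significance_stars(res$p_value),
        n = if (is.null(res)) sum(ok) else res$n)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_study", "data.frame")
  out
}

#' @export
print.correlation_study <- function(x, digits = 3, ...) {
  cat("Spearman correlations (*: p < 0.05, **: p < 0.01)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Pre/post treatment comparison with change correlations
#'
#' For each paired variable, reports both the median (min-max) and the
#' mean (SD) before and after treatment together with the Wilcoxon
#' signed-rank p-value (clinical scores are conventionally summarised by
#' medians, videographic parameters by means; both summaries are computed
#' for every variable). For each (metric, score) combination the Spearman
#' correlation between the videographic log change `log10(T2/T1)` and the
#' score improvement `R2 - R1` is added.
#'
#' @param cohort data frame with one row per patient.
#' @param score_pairs named list of `c(pre, post)` column-name pairs for
#'   clinical scores.
#' @param metric_pairs named list of `c(pre, post)` column-name pairs for
#'   videographic parameters (positive-valued; change is computed on the
#'   log10 scale).
#' @return list of class `prepost_study` with elements `summary` (one row
#'   per variable) and `change_correlation` (one row per metric x score).
#' @export
run_prepost_study <- function(cohort, score_pairs, metric_pairs) {
  check_that(is.data.frame(cohort), "'cohort' must be a data frame")
  all_cols <- unlist(c(score_pairs, metric_pairs))
  check_that(all(all_cols %in% names(cohort)),
             "missing columns in cohort table")
  incomplete <- !stats::complete.cases(cohort[, all_cols, drop = FALSE])
  if (any(incomplete)) {
    ids <- if ("id" %in% names(cohort)) cohort$id[incomplete]
           else which(incomplete)
    stop(sprintf("unpaired pre/post rows for: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  summarise_pair <- function(name, pair, kind) {
    pre <- cohort[[pair[1L]]]; post <- cohort[[pair[2L]]]
    wt <- wilcoxon_signed_rank(pre, post)
    data.frame(variable = name, kind = kind,
               median_pre = median(pre), min_pre = min(pre),
               max_pre = max(pre),
               median_post = median(post), min_post = min(post),
               max_post = max(post),
               mean_pre = mean(pre), sd_pre = sd(pre),
               mean_post = mean(post), sd_post = sd(post),
               p_value = wt$p_value,
               signif = significance_stars(wt$p_value))
  }
  summ <- rbind(
    do.call(rbind, Map(summarise_pair, names(score_pairs), score_pairs,
                       "score")),
    do.call(rbind, Map(summarise_pair, names(metric_pairs), metric_pairs,
                       "metric")))
  rownames(summ) <- NULL

  rows <- list()
  for (mn in names(metric_pairs)) {
    mp <- metric_pairs[[mn]]
    lt <- log_change(cohort[[mp[1L]]], cohort[[mp[2L]]])
    for (sn in names(score_pairs)) {
      sp <- score_pairs[[sn]]
      dr <- cohort[[sp[2L]]] - cohort[[sp[1L]]]
      res <- if (length(unique(lt)) > 1L && length(unique(dr)) > 1L)
        spearman_rho(lt, dr) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mn, score = sn,
        rho = res$rho %||% NA_real_,
        p_value = res$p_value %||% NA_real_,
        signif = if (is.null(res)) "" else significance_stars(res$p_value))
    }
  }
  change <- do.call(rbind, rows)
  structure(list(summary = summ, change_correlation = change,
                 n = nrow(cohort)),
            class = "prepost_study")
}

#' @export
print.prepost_study <- function(x, digits = 3, ...) {
  cat(sprintf("Pre/post treatment comparison, n = %d\n", x$n))
  cat("\nSummary (Wilcoxon signed-rank p):\n")
  s <- x$summary
  disp <- data.frame(
    variable = s$variable,
    pre = ifelse(s$kind == "score",
                 sprintf("%.4g (%.4g-%.4g)", s$median_pre, s$min_pre, s$max_pre),
                 sprintf("%.4g (%.4g)", s$mean_pre, s$sd_pre)),
    post = ifelse(s$kind == "score",
                  sprintf("%.4g (%.4g-%.4g)", s$median_post, s$min_post,
                          s$max_post),
                  sprintf("%.4g (%.4g)", s$mean_post, s$sd_post)),
    p = format.pval(s$p_value, digits = 2), stars = s$signif)
  print.data.frame(disp, row.names = FALSE)
  cat("\nChange correlations: log10(T2/T1) vs (R2 - R1), Spearman rho:\n")
  print.data.frame(x$change_correlation, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Assemble a full study report
#'
#' Bundles the three study sections into one printable report mirroring the
#' result tables of a clinical validation study: reliability, correlation
#' with clinical ratings, and pre/post treatment change.
#'
#' @param reliability a [run_reliability_study()] result (or list of them).
#' @param correlation a [run_correlation_study()] result.
#' @param prepost a [run_prepost_study()] result.
#' @return an object of class `study_report`.
#' @export
study_report <- function(reliability = NULL, correlation = NULL,
                         prepost = NULL) {
  structure(list(reliability = reliability, correlation = correlation,
                 prepost = prepost),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== Video tremor analysis study report ====\n")
  if (!is.null(x$reliability)) {
    cat("\n-- Reliability --\n")
    if (inherits(x$reliability, "reliability_study")) print(x$reliability)
    else for (r in x$reliability) print(r)
  }
  if (!is.null(x$correlation)) {
    cat("\n-- Correlation with clinical scores --\n")
    print(x$correlation)
  }
  if (!is.null(x$prepost)) {
    cat("\n-- Pre/post treatment --\n")
    print(x$prepost)
  }
  invisible(x)
}
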