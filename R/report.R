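#' Mean, SD and t-distribution 95% confidence interval
#'
#' The CI of the mean assumes a t-distribution with `N - 1` degrees of
#' freedom: `mean +/- t_{0.975, n-1} * SD / sqrt(n)`.
#'
#' @param values numeric vector of per-subject metric values (NAs dropped)
#' @param conf confidence level (default 0.95)
#' @return one-row data.frame with columns mean, ci_low, ci_high, sd, n;
#'   with `n < 2` the CI and SD are `NA` and a warning is raised
#' @export
summarize_metric <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values to summarize")
  m <- mean(values)
  if (n < 2) {
    warning("n < 2: confidence interval undefined")
    return(data.frame(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                      sd = NA_real_, n = n))
  }
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  data.frame(mean = m, ci_low = m - half, ci_high = m + half, sd = s, n = n)
}

#' Cohort metric report
#'
#' Aggregates per-subject long-format metric rows (from
#' [evaluate_subject()]) into the standard report layout: one row per
#' (structure, metric) with mean, 95% CI bounds and SD.
#'
#' @param subject_rows data.frame rbind of [evaluate_subject()] outputs
#' @return data.frame with columns structure, metric, mean, ci_low,
#'   ci_high, sd, n
#' @export
metric_report <- function(subject_rows) {
  stopifnot(all(c("group", "metric", "value") %in% names(subject_rows)))
  keys <- unique(subject_rows[, c("group", "metric")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- subject_rows$group == keys$group[i] &
      subject_rows$metric == keys$metric[i]
    vals <- subject_rows$value[sel]
    if (all(is.na(vals)))
      return(data.frame(structure = keys$group[i], metric = keys$metric[i],
                        mean = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, sd = NA_real_, n = 0L))
    s <- suppressWarnings(summarize_metric(vals))
    data.frame(structure = keys$group[i], metric = keys$metric[i], s)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate a cohort of predictions and write CSV reports
#'
#' @param preds named list of predicted `avp_labelmap`s keyed by subject
#' @param gts named list of reference `avp_labelmap`s with the same keys
#' @param out_prefix if non-NULL, writes `<prefix>_subjects.csv`
#'   (long format) and `<prefix>_summary.csv` (report layout)
#' @return list with `subjects` (long data.frame) and `summary`
#' @export
evaluate_cohort <- function(preds, gts, out_prefix = NULL) {
  ids <- names(gts)
  stopifnot(length(ids) > 0, all(ids %in% names(preds)))
  rows <- do.call(rbind, lapply(ids, function(id) {
    r <- evaluate_subject(preds[[id]], gts[[id]])
    r$subject_id <- id
    r
  }))
  summ <- metric_report(rows)
  if (!is.null(out_prefix)) {
    utils::write.csv(rows, paste0(out_prefix, "_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(summ, paste0(out_prefix, "_summary.csv"),
                     row.names = FALSE)
  }
  list(subjects = rows, summary = summ)
}
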