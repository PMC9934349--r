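#' Confusion-matrix counts of a cohort against ground truth
#'
#' Membership is person-level: a person counts as algorithm-positive iff
#' they appear in the cohort, with no tolerance on the index date (timing
#' accuracy is reported separately by [index_date_error()]). The
#' evaluation denominator comprises every non-case plus every case whose
#' true onset falls within their observation period; cases with onset
#' outside observation are excluded, since no coded record of the onset
#' episode can exist.
#'
#' @param cohort Cohort data frame from [build_cohort()].
#' @param ground_truth Ground-truth data frame (`person_id`, `has_sle`,
#'   `onset_date`).
#' @param persons Person table (defines the population).
#' @param observation_periods Observation-period table (defines onset
#'   eligibility for cases).
#' @return Named integer vector `c(tp, fp, tn, fn)` of class
#'   `confusion_counts`.
#' @export
confusion_counts <- function(cohort, ground_truth, persons,
                             observation_periods) {
  missing <- setdiff(cohort$person_id, ground_truth$person_id)
  if (length(missing) > 0) {
    stop("cohort person(s) missing from ground truth: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  gt <- ground_truth[ground_truth$person_id %in% persons$person_id, ,
                     drop = FALSE]
  i <- match(gt$person_id, observation_periods$person_id)
  start <- observation_periods$observation_period_start_date[i]
  end <- observation_periods$observation_period_end_date[i]
  eligible <- !gt$has_sle |
    (!is.na(gt$onset_date) & gt$onset_date >= start & gt$onset_date <= end)
  gt <- gt[eligible, , drop = FALSE]
  positive <- gt$person_id %in% cohort$person_id
  structure(c(tp = sum(positive & gt$has_sle),
              fp = sum(positive & !gt$has_sle),
              tn = sum(!positive & !gt$has_sle),
              fn = sum(!positive & gt$has_sle)),
            class = "confusion_counts")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval; stable at proportions near 0 or 1, where
#' the Wald interval degenerates (specificities of claims algorithms are
#' routinely 0.999+). Agrees with `stats::prop.test(correct = FALSE)`.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return `c(low, high)`, or `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Performance characteristics from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV (each with a 95% Wilson interval)
#' and the F1 score (harmonic mean of sensitivity and PPV; no interval,
#' as it is not a single binomial proportion). A metric whose denominator
#' is zero is reported as `NA`, not 0.
#'
#' @param counts A `confusion_counts` vector (or any named vector with
#'   `tp`, `fp`, `tn`, `fn`).
#' @return An `sle_performance` list: the four counts, the five point
#'   estimates, and `ci` (a 2-column matrix of lower/upper bounds).
#' @export
performance <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  metric <- function(x, n) if (n > 0) x / n else NA_real_
  sens <- metric(tp, tp + fn)
  spec <- metric(tn, tn + fp)
  ppv <- metric(tp, tp + fp)
  npv <- metric(tn, tn + fn)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  ci <- rbind(sensitivity = wilson_ci(tp, tp + fn),
              specificity = wilson_ci(tn, tn + fp),
              ppv = wilson_ci(tp, tp + fp),
              npv = wilson_ci(tn, tn + fn))
  colnames(ci) <- c("low", "high")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1, ci = ci),
            class = "sle_performance")
}

#' @export
print.sle_performance <- function(x, digits = 3, ...) {
  cat("<sle_performance> tp", x$tp, "fp", x$fp, "tn", x$tn, "fn", x$fn, "\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    ci <- x$ci[m, ]
    cat(sprintf("  %-12s %s (%s-%s)\n", m,
                format(round(x[[m]], digits), nsmall = digits),
                format(round(ci[1], digits), nsmall = digits),
                format(round(ci[2], digits), nsmall = digits)))
  }
  cat(sprintf("  %-12s %s\n", "f1",
              format(round(x$f1, digits), nsmall = digits)))
  invisible(x)
}

#' F1 score from sensitivity and positive predictive value
#'
#' @param sensitivity,ppv Proportions.
#' @return `2 * ppv * sensitivity / (ppv + sensitivity)`; vectorised.
#' @export
f1_score <- function(sensitivity, ppv) {
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Unweighted cross-database mean of a performance metric
#'
#' Published multi-database summaries average point estimates across
#' databases without weighting by database size; this helper does the
#' same. Estimates where the metric is undefined (`NA`) are skipped with
#' a warning. Use [percent()] to reproduce whole-percent reporting.
#'
#' @param estimates A list of `sle_performance` objects, or a data frame
#'   with the metric as a column.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"npv"`, `"f1"`.
#' @return The unweighted arithmetic mean (a proportion).
#' @export
cross_database_mean <- function(estimates, metric) {
  values <- if (is.data.frame(estimates)) {
    estimates[[metric]]
  } else {
    vapply(estimates, function(e) {
      v <- e[[metric]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  if (length(values) == 0 || all(is.na(values))) {
    stop("no estimates provide metric '", metric, "'", call. = FALSE)
  }
  if (anyNA(values)) {
    warning(sum(is.na(values)), " estimate(s) lack metric '", metric,
            "'; skipped", call. = FALSE)
  }
  mean(values, na.rm = TRUE)
}

#' Published validation estimates shipped with the package
#'
#' Point estimates of sensitivity, PPV, specificity and NPV for the six
#' algorithms across seven large observational databases, as published in
#' the multi-database validation of these algorithm definitions. Used to
#' reproduce the printed cross-database summary statistics.
#'
#' @return Data frame with columns `algorithm_id`, `database`,
#'   `sensitivity`, `ppv`, `specificity`, `npv`.
#' @export
sle_reference_performance <- function() {
  path <- system.file("extdata", "reference_performance.csv",
                      package = "SlePhenotyper", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(algorithm_id = "character",
                                 database = "character",
                                 sensitivity = "numeric", ppv = "numeric",
                                 specificity = "numeric", npv = "numeric"))
}

#' Published covariate-proportion pairs for cohort comparison
#'
#' Proportions of subjects with an SLE diagnosis code or a
#' hydroxychloroquine prescription in the 31--365 days after index, for
#' the confirmed-code versus single-code incident cohorts in three US
#' databases, together with the published standardized differences.
#'
#' @return Data frame with columns `database`, `covariate`,
#'   `p_incident_2x`, `p_incident_1x`, `published_smd`.
#' @export
sle_reference_characterization <- function() {
  path <- system.file("extdata", "reference_characterization.csv",
                      package = "SlePhenotyper", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Index-date error of cohort entries against true onset
#'
#' For each cohort entry belonging to a true case, the signed error is
#' `index_date - onset_date` in days (positive: entry later than onset).
#' Summarises the mean, median and the fraction anchored exactly at
#' onset. Quantifies how much the prodrome-based correction improves
#' index-date accuracy on simulated data.
#'
#' @param cohort Cohort data frame.
#' @param ground_truth Ground-truth data frame.
#' @return List `n`, `mean_days`, `median_days`, `mean_abs_days` (mean of
#'   the absolute error, since a corrected index can also overshoot
#'   onset), `fraction_exact`, of class `index_date_error_summary`.
#' @export
index_date_error <- function(cohort, ground_truth) {
  gt <- ground_truth[ground_truth$has_sle, , drop = FALSE]
  i <- match(cohort$person_id, gt$person_id)
  keep <- !is.na(i)
  err <- as.integer(cohort$index_date[keep] - gt$onset_date[i[keep]])
  structure(list(n = length(err),
                 mean_days = if (length(err)) mean(err) else NA_real_,
                 median_days = if (length(err)) stats::median(err) else NA_real_,
                 mean_abs_days = if (length(err)) mean(abs(err)) else NA_real_,
                 fraction_exact = if (length(err)) mean(err == 0) else NA_real_),
            class = "index_date_error_summary")
}

#' @export
print.index_date_error_summary <- function(x, ...) {
  cat("<index_date_error> n =", x$n, "\n")
  cat("  mean:", round(x$mean_days, 1), "days; median:", x$median_days,
      "days; exact:", round(100 * x$fraction_exact, 1), "%\n")
  invisible(x)
}
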