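#' Rogan-Gladen correction of an observed prevalence
#'
#' Corrects a cohort-derived proportion for outcome misclassification
#' given the classifying algorithm's sensitivity and specificity:
#' `(p_obs + specificity - 1) / (sensitivity + specificity - 1)`, clipped
#' to \[0, 1\]. Requires an informative classifier
#' (`sensitivity + specificity > 1`).
#'
#' @param p_obs Observed proportion(s).
#' @param sensitivity,specificity Algorithm performance parameters.
#' @return Corrected proportion(s).
#' @export
correct_prevalence <- function(p_obs, sensitivity, specificity) {
  .check_se_sp(sensitivity, specificity)
  pmin(1, pmax(0, (p_obs + specificity - 1) /
                 (sensitivity + specificity - 1)))
}

.check_se_sp <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  if (any(se + sp <= 1)) {
    stop("sensitivity + specificity must exceed 1 (non-informative ",
         "classifier); got ", se[which(se + sp <= 1)[1]], " + ",
         sp[which(se + sp <= 1)[1]], call. = FALSE)
  }
}

#' Rogan-Gladen correction of an observed incidence rate
#'
#' Removes expected false-positive events and rescales for missed true
#' events: corrected events =
#' `(events - (1 - specificity) * n_at_risk) / (sensitivity + specificity - 1)`,
#' floored at 0; the corrected rate is per 100,000 person-years.
#'
#' @param events Observed event count.
#' @param person_years Person-years at risk.
#' @param n_at_risk Number of persons at risk (the base from which false
#'   positives arise).
#' @param sensitivity,specificity Algorithm performance parameters.
#' @return Corrected rate per 100,000 person-years, with the corrected
#'   event count as attribute `corrected_events`.
#' @export
correct_incidence <- function(events, person_years, n_at_risk,
                              sensitivity, specificity) {
  .check_se_sp(sensitivity, specificity)
  stopifnot(person_years > 0, n_at_risk >= 0, events >= 0)
  corrected <- max(0, (events - (1 - specificity) * n_at_risk) /
                     (sensitivity + specificity - 1))
  structure(1e5 * corrected / person_years, corrected_events = corrected)
}

# Beta parameters moment-matched to a point estimate and 95% CI width.
.beta_match <- function(point, ci) {
  v <- ((ci[2] - ci[1]) / (2 * stats::qnorm(0.975)))^2
  if (v <= 0) return(NULL)  # degenerate: caller collapses to the point
  m <- min(max(point, 1e-6), 1 - 1e-6)
  v <- min(v, m * (1 - m) * 0.999)  # keep both shape parameters positive
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Probabilistic bias interval for a misclassification-corrected estimate
#'
#' Propagates uncertainty in the algorithm's sensitivity and specificity
#' through the Rogan-Gladen correction: draws `(se, sp)` pairs from Beta
#' distributions moment-matched to each point estimate and its 95% CI,
#' applies the deterministic correction per draw, and reports the
#' 2.5/97.5 percentiles. Draws with `se + sp <= 1` are discarded (an
#' error if fewer than half the draws remain). Zero-width CIs collapse to
#' the deterministic correction.
#'
#' @param p_obs Observed proportion (for prevalence correction), or
#'   `NULL` when correcting a rate.
#' @param events,person_years,n_at_risk Rate inputs (used when `p_obs` is
#'   `NULL`), as in [correct_incidence()].
#' @param se,sp Point estimates of sensitivity and specificity.
#' @param se_ci,sp_ci Length-2 95% confidence intervals.
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @return A `qba_result` list: `observed`, `corrected`, `interval`
#'   (`c(low, high)`), `se_used`, `sp_used`, `n_draws` (draws kept).
#' @export
probabilistic_interval <- function(p_obs = NULL, events = NULL,
                                   person_years = NULL, n_at_risk = NULL,
                                   se, sp, se_ci, sp_ci,
                                   n_draws = 1000, seed = 1) {
  .check_se_sp(se, sp)
  stopifnot(length(se_ci) == 2, length(sp_ci) == 2,
            se_ci[1] <= se_ci[2], sp_ci[1] <= sp_ci[2])
  is_rate <- is.null(p_obs)
  correct_one <- function(se_d, sp_d) {
    if (is_rate) {
      as.numeric(correct_incidence(events, person_years, n_at_risk,
                                   se_d, sp_d))
    } else {
      correct_prevalence(p_obs, se_d, sp_d)
    }
  }
  observed <- if (is_rate) 1e5 * events / person_years else p_obs
  corrected <- correct_one(se, sp)

  set.seed(as.integer(seed))
  se_par <- .beta_match(se, se_ci)
  sp_par <- .beta_match(sp, sp_ci)
  se_draws <- if (is.null(se_par)) rep(se, n_draws) else {
    stats::rbeta(n_draws, se_par[1], se_par[2])
  }
  sp_draws <- if (is.null(sp_par)) rep(sp, n_draws) else {
    stats::rbeta(n_draws, sp_par[1], sp_par[2])
  }
  keep <- se_draws + sp_draws > 1
  if (sum(keep) < n_draws / 2) {
    stop("more than half of the (se, sp) draws were non-informative; ",
         "the CIs are too wide for a stable correction", call. = FALSE)
  }
  vals <- mapply(correct_one, se_draws[keep], sp_draws[keep])
  interval <- unname(stats::quantile(vals, c(0.025, 0.975)))
  structure(list(observed = observed, corrected = corrected,
                 interval = interval, se_used = se, sp_used = sp,
                 n_draws = sum(keep)),
            class = "qba_result")
}

#' @export
print.qba_result <- function(x, digits = 4, ...) {
  cat("<qba_result>\n")
  cat("  observed: ", signif(x$observed, digits), "\n")
  cat("  corrected:", signif(x$corrected, digits),
      sprintf(" (95%% interval %s - %s)", signif(x$interval[1], digits),
              signif(x$interval[2], digits)), "\n")
  cat("  se =", x$se_used, " sp =", x$sp_used, " draws =", x$n_draws, "\n")
  invisible(x)
}
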