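#' Configuration for the synthetic claims simulator
#'
#' Builds a validated configuration with defaults calibrated to the
#' population features the SLE algorithms were characterised against:
#' an overall incidence of about 16 cases per 100,000 person-years, a
#' strong female excess among cases (~87% female at the default
#' multiplier with a balanced population), incidence peaking in the
#' 50--59-year age band, short bounded claims follow-up (median 1.5
#' years), diagnosis delay after true onset, prodromal signs/symptoms and
#' empiric treatment preceding the first diagnosis code, repeat coding of
#' confirmed disease, and occasional spurious rule-out codes in
#' non-cases (which never repeat and never co-occur with antimalarials —
#' exactly the mechanism confirmed-code algorithms exploit).
#'
#' `prodrome_prob` is the target fraction of case cohort entries whose
#' entry event is a precursor rather than a diagnosis code; the simulator
#' deflates the internal insertion probability to account for background
#' sign/symptom events that coincidentally fall in the pre-diagnosis
#' window, so the observable fraction matches the configured value.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param calendar_window Two dates bounding all observation.
#' @param followup_years_median Median observation-period length, years.
#' @param female_fraction_population Population share of females.
#' @param sle_incidence_per_100k_py True onset rate per 100,000
#'   person-years of observation.
#' @param female_case_multiplier Female:male hazard ratio for SLE.
#' @param age_peak_band 10-year age band ("50-59") where the hazard peaks;
#'   bands decay geometrically away from the peak.
#' @param prevalent_case_fraction Share of cases whose onset precedes
#'   observation start.
#' @param dx_delay_days_mean Mean (geometric) delay from onset to the
#'   first diagnosis code, days.
#' @param prodrome_prob Target fraction of case index events that are
#'   precursor events (see above).
#' @param prodrome_lead_days_max Maximum lead of prodromal events before
#'   the first diagnosis code, days.
#' @param repeat_code_prob_per_month Monthly probability that a case
#'   receives a further SLE code after the first.
#' @param ruleout_code_prob Probability a non-case receives one spurious
#'   SLE code (never repeated).
#' @param hcq_prob_cases,hcq_prob_noncases Probability of a
#'   hydroxychloroquine exposure for cases (shortly after the first code)
#'   and non-cases (anytime; never alongside a rule-out code).
#' @param background_symptom_rate_per_py Poisson rate of nonspecific
#'   sign/symptom events for everyone.
#' @param comorbidity_enrichment Named list: concept-set name ->
#'   `c(case = p, noncase = p)` probabilities of one coded comorbidity.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_persons = 10000,
                              seed = 1,
                              calendar_window = as.Date(c("2010-01-01",
                                                          "2020-12-31")),
                              followup_years_median = 1.5,
                              female_fraction_population = 0.5,
                              sle_incidence_per_100k_py = 16,
                              female_case_multiplier = 7,
                              age_peak_band = "50-59",
                              prevalent_case_fraction = 0.3,
                              dx_delay_days_mean = 45,
                              prodrome_prob = 0.45,
                              prodrome_lead_days_max = 90,
                              repeat_code_prob_per_month = 0.25,
                              ruleout_code_prob = 0.002,
                              hcq_prob_cases = 0.38,
                              hcq_prob_noncases = 0.002,
                              background_symptom_rate_per_py = 0.3,
                              comorbidity_enrichment = list(
                                rheumatoid_arthritis = c(case = 0.12, noncase = 0.02),
                                renal_impairment = c(case = 0.08, noncase = 0.015),
                                heart_disease = c(case = 0.10, noncase = 0.04))) {
  cfg <- list(n_persons = n_persons, seed = seed,
              calendar_window = as.Date(calendar_window),
              followup_years_median = followup_years_median,
              female_fraction_population = female_fraction_population,
              sle_incidence_per_100k_py = sle_incidence_per_100k_py,
              female_case_multiplier = female_case_multiplier,
              age_peak_band = age_peak_band,
              prevalent_case_fraction = prevalent_case_fraction,
              dx_delay_days_mean = dx_delay_days_mean,
              prodrome_prob = prodrome_prob,
              prodrome_lead_days_max = prodrome_lead_days_max,
              repeat_code_prob_per_month = repeat_code_prob_per_month,
              ruleout_code_prob = ruleout_code_prob,
              hcq_prob_cases = hcq_prob_cases,
              hcq_prob_noncases = hcq_prob_noncases,
              background_symptom_rate_per_py = background_symptom_rate_per_py,
              comorbidity_enrichment = comorbidity_enrichment)
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.sim_proportions <- c("female_fraction_population", "prevalent_case_fraction",
                      "prodrome_prob", "repeat_code_prob_per_month",
                      "ruleout_code_prob", "hcq_prob_cases",
                      "hcq_prob_noncases")
.sim_nonneg <- c("sle_incidence_per_100k_py", "female_case_multiplier",
                 "dx_delay_days_mean", "prodrome_lead_days_max",
                 "background_symptom_rate_per_py", "followup_years_median")

.age_bands <- paste(seq(0, 80, 10), c(seq(9, 79, 10), "plus"), sep = "-")

.validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation config field '", field, "': ", why,
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
      is.na(cfg$n_persons) || cfg$n_persons < 0 ||
      cfg$n_persons != floor(cfg$n_persons)) {
    bad("n_persons", "must be a non-negative integer")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    bad("seed", "must be a single integer")
  }
  if (length(cfg$calendar_window) != 2 || anyNA(cfg$calendar_window) ||
      cfg$calendar_window[1] > cfg$calendar_window[2]) {
    bad("calendar_window", "must be two ordered dates")
  }
  for (f in .sim_proportions) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      bad(f, "must be a proportion in [0, 1]")
    }
  }
  for (f in .sim_nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      bad(f, "must be a non-negative number")
    }
  }
  if (!cfg$age_peak_band %in% .age_bands) {
    bad("age_peak_band", paste("must be one of",
                               paste(.age_bands, collapse = ", ")))
  }
  for (nm in names(cfg$comorbidity_enrichment)) {
    v <- cfg$comorbidity_enrichment[[nm]]
    if (!is.numeric(v) || !all(c("case", "noncase") %in% names(v)) ||
        any(v < 0) || any(v > 1)) {
      bad("comorbidity_enrichment", paste0("entry '", nm,
          "' must be c(case=, noncase=) proportions"))
    }
  }
  invisible(cfg)
}

# Hazard multiplier per 10-year age band, geometric decay from the peak.
.age_multipliers <- function(peak_band) {
  d <- abs(seq_along(.age_bands) - match(peak_band, .age_bands))
  stats::setNames(1.6 * 0.7^d, .age_bands)
}

.empty_sim_tables <- function() {
  structure(list(
    person = data.frame(person_id = character(0), sex = character(0),
                        birth_year = integer(0), stringsAsFactors = FALSE),
    observation_period = data.frame(
      person_id = character(0),
      observation_period_start_date = as.Date(character(0)),
      observation_period_end_date = as.Date(character(0)),
      stringsAsFactors = FALSE),
    event = data.frame(person_id = character(0),
                       event_date = as.Date(character(0)),
                       domain = character(0), vocabulary = character(0),
                       code = character(0), visit_context = character(0),
                       stringsAsFactors = FALSE),
    ground_truth = data.frame(person_id = character(0), has_sle = logical(0),
                              onset_date = as.Date(character(0)),
                              stringsAsFactors = FALSE)),
    class = "sle_database")
}

.sample_codes <- function(codes_df, k) {
  i <- sample.int(nrow(codes_df), k, replace = TRUE)
  codes_df[i, c("vocabulary", "code"), drop = FALSE]
}

#' Simulate a synthetic observational database with ground truth
#'
#' Seeded generative model of a claims-like database. Per person, in
#' documented draw order: (1) one observation period placed in the
#' calendar window with exponentially distributed length (median
#' `followup_years_median`; the start is placed so the period fits inside
#' the window) and demographics
#' (sex; age at observation start uniform on 0--84); (2) latent SLE
#' status from the configured incidence scaled by sex and age-band
#' multipliers (normalised so the population marginal rate matches the
#' configured rate), with onset before observation start with probability
#' `prevalent_case_fraction`, else uniform within observation; (3) for
#' cases, a first SLE code at onset plus a geometric coding delay
#' (clamped into observation), prodromal sign/symptom/corticosteroid
#' events 1--`prodrome_lead_days_max` days before the first code,
#' monthly-Bernoulli repeat codes, and hydroxychloroquine exposure with
#' probability `hcq_prob_cases`; (4) for non-cases, at most one spurious
#' rule-out SLE code; (5) for everyone, background sign/symptom events as
#' a Poisson process and comorbidity codes per the enrichment map. All
#' draws come from one seeded generator, so a fixed seed reproduces the
#' database exactly.
#'
#' @param config A `simulation_config`.
#' @return An `sle_database` whose `ground_truth` component holds
#'   `person_id`, `has_sle` and `onset_date` (NA for non-cases).
#' @export
simulate_population <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  .validate_sim_config(config)
  n <- as.integer(config$n_persons)
  if (n == 0) return(.empty_sim_tables())
  set.seed(as.integer(config$seed))

  win_start <- as.integer(config$calendar_window[1])
  win_end <- as.integer(config$calendar_window[2])
  ids <- sprintf("p%0*d", max(6L, nchar(n)), seq_len(n))

  # (1) observation period, sex, age
  # duration first, then a start that leaves room, so the window end does
  # not truncate the follow-up distribution (keeps the median on target)
  dur_years <- stats::rexp(n, rate = log(2) / config$followup_years_median)
  dur_days <- pmin(pmax(1, round(dur_years * 365.25)), win_end - win_start)
  obs_start <- win_start +
    floor(stats::runif(n) * (win_end - win_start - dur_days + 1))
  obs_end <- obs_start + dur_days
  obs_days <- obs_end - obs_start + 1
  py <- obs_days / 365.25
  sex <- ifelse(stats::runif(n) < config$female_fraction_population,
                "female", "male")
  age <- floor(stats::runif(n) * 85)
  birth_year <- as.integer(format(as.Date(obs_start, origin = "1970-01-01"),
                                  "%Y")) - age

  # (2) latent status
  band <- .age_bands[pmin(age %/% 10 + 1, 9)]
  mult <- .age_multipliers(config$age_peak_band)[band] *
    ifelse(sex == "female", config$female_case_multiplier, 1)
  w <- mult / (sum(mult * py) / sum(py))
  p_incident <- config$sle_incidence_per_100k_py / 1e5 * w * py
  p_case <- pmin(p_incident / max(1 - config$prevalent_case_fraction, 1e-12),
                 0.99)
  is_case <- stats::runif(n) < p_case
  u_prev <- stats::runif(n)
  is_prevalent <- is_case & u_prev < config$prevalent_case_fraction
  u_onset <- stats::runif(n)
  onset <- rep(NA_integer_, n)
  onset[is_case & !is_prevalent] <-
    obs_start[is_case & !is_prevalent] +
    floor(u_onset[is_case & !is_prevalent] * obs_days[is_case & !is_prevalent])
  onset[is_prevalent] <- obs_start[is_prevalent] - 1L -
    floor(u_onset[is_prevalent] * 5 * 365)

  registry <- default_concept_sets()
  dx_codes <- .set_codes(registry, "sle_diagnosis")
  sign_codes <- .set_codes(registry, "sle_signs_symptoms")
  steroid_codes <- .set_codes(registry, "sle_treatment_drugs")
  steroid_codes <- steroid_codes[steroid_codes$code != "5521", , drop = FALSE]

  chunks <- vector("list", 0)
  add_events <- function(person, date, domain, voc, code) {
    chunks[[length(chunks) + 1L]] <<- list(person = person,
                                           date = as.integer(date),
                                           domain = domain, voc = voc,
                                           code = code)
  }

  # (3) case coding
  case_idx <- which(is_case)
  n_case <- length(case_idx)
  if (n_case > 0) {
    delay <- stats::rgeom(n_case, prob = 1 / (1 + config$dx_delay_days_mean))
    first_code <- pmin(pmax(onset[case_idx] + delay, obs_start[case_idx]),
                       obs_end[case_idx])
    fc_codes <- .sample_codes(dx_codes, n_case)
    add_events(ids[case_idx], first_code, rep("condition", n_case),
               fc_codes$vocabulary, fc_codes$code)

    # prodromes: insertion probability deflated for background coincidence
    # so the realised precursor-entry fraction targets prodrome_prob
    p_bg <- 1 - exp(-config$background_symptom_rate_per_py *
                      config$prodrome_lead_days_max / 365.25)
    p_insert <- max(0, (config$prodrome_prob - p_bg) / (1 - p_bg))
    u_pro <- stats::runif(n_case)
    for (j in seq_len(n_case)) {
      i <- case_idx[j]
      avail <- min(config$prodrome_lead_days_max,
                   first_code[j] - obs_start[i])
      if (u_pro[j] < p_insert && avail >= 1) {
        k <- sample.int(3, 1)
        leads <- sample.int(avail, k, replace = TRUE)
        as_sign <- stats::runif(k) < 0.7
        pc <- rbind(.sample_codes(sign_codes, sum(as_sign)),
                    .sample_codes(steroid_codes, sum(!as_sign)))
        add_events(rep(ids[i], k), first_code[j] - leads,
                   ifelse(c(rep(TRUE, sum(as_sign)), rep(FALSE, sum(!as_sign))),
                          "condition", "drug"),
                   pc$vocabulary, pc$code)
      }
      # repeat codes, one Bernoulli per 30-day month after the first code
      m_avail <- (obs_end[i] - first_code[j]) %/% 30L
      if (m_avail >= 1) {
        hit <- which(stats::runif(m_avail) < config$repeat_code_prob_per_month)
        if (length(hit) > 0) {
          day_in_month <- sample.int(30, length(hit), replace = TRUE)
          rc <- .sample_codes(dx_codes, length(hit))
          add_events(rep(ids[i], length(hit)),
                     first_code[j] + (hit - 1L) * 30L + day_in_month,
                     rep("condition", length(hit)), rc$vocabulary, rc$code)
        }
      }
    }

    hcq <- stats::runif(n_case) < config$hcq_prob_cases
    if (any(hcq)) {
      off <- sample.int(61, sum(hcq), replace = TRUE) - 1L
      hdate <- pmin(first_code[hcq] + off, obs_end[case_idx[hcq]])
      add_events(ids[case_idx[hcq]], hdate, rep("drug", sum(hcq)),
                 rep("RxNorm", sum(hcq)), rep("5521", sum(hcq)))
    }
  }

  # (4) non-case rule-out codes, then non-case hydroxychloroquine
  nc_idx <- which(!is_case)
  if (length(nc_idx) > 0) {
    ro <- stats::runif(length(nc_idx)) < config$ruleout_code_prob
    if (any(ro)) {
      i <- nc_idx[ro]
      d <- obs_start[i] + floor(stats::runif(length(i)) * obs_days[i])
      rc <- .sample_codes(dx_codes, length(i))
      add_events(ids[i], d, rep("condition", length(i)),
                 rc$vocabulary, rc$code)
    }
    # rule-out recipients never receive antimalarials
    nh_idx <- nc_idx[!ro]
    hq <- stats::runif(length(nh_idx)) < config$hcq_prob_noncases
    if (any(hq)) {
      i <- nh_idx[hq]
      d <- obs_start[i] + floor(stats::runif(length(i)) * obs_days[i])
      add_events(ids[i], d, rep("drug", length(i)),
                 rep("RxNorm", length(i)), rep("5521", length(i)))
    }
  }

  # (5) background symptoms and comorbidities for everyone
  k_bg <- stats::rpois(n, config$background_symptom_rate_per_py * py)
  if (sum(k_bg) > 0) {
    i <- rep(seq_len(n), k_bg)
    d <- obs_start[i] + floor(stats::runif(length(i)) * obs_days[i])
    bc <- .sample_codes(sign_codes, length(i))
    add_events(ids[i], d, rep("condition", length(i)),
               bc$vocabulary, bc$code)
  }
  for (nm in names(config$comorbidity_enrichment)) {
    pr <- config$comorbidity_enrichment[[nm]]
    p <- ifelse(is_case, pr[["case"]], pr[["noncase"]])
    hit <- stats::runif(n) < p
    if (any(hit)) {
      i <- which(hit)
      d <- obs_start[i] + floor(stats::runif(length(i)) * obs_days[i])
      cc <- .sample_codes(.set_codes(registry, nm), length(i))
      add_events(ids[i], d, rep("condition", length(i)),
                 cc$vocabulary, cc$code)
    }
  }

  pull <- function(f) unlist(lapply(chunks, `[[`, f), use.names = FALSE)
  event <- data.frame(
    person_id = as.character(pull("person")),
    event_date = as.Date(pull("date") %||% integer(0), origin = "1970-01-01"),
    domain = as.character(pull("domain")),
    vocabulary = as.character(pull("voc")),
    code = as.character(pull("code")), stringsAsFactors = FALSE)
  event$visit_context <- sample(.visit_contexts, nrow(event), replace = TRUE,
                                prob = c(0.90, 0.05, 0.03, 0.02))
  ord <- order(event$person_id, event$event_date, event$domain,
               event$vocabulary, event$code)
  event <- event[ord, , drop = FALSE]
  rownames(event) <- NULL

  structure(list(
    person = data.frame(person_id = ids, sex = sex, birth_year = birth_year,
                        stringsAsFactors = FALSE),
    observation_period = data.frame(
      person_id = ids,
      observation_period_start_date = as.Date(obs_start, origin = "1970-01-01"),
      observation_period_end_date = as.Date(obs_end, origin = "1970-01-01"),
      stringsAsFactors = FALSE),
    event = event,
    ground_truth = data.frame(person_id = ids, has_sle = is_case,
                              onset_date = as.Date(onset, origin = "1970-01-01"),
                              stringsAsFactors = FALSE)),
    class = "sle_database")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  n_persons:", x$n_persons, " seed:", x$seed, "\n")
  cat("  incidence:", x$sle_incidence_per_100k_py, "per 100k PY;",
      "prevalent fraction:", x$prevalent_case_fraction, "\n")
  cat("  median follow-up:", x$followup_years_median, "y;",
      "prodrome prob:", x$prodrome_prob, "\n")
  invisible(x)
}
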