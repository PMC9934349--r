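#' Person counts per algorithm
#'
#' @param cohorts A single cohort data frame or a list of them (e.g. one
#'   per algorithm); rows are concatenated.
#' @return Data frame `algorithm_id`, `n_persons`.
#' @export
cohort_counts <- function(cohorts) {
  if (is.data.frame(cohorts)) cohorts <- list(cohorts)
  all <- do.call(rbind, cohorts)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(algorithm_id = character(0), n_persons = integer(0)))
  }
  agg <- stats::aggregate(list(n_persons = all$person_id),
                          by = list(algorithm_id = all$algorithm_id),
                          FUN = function(x) length(unique(x)))
  agg[order(agg$algorithm_id), , drop = FALSE]
}

#' Person-level overlap between two cohorts
#'
#' @param cohort_a,cohort_b Cohort data frames.
#' @return Named integer vector `c(n_only_a, n_both, n_only_b)`.
#' @export
overlap <- function(cohort_a, cohort_b) {
  a <- unique(cohort_a$person_id)
  b <- unique(cohort_b$person_id)
  both <- length(intersect(a, b))
  c(n_only_a = length(a) - both, n_both = both, n_only_b = length(b) - both)
}

#' Incidence rate of cohort entry per 100,000 person-years
#'
#' At-risk time per person runs from 365 days after observation start
#' (aligning the denominator with the incident algorithms' washout) to
#' the earlier of the cohort index date and observation end; persons
#' observed for less than 365 days contribute nothing. Events are counted
#' at the index date. Optionally stratified by 10-year age band (cases:
#' age at index; others: age at the midpoint of their at-risk time), sex
#' and calendar year (person-time split across years).
#'
#' @param cohort Cohort data frame built with incident semantics.
#' @param persons Person table.
#' @param observation_periods Observation-period table.
#' @param strata Character vector from `c("age_band", "sex", "year")`;
#'   empty (default) gives one overall estimate.
#' @return Data frame `age_band`, `sex`, `year` (unused strata `"all"`),
#'   `events`, `person_years`, `rate_per_100k`.
#' @export
incidence_rate <- function(cohort, persons, observation_periods,
                           strata = character(0)) {
  stopifnot(all(strata %in% c("age_band", "sex", "year")))
  i <- match(persons$person_id, observation_periods$person_id)
  start <- observation_periods$observation_period_start_date[i]
  end <- observation_periods$observation_period_end_date[i]
  idx <- cohort$index_date[match(persons$person_id, cohort$person_id)]
  risk_start <- start + 365
  risk_end <- as.Date(pmin(as.integer(end),
                           ifelse(is.na(idx), as.integer(end),
                                  as.integer(idx))),
                      origin = "1970-01-01")
  keep <- !is.na(risk_start) & risk_end >= risk_start
  if (!any(keep)) {
    warning("no person-time at risk", call. = FALSE)
    return(data.frame(age_band = character(0), sex = character(0),
                      year = character(0), events = integer(0),
                      person_years = numeric(0), rate_per_100k = numeric(0)))
  }
  p <- persons[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]; idx <- idx[keep]
  risk_start <- risk_start[keep]; risk_end <- risk_end[keep]
  is_event <- !is.na(idx) & idx >= risk_start & idx <= end

  anchor <- as.Date(ifelse(is_event, as.integer(idx),
                           (as.integer(risk_start) + as.integer(risk_end)) %/% 2),
                    origin = "1970-01-01")
  age <- as.integer(format(anchor, "%Y")) - p$birth_year
  band <- .age_bands[pmin(pmax(age, 0) %/% 10 + 1, 9)]

  if ("year" %in% strata) {
    y0 <- as.integer(format(risk_start, "%Y"))
    y1 <- as.integer(format(risk_end, "%Y"))
    reps <- y1 - y0 + 1L
    row <- rep(seq_along(reps), reps)
    year <- unlist(mapply(seq, y0, y1, SIMPLIFY = FALSE), use.names = FALSE)
    seg_start <- pmax(as.integer(risk_start)[row],
                      as.integer(as.Date(paste0(year, "-01-01"))))
    seg_end <- pmin(as.integer(risk_end)[row],
                    as.integer(as.Date(paste0(year, "-12-31"))))
    days <- seg_end - seg_start + 1
    ev <- is_event[row] & year == as.integer(format(risk_end[row], "%Y"))
    d <- data.frame(age_band = band[row], sex = p$sex[row],
                    year = as.character(year), days = days, event = ev,
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(age_band = band, sex = p$sex, year = "all",
                    days = as.integer(risk_end - risk_start) + 1L,
                    event = is_event, stringsAsFactors = FALSE)
  }
  if (!"age_band" %in% strata) d$age_band <- "all"
  if (!"sex" %in% strata) d$sex <- "all"

  agg <- stats::aggregate(cbind(events = d$event, days = d$days),
                          by = list(age_band = d$age_band, sex = d$sex,
                                    year = d$year),
                          FUN = sum)
  zero <- agg$days <= 0
  if (any(zero)) {
    warning(sum(zero), " stratum(s) with zero person-years omitted",
            call. = FALSE)
    agg <- agg[!zero, , drop = FALSE]
  }
  agg$person_years <- agg$days / 365.25
  agg$rate_per_100k <- 1e5 * agg$events / agg$person_years
  agg$days <- NULL
  agg <- agg[order(agg$age_band, agg$sex, agg$year), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Standardized difference between two binomial proportions
#'
#' Computes `(p1 - p2) / sqrt(p1(1-p1) + p2(1-p2))`. By convention a
#' magnitude above 0.1 flags imbalance between cohorts. The default
#' denominator omits the textbook `/2` inside the square root; this is
#' the variant that reproduces the published cohort-comparison values
#' exactly (set `pooled = TRUE` for the textbook form
#' `sqrt((p1(1-p1) + p2(1-p2)) / 2)`).
#'
#' @param p1,p2 Proportions in \[0, 1\]; vectorised.
#' @param pooled Use the textbook pooled denominator.
#' @return Signed standardized difference(s); `NA` with a warning where
#'   the denominator is zero (both proportions at the same degenerate
#'   endpoint).
#' @export
smd_binary <- function(p1, p2, pooled = FALSE) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  v <- p1 * (1 - p1) + p2 * (1 - p2)
  if (pooled) v <- v / 2
  out <- ifelse(v > 0, (p1 - p2) / sqrt(v), NA_real_)
  if (anyNA(out)) {
    warning("zero-variance proportion pair(s); SMD undefined, returned NA",
            call. = FALSE)
  }
  out
}

#' Temporal covariate prevalence around the index date
#'
#' For every concept set in the registry and every day window relative to
#' the index date, the fraction of cohort persons with at least one
#' qualifying event in the window (both endpoints inclusive).
#'
#' @param cohort Cohort data frame.
#' @param events Event table.
#' @param registry A `concept_registry`.
#' @param windows Data frame with columns `start`, `end` (days relative
#'   to index); default: `[-365,-31]`, `[-30,-1]`, `[0,0]`, `[1,30]`,
#'   `[31,365]`.
#' @return Long data frame `window`, `concept_set`, `proportion`.
#' @export
temporal_characterization <- function(cohort, events,
                                      registry = default_concept_sets(),
                                      windows = NULL) {
  if (is.null(windows)) {
    windows <- data.frame(start = c(-365, -30, 0, 1, 31),
                          end = c(-31, -1, 0, 30, 365))
  }
  wlab <- paste0("[", windows$start, ",", windows$end, "]")
  n_c <- length(unique(cohort$person_id))
  sets <- names(registry$sets)
  out <- expand.grid(window = wlab, concept_set = sets,
                     stringsAsFactors = FALSE)
  out$proportion <- 0
  if (n_c == 0 || nrow(events) == 0) return(out)

  ev <- events[events$person_id %in% cohort$person_id, , drop = FALSE]
  delta <- as.integer(ev$event_date -
                        cohort$index_date[match(ev$person_id,
                                                cohort$person_id)])
  key <- .code_key(ev$vocabulary, ev$code)
  for (s in sets) {
    member <- key %in% registry$set_keys[[s]]
    for (w in seq_len(nrow(windows))) {
      hit <- member & delta >= windows$start[w] & delta <= windows$end[w]
      out$proportion[out$concept_set == s & out$window == wlab[w]] <-
        length(unique(ev$person_id[hit])) / n_c
    }
  }
  out
}

#' Breakdown of cohort entries by entry-event role
#'
#' What fraction of index events are diagnosis codes versus prodromal
#' signs/symptoms or treatment drugs; fractions sum to 1.
#'
#' @param cohort Cohort data frame.
#' @return Data frame `entry_event_role`, `n`, `fraction`.
#' @export
index_event_breakdown <- function(cohort) {
  if (nrow(cohort) == 0) {
    return(data.frame(entry_event_role = character(0), n = integer(0),
                      fraction = numeric(0)))
  }
  tab <- table(cohort$entry_event_role)
  data.frame(entry_event_role = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(cohort),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match non-case comparator subjects to a cohort
#'
#' For each cohort entry, samples without replacement up to `ratio`
#' persons outside the cohort with the same sex, the same 5-year age
#' band, and at least one clinical event in the same calendar year-month
#' as the case's index date; that event's date becomes the matched index.
#' Matched subjects must have at least 365 days of observation before
#' their matched index (mirroring the cohort's look-back). Controls are
#' used at most once. Deterministic under a fixed seed; shortfalls are
#' reported in a warning.
#'
#' @param cohort Cohort data frame (the cases).
#' @param persons Person table.
#' @param observation_periods Observation-period table.
#' @param events Event table (provides candidate visit dates).
#' @param ratio Target controls per case (default 10).
#' @param seed Integer seed for the sampling.
#' @return Data frame `matched_case_id`, `person_id`, `index_date`.
#' @export
match_controls <- function(cohort, persons, observation_periods, events,
                           ratio = 10, seed = 1) {
  pool_ids <- setdiff(persons$person_id, cohort$person_id)
  if (length(pool_ids) == 0) {
    stop("empty candidate pool: every person is in the cohort",
         call. = FALSE)
  }
  set.seed(as.integer(seed))

  ev <- events[events$person_id %in% pool_ids, , drop = FALSE]
  ev <- ev[order(ev$person_id, ev$event_date), , drop = FALSE]
  ym <- format(ev$event_date, "%Y-%m")
  firsts <- !duplicated(paste(ev$person_id, ym))
  cand <- data.frame(person_id = ev$person_id[firsts],
                     date = ev$event_date[firsts], ym = ym[firsts],
                     stringsAsFactors = FALSE)
  i <- match(cand$person_id, observation_periods$person_id)
  ok <- as.integer(cand$date -
                     observation_periods$observation_period_start_date[i]) >=
    365 &
    cand$date <= observation_periods$observation_period_end_date[i]
  cand <- cand[ok, , drop = FALSE]
  pi <- match(cand$person_id, persons$person_id)
  cand_age <- as.integer(substr(cand$ym, 1, 4)) - persons$birth_year[pi]
  cand$key <- paste(persons$sex[pi], cand_age %/% 5, cand$ym)
  groups <- split(seq_len(nrow(cand)), cand$key)

  ci <- match(cohort$person_id, persons$person_id)
  case_age <- as.integer(format(cohort$index_date, "%Y")) -
    persons$birth_year[ci]
  case_key <- paste(persons$sex[ci], case_age %/% 5,
                    format(cohort$index_date, "%Y-%m"))

  used <- logical(nrow(cand))
  res <- vector("list", nrow(cohort))
  shortfall <- 0L
  ord <- order(cohort$person_id)
  for (k in ord) {
    avail <- groups[[case_key[k]]]
    avail <- avail[!used[avail]]
    # a person may appear under several candidate months; keep one row each
    avail <- avail[!duplicated(cand$person_id[avail])]
    take <- min(ratio, length(avail))
    if (take < ratio) shortfall <- shortfall + (ratio - take)
    if (take > 0) {
      pick <- avail[sample.int(length(avail), take)]
      used[pick] <- TRUE
      # block other months of the chosen persons
      used[cand$person_id %in% cand$person_id[pick]] <- TRUE
      res[[k]] <- data.frame(matched_case_id = cohort$person_id[k],
                             person_id = cand$person_id[pick],
                             index_date = cand$date[pick],
                             stringsAsFactors = FALSE)
    }
  }
  if (shortfall > 0) {
    warning("matching shortfall: ", shortfall, " control slot(s) unfilled",
            call. = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(matched_case_id = character(0),
                      person_id = character(0),
                      index_date = as.Date(character(0)),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
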