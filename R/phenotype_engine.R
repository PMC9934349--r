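#' Identifiers of the built-in phenotype algorithms
#'
#' Four SLE algorithms (incident/prevalent entry crossed with a single
#' diagnosis code or a confirmed second code, each correcting the index
#' date for prodromal events) plus the two comparator algorithms of
#' Barnado and colleagues (three diagnosis codes on distinct dates and
#' ever-use of an antimalarial, with or without exclusion of
#' dermatomyositis/systemic sclerosis).
#'
#' @return Character vector of algorithm ids.
#' @export
sle_algorithms <- function() {
  c("incident_1x", "incident_2x", "prevalent_1x", "prevalent_2x",
    "barnado_3x_am", "barnado_3x_am_excl")
}

#' Declarative specification of one phenotype algorithm
#'
#' Windows are in whole days and both endpoints of every window are
#' inclusive (the definitions are written as closed ranges: a confirmatory
#' code "31--365 days after the first code" admits day 31 and day 365).
#'
#' @param algorithm_id One of [sle_algorithms()].
#' @return An `algorithm_spec` list: `algorithm_id`, `washout_days` (365
#'   for incident entry, else 0), `correction_window_days` (90 for the
#'   four corrected algorithms, 0 for the comparators),
#'   `second_code_window` (`c(31, 365)` or `NULL`), `min_code_count`,
#'   `require_ever_antimalarial`, `exclusion_set_name` (or `NULL`).
#' @export
algorithm_spec <- function(algorithm_id) {
  specs <- list(
    incident_1x = list(washout_days = 365, correction_window_days = 90,
                       second_code_window = NULL, min_code_count = 1,
                       require_ever_antimalarial = FALSE,
                       exclusion_set_name = NULL),
    incident_2x = list(washout_days = 365, correction_window_days = 90,
                       second_code_window = c(31, 365), min_code_count = 2,
                       require_ever_antimalarial = FALSE,
                       exclusion_set_name = NULL),
    prevalent_1x = list(washout_days = 0, correction_window_days = 90,
                        second_code_window = NULL, min_code_count = 1,
                        require_ever_antimalarial = FALSE,
                        exclusion_set_name = NULL),
    prevalent_2x = list(washout_days = 0, correction_window_days = 90,
                        second_code_window = c(31, 365), min_code_count = 2,
                        require_ever_antimalarial = FALSE,
                        exclusion_set_name = NULL),
    barnado_3x_am = list(washout_days = 0, correction_window_days = 0,
                         second_code_window = NULL, min_code_count = 3,
                         require_ever_antimalarial = TRUE,
                         exclusion_set_name = NULL),
    barnado_3x_am_excl = list(washout_days = 0, correction_window_days = 0,
                              second_code_window = NULL, min_code_count = 3,
                              require_ever_antimalarial = TRUE,
                              exclusion_set_name = "barnado_exclusions")
  )
  if (!algorithm_id %in% names(specs)) {
    stop("unknown algorithm_id: '", algorithm_id, "' (expected one of ",
         paste(sle_algorithms(), collapse = ", "), ")", call. = FALSE)
  }
  structure(c(list(algorithm_id = algorithm_id), specs[[algorithm_id]]),
            class = "algorithm_spec")
}

.empty_cohort <- function(algorithm_id) {
  data.frame(algorithm_id = character(0), person_id = character(0),
             index_date = as.Date(character(0)),
             first_dx_date = as.Date(character(0)),
             entry_event_role = character(0), vocabulary = character(0),
             code = character(0), stringsAsFactors = FALSE)
}

#' Date of a person's earliest SLE diagnosis code
#'
#' @param events Event data frame for a single person.
#' @param registry A `concept_registry`.
#' @return A `Date`, or `NA` (length-one `Date`) if the person has no
#'   SLE diagnosis code.
#' @export
first_sle_code_date <- function(events, registry) {
  dx <- events[.has_role(events, registry, "sle_diagnosis"), , drop = FALSE]
  if (nrow(dx) == 0) return(as.Date(NA))
  min(dx$event_date)
}

#' Correct a cohort index date for prodromal signs, symptoms and drugs
#'
#' Early SLE is often coded only as nonspecific signs or symptoms (or
#' treated empirically) before the first diagnosis code appears, so the
#' first code systematically postdates disease onset. The correction
#' re-anchors cohort entry to the earliest sign/symptom or treatment-drug
#' event that precedes the first diagnosis code by 1 to `window_days`
#' days. Only events inside that window qualify; there is no chaining
#' through earlier events, and an event on the diagnosis date itself does
#' not move the index.
#'
#' @param events Event data frame for a single person.
#' @param first_dx_date The person's first SLE diagnosis code date.
#' @param registry A `concept_registry`.
#' @param window_days Maximum lead time in days (default 90).
#' @return List with `index_date`, `entry_event_role` (one of
#'   `sle_diagnosis`, `sle_sign_symptom`, `sle_treatment_drug`),
#'   `vocabulary` and `code` of the entry event.
#' @export
correct_index_date <- function(events, first_dx_date, registry,
                               window_days = 90) {
  stopifnot(!is.na(first_dx_date))
  gap <- as.integer(first_dx_date - events$event_date)
  is_prec <- .has_role(events, registry,
                       c("sle_sign_symptom", "sle_treatment_drug")) &
    gap >= 1L & gap <= window_days
  if (any(is_prec)) {
    prec <- events[is_prec, , drop = FALSE]
    is_sign <- .has_role(prec, registry, "sle_sign_symptom")
    role <- ifelse(is_sign, "sle_sign_symptom", "sle_treatment_drug")
    # deterministic tie-break on the earliest date: signs/symptoms before
    # drugs, then vocabulary, then code
    ord <- order(prec$event_date, role != "sle_sign_symptom",
                 prec$vocabulary, prec$code)
    pick <- ord[1]
    return(list(index_date = prec$event_date[pick],
                entry_event_role = role[pick],
                vocabulary = prec$vocabulary[pick], code = prec$code[pick]))
  }
  dx <- events[.has_role(events, registry, "sle_diagnosis") &
                 events$event_date == first_dx_date, , drop = FALSE]
  ord <- order(dx$vocabulary, dx$code)
  list(index_date = first_dx_date, entry_event_role = "sle_diagnosis",
       vocabulary = dx$vocabulary[ord[1]], code = dx$code[ord[1]])
}

#' Is a confirmatory second diagnosis code present?
#'
#' @param events Event data frame for a single person.
#' @param first_dx_date The first SLE diagnosis code date (the window is
#'   anchored here, not at the corrected index date).
#' @param registry A `concept_registry`.
#' @param window Inclusive day window, default `c(31, 365)`.
#' @return `TRUE` iff some SLE diagnosis code falls 31--365 days (both
#'   inclusive) after the first code.
#' @export
second_code_present <- function(events, first_dx_date, registry,
                                window = c(31, 365)) {
  stopifnot(!is.na(first_dx_date))
  dx <- events[.has_role(events, registry, "sle_diagnosis"), , drop = FALSE]
  gap <- as.integer(dx$event_date - first_dx_date)
  any(gap >= window[1] & gap <= window[2])
}

#' Is the incident-entry look-back requirement satisfied?
#'
#' Incident entry requires at least `washout_days` of continuous
#' observation before the (corrected) index date, so that the episode is
#' plausibly the first.
#'
#' @param index_date Candidate index date.
#' @param observation_period One-row data frame (or list) with
#'   `observation_period_start_date`.
#' @param washout_days Minimum prior observation, default 365. Zero (the
#'   prevalent algorithms) always passes.
#' @return Logical.
#' @export
lookback_satisfied <- function(index_date, observation_period,
                               washout_days = 365) {
  as.integer(index_date - observation_period$observation_period_start_date) >=
    washout_days
}

# One observation period per person, chosen as the period containing
# `anchor` (falling back to the latest period starting on or before it,
# then to the earliest period). Simulated data always has one period.
.person_periods <- function(observation_periods, person_ids, anchors) {
  ops <- observation_periods[observation_periods$person_id %in% person_ids, ,
                             drop = FALSE]
  if (!anyDuplicated(ops$person_id)) {
    i <- match(person_ids, ops$person_id)
    return(data.frame(person_id = person_ids,
                      start = ops$observation_period_start_date[i],
                      end = ops$observation_period_end_date[i]))
  }
  start <- as.Date(rep(NA, length(person_ids)))
  end <- start
  for (k in seq_along(person_ids)) {
    cand <- ops[ops$person_id == person_ids[k], , drop = FALSE]
    inside <- cand$observation_period_start_date <= anchors[k] &
      cand$observation_period_end_date >= anchors[k]
    if (any(inside)) {
      cand <- cand[inside, , drop = FALSE][1, ]
    } else {
      before <- cand$observation_period_start_date <= anchors[k]
      cand <- if (any(before)) {
        cand[before, , drop = FALSE][which.max(
          cand$observation_period_start_date[before]), ]
      } else {
        cand[which.min(cand$observation_period_start_date), ]
      }
    }
    start[k] <- cand$observation_period_start_date
    end[k] <- cand$observation_period_end_date
  }
  data.frame(person_id = person_ids, start = start, end = end)
}

#' Build a phenotype cohort
#'
#' Applies one algorithm to a whole database. Per person: locate the first
#' SLE diagnosis code; for the `*_2x` algorithms require a confirmatory
#' code 31--365 days after it; re-anchor the index date to a qualifying
#' prodromal event ([correct_index_date()]); for the `incident_*`
#' algorithms require 365 days of observation before the corrected index
#' ([lookback_satisfied()]). Each person enters at most once. The result
#' is deterministic and independent of event ordering.
#'
#' @param spec An `algorithm_spec` or an algorithm id string.
#' @param db An `sle_database`.
#' @param registry A `concept_registry`; defaults to the shipped sets.
#' @param correct_index Set `FALSE` to disable index-date correction (used
#'   to quantify the benefit of the correction); entry is then always the
#'   first diagnosis code.
#' @return Data frame of cohort entries: `algorithm_id`, `person_id`,
#'   `index_date`, `first_dx_date`, `entry_event_role`, `vocabulary`,
#'   `code`, sorted by `person_id`.
#' @export
build_cohort <- function(spec, db, registry = default_concept_sets(),
                         correct_index = TRUE) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  stopifnot(inherits(spec, "algorithm_spec"), inherits(db, "sle_database"))
  if (spec$require_ever_antimalarial) {
    return(build_barnado_cohort(spec$algorithm_id, db, registry))
  }
  ev <- db$event
  if (nrow(ev) == 0) return(.empty_cohort(spec$algorithm_id))

  dx <- ev[.has_role(ev, registry, "sle_diagnosis"), , drop = FALSE]
  if (nrow(dx) == 0) return(.empty_cohort(spec$algorithm_id))
  ord <- order(dx$person_id, dx$event_date, dx$vocabulary, dx$code)
  dx <- dx[ord, , drop = FALSE]
  first <- dx[!duplicated(dx$person_id), , drop = FALSE]
  entry <- data.frame(person_id = first$person_id,
                      first_dx_date = first$event_date,
                      index_date = first$event_date,
                      entry_event_role = "sle_diagnosis",
                      vocabulary = first$vocabulary, code = first$code,
                      stringsAsFactors = FALSE)

  if (!is.null(spec$second_code_window)) {
    w <- spec$second_code_window
    gap <- as.integer(dx$event_date -
                        entry$first_dx_date[match(dx$person_id,
                                                  entry$person_id)])
    confirmed <- unique(dx$person_id[gap >= w[1] & gap <= w[2]])
    entry <- entry[entry$person_id %in% confirmed, , drop = FALSE]
    if (nrow(entry) == 0) return(.empty_cohort(spec$algorithm_id))
  }

  if (correct_index && spec$correction_window_days > 0) {
    prec <- ev[.has_role(ev, registry,
                         c("sle_sign_symptom", "sle_treatment_drug")), ,
               drop = FALSE]
    prec <- prec[prec$person_id %in% entry$person_id, , drop = FALSE]
    if (nrow(prec) > 0) {
      fdx <- entry$first_dx_date[match(prec$person_id, entry$person_id)]
      gap <- as.integer(fdx - prec$event_date)
      prec <- prec[gap >= 1L & gap <= spec$correction_window_days, ,
                   drop = FALSE]
      if (nrow(prec) > 0) {
        is_sign <- .has_role(prec, registry, "sle_sign_symptom")
        role <- ifelse(is_sign, "sle_sign_symptom", "sle_treatment_drug")
        ordp <- order(prec$person_id, prec$event_date,
                      role != "sle_sign_symptom", prec$vocabulary, prec$code)
        prec <- prec[ordp, , drop = FALSE]
        role <- role[ordp]
        keep <- !duplicated(prec$person_id)
        prec <- prec[keep, , drop = FALSE]
        role <- role[keep]
        i <- match(prec$person_id, entry$person_id)
        entry$index_date[i] <- prec$event_date
        entry$entry_event_role[i] <- role
        entry$vocabulary[i] <- prec$vocabulary
        entry$code[i] <- prec$code
      }
    }
  }

  if (spec$washout_days > 0) {
    pp <- .person_periods(db$observation_period, entry$person_id,
                          entry$first_dx_date)
    ok <- as.integer(entry$index_date - pp$start) >= spec$washout_days
    entry <- entry[ok, , drop = FALSE]
  }

  if (nrow(entry) == 0) return(.empty_cohort(spec$algorithm_id))
  out <- data.frame(algorithm_id = spec$algorithm_id,
                    person_id = entry$person_id,
                    index_date = entry$index_date,
                    first_dx_date = entry$first_dx_date,
                    entry_event_role = entry$entry_event_role,
                    vocabulary = entry$vocabulary, code = entry$code,
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a Barnado-style comparator cohort
#'
#' Inclusion: at least three SLE diagnosis codes on distinct calendar
#' dates (distinct dates guard against same-day duplicate billing rows)
#' and at least one antimalarial exposure at any time. The `_excl` variant
#' additionally excludes anyone ever coded for dermatomyositis or systemic
#' sclerosis. The index date is the later of the third distinct-date SLE
#' code and the first antimalarial; no index-date correction is applied.
#'
#' @param variant `"barnado_3x_am"` or `"barnado_3x_am_excl"`.
#' @param db An `sle_database`.
#' @param registry A `concept_registry` containing `antimalarial` and (for
#'   the exclusion variant) `exclusion_dx` sets.
#' @return Cohort data frame as in [build_cohort()]. `first_dx_date` is
#'   the first SLE code; the index may postdate it.
#' @export
build_barnado_cohort <- function(variant, db,
                                 registry = default_concept_sets()) {
  stopifnot(variant %in% c("barnado_3x_am", "barnado_3x_am_excl"),
            inherits(db, "sle_database"))
  ev <- db$event
  if (nrow(ev) == 0) return(.empty_cohort(variant))

  dx <- ev[.has_role(ev, registry, "sle_diagnosis"), , drop = FALSE]
  ord <- order(dx$person_id, dx$event_date, dx$vocabulary, dx$code)
  dx <- dx[ord, , drop = FALSE]
  # distinct (person, date)
  dxd <- dx[!duplicated(paste(dx$person_id, dx$event_date)), , drop = FALSE]
  cnt <- table(dxd$person_id)
  qual_dx <- names(cnt)[cnt >= 3]

  am <- ev[.has_role(ev, registry, "antimalarial"), , drop = FALSE]
  orda <- order(am$person_id, am$event_date, am$vocabulary, am$code)
  am <- am[orda, , drop = FALSE]
  first_am <- am[!duplicated(am$person_id), , drop = FALSE]

  ids <- intersect(qual_dx, first_am$person_id)
  if (variant == "barnado_3x_am_excl") {
    excl <- ev[.has_role(ev, registry, "exclusion_dx"), , drop = FALSE]
    ids <- setdiff(ids, unique(excl$person_id))
  }
  if (length(ids) == 0) return(.empty_cohort(variant))
  ids <- sort(ids)

  dxd <- dxd[dxd$person_id %in% ids, , drop = FALSE]
  third <- do.call(rbind, lapply(split(dxd, dxd$person_id), function(d) d[3, ]))
  first_dx <- dxd[!duplicated(dxd$person_id), , drop = FALSE]
  third <- third[match(ids, third$person_id), , drop = FALSE]
  first_dx <- first_dx[match(ids, first_dx$person_id), , drop = FALSE]
  fam <- first_am[match(ids, first_am$person_id), , drop = FALSE]

  am_later <- fam$event_date > third$event_date
  out <- data.frame(
    algorithm_id = variant, person_id = ids,
    index_date = as.Date(ifelse(am_later, fam$event_date, third$event_date),
                         origin = "1970-01-01"),
    first_dx_date = first_dx$event_date,
    entry_event_role = ifelse(am_later, "sle_treatment_drug", "sle_diagnosis"),
    vocabulary = ifelse(am_later, fam$vocabulary, third$vocabulary),
    code = ifelse(am_later, fam$code, third$code),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat("<algorithm_spec>", x$algorithm_id, "\n")
  cat("  washout:", x$washout_days, "days; correction window:",
      x$correction_window_days, "days\n")
  if (!is.null(x$second_code_window)) {
    cat("  second code:", x$second_code_window[1], "-",
        x$second_code_window[2], "days after first code\n")
  }
  if (x$require_ever_antimalarial) {
    cat("  requires >=", x$min_code_count,
        "distinct-date codes and ever antimalarial\n")
  }
  if (!is.null(x$exclusion_set_name)) {
    cat("  exclusions:", x$exclusion_set_name, "\n")
  }
  invisible(x)
}
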