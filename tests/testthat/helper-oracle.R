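# Brute-force reference implementations, written as literal per-person
# loops over every rule, independent of the vectorised production path.

oracle_roles <- function(vocabulary, code, registry) {
  classify_event(list(vocabulary = vocabulary, code = code), registry)
}

# literal transcription of the entry rules for one person
oracle_person_entry <- function(spec, events, period, registry) {
  if (nrow(events) == 0) return(NULL)
  roles <- lapply(seq_len(nrow(events)), function(i) {
    oracle_roles(events$vocabulary[i], events$code[i], registry)
  })
  dx_dates <- events$event_date[vapply(roles, function(r) {
    "sle_diagnosis" %in% r
  }, logical(1))]
  if (length(dx_dates) == 0) return(NULL)
  first_dx <- min(dx_dates)

  if (!is.null(spec$second_code_window)) {
    ok <- FALSE
    for (d in as.integer(dx_dates)) {
      gap <- d - as.integer(first_dx)
      if (gap >= spec$second_code_window[1] &&
          gap <= spec$second_code_window[2]) ok <- TRUE
    }
    if (!ok) return(NULL)
  }

  index <- first_dx
  if (spec$correction_window_days > 0) {
    prec_dates <- as.Date(character(0))
    for (i in seq_len(nrow(events))) {
      gap <- as.integer(first_dx - events$event_date[i])
      if (any(c("sle_sign_symptom", "sle_treatment_drug") %in% roles[[i]]) &&
          gap >= 1 && gap <= spec$correction_window_days) {
        prec_dates <- c(prec_dates, events$event_date[i])
      }
    }
    if (length(prec_dates) > 0) index <- min(prec_dates)
  }

  if (spec$washout_days > 0) {
    if (as.integer(index - period$observation_period_start_date) <
        spec$washout_days) {
      return(NULL)
    }
  }
  list(index_date = index, first_dx_date = first_dx)
}

oracle_barnado_entry <- function(variant, events, registry) {
  if (nrow(events) == 0) return(NULL)
  roles <- lapply(seq_len(nrow(events)), function(i) {
    oracle_roles(events$vocabulary[i], events$code[i], registry)
  })
  has <- function(i, r) r %in% roles[[i]]
  dx_dates <- sort(unique(events$event_date[sapply(seq_len(nrow(events)),
                                                   has, "sle_diagnosis")]))
  am_dates <- events$event_date[sapply(seq_len(nrow(events)), has,
                                       "antimalarial")]
  if (length(dx_dates) < 3 || length(am_dates) == 0) return(NULL)
  if (variant == "barnado_3x_am_excl" &&
      any(sapply(seq_len(nrow(events)), has, "exclusion_dx"))) {
    return(NULL)
  }
  list(index_date = max(dx_dates[3], min(am_dates)),
       first_dx_date = dx_dates[1])
}

oracle_cohort <- function(algorithm_id, db, registry) {
  spec <- algorithm_spec(algorithm_id)
  out <- NULL
  for (pid in db$person$person_id) {
    events <- db$event[db$event$person_id == pid, , drop = FALSE]
    if (spec$require_ever_antimalarial) {
      entry <- oracle_barnado_entry(algorithm_id, events, registry)
    } else {
      period <- db$observation_period[
        db$observation_period$person_id == pid, , drop = FALSE]
      entry <- oracle_person_entry(spec, events, period, registry)
    }
    if (!is.null(entry)) {
      out <- rbind(out, data.frame(person_id = pid,
                                   index_date = entry$index_date,
                                   first_dx_date = entry$first_dx_date,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(person_id = character(0),
                      index_date = as.Date(character(0)),
                      first_dx_date = as.Date(character(0)))
  }
  out[order(out$person_id), , drop = FALSE]
}

# literal confusion tally over every person
oracle_confusion <- function(cohort, ground_truth, persons,
                             observation_periods) {
  tp <- fp <- tn <- fn <- 0L
  for (pid in persons$person_id) {
    g <- ground_truth[ground_truth$person_id == pid, ]
    op <- observation_periods[observation_periods$person_id == pid, ]
    if (g$has_sle) {
      if (is.na(g$onset_date) ||
          g$onset_date < op$observation_period_start_date ||
          g$onset_date > op$observation_period_end_date) next
    }
    pos <- pid %in% cohort$person_id
    if (g$has_sle && pos) tp <- tp + 1L
    if (g$has_sle && !pos) fn <- fn + 1L
    if (!g$has_sle && pos) fp <- fp + 1L
    if (!g$has_sle && !pos) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
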