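# In-code fixture builders: no fixture files, everything is constructed here.

toy_db <- function(person, observation_period, event = NULL,
                   ground_truth = NULL) {
  if (is.null(event)) {
    event <- data.frame(person_id = character(0),
                        event_date = as.Date(character(0)),
                        domain = character(0), vocabulary = character(0),
                        code = character(0), visit_context = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(person = person, observation_period = observation_period,
                 event = event, ground_truth = ground_truth),
            class = "sle_database")
}

persons_df <- function(ids, sex = "female", birth_year = 1970L) {
  data.frame(person_id = ids, sex = rep_len(sex, length(ids)),
             birth_year = rep_len(as.integer(birth_year), length(ids)),
             stringsAsFactors = FALSE)
}

periods_df <- function(ids, start, end) {
  data.frame(person_id = ids,
             observation_period_start_date = as.Date(rep_len(start, length(ids))),
             observation_period_end_date = as.Date(rep_len(end, length(ids))),
             stringsAsFactors = FALSE)
}

events_df <- function(person_id, event_date, vocabulary, code,
                      domain = "condition", visit_context = "outpatient") {
  n <- length(event_date)
  data.frame(person_id = rep_len(person_id, n),
             event_date = as.Date(event_date),
             domain = rep_len(domain, n),
             vocabulary = rep_len(vocabulary, n),
             code = rep_len(code, n),
             visit_context = rep_len(visit_context, n),
             stringsAsFactors = FALSE)
}

# A single-person database whose observation starts at `origin`; event
# positions are given in days since `origin` (day 0 = observation start).
day_db <- function(dx_days = integer(0), sign_days = integer(0),
                   drug_days = integer(0), am_days = integer(0),
                   excl_days = integer(0), obs_len = 3000,
                   origin = as.Date("2015-01-01"), id = "p1") {
  ev <- rbind(
    events_df(id, origin + dx_days, "ICD9CM", "710.0"),
    events_df(id, origin + sign_days, "ICD10CM", "R53.81"),
    events_df(id, origin + drug_days, "RxNorm", "8640", domain = "drug"),
    events_df(id, origin + am_days, "RxNorm", "5521", domain = "drug"),
    events_df(id, origin + excl_days, "ICD9CM", "710.3"))
  toy_db(persons_df(id), periods_df(id, origin, origin + obs_len), ev)
}

# Random tiny database (<= 20 persons) drawing from known and junk codes;
# used for brute-force oracle agreement.
random_small_db <- function(seed) {
  set.seed(seed)
  n <- sample.int(20, 1)
  ids <- sprintf("r%02d", seq_len(n))
  origin <- as.Date("2012-01-01")
  start <- origin + sample.int(400, n, replace = TRUE)
  len <- sample(30:2200, n, replace = TRUE)
  codebook <- rbind(
    data.frame(vocabulary = "ICD9CM", code = "710.0", domain = "condition"),
    data.frame(vocabulary = "SNOMED", code = "257628", domain = "condition"),
    data.frame(vocabulary = "ICD10CM", code = "R53.81", domain = "condition"),
    data.frame(vocabulary = "ICD10CM", code = "M54.5", domain = "condition"),
    data.frame(vocabulary = "RxNorm", code = "8640", domain = "drug"),
    data.frame(vocabulary = "RxNorm", code = "5521", domain = "drug"),
    data.frame(vocabulary = "RxNorm", code = "2393", domain = "drug"),
    data.frame(vocabulary = "ICD9CM", code = "710.3", domain = "condition"),
    data.frame(vocabulary = "ICD9CM", code = "710.1", domain = "condition"),
    data.frame(vocabulary = "ICD10CM", code = "Z99.9", domain = "condition"))
  ev <- NULL
  for (i in seq_len(n)) {
    k <- stats::rpois(1, 4)
    if (k == 0) next
    pick <- sample.int(nrow(codebook), k, replace = TRUE)
    # allow events slightly outside the period to exercise edge rules
    d <- start[i] + sample((-30):(len[i] + 30), k, replace = TRUE)
    ev <- rbind(ev, events_df(ids[i], d, codebook$vocabulary[pick],
                              codebook$code[pick],
                              domain = codebook$domain[pick]))
  }
  toy_db(persons_df(ids, sex = sample(c("female", "male"), n, TRUE)),
         periods_df(ids, start, start + len), ev)
}

# shuffle event rows to probe order-independence
shuffle_events <- function(db, seed = 99) {
  set.seed(seed)
  if (nrow(db$event) > 1) {
    db$event <- db$event[sample.int(nrow(db$event)), , drop = FALSE]
    rownames(db$event) <- NULL
  }
  db
}
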