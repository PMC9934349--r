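registry <- default_concept_sets()

test_that("cohort counts and overlap follow person-level set algebra", {
  db <- simulate_population(simulation_config(
    n_persons = 8000, seed = 41, sle_incidence_per_100k_py = 2000))
  c1 <- build_cohort("incident_1x", db, registry)
  c2 <- build_cohort("incident_2x", db, registry)
  counts <- cohort_counts(list(c1, c2))
  expect_equal(counts$n_persons[counts$algorithm_id == "incident_1x"],
               nrow(c1))
  # confirmed-code cohorts can never be larger
  expect_lte(nrow(c2), nrow(c1))

  expect_equal(overlap(c1, c1), c(n_only_a = 0, n_both = nrow(c1),
                                  n_only_b = 0))
  # every confirmed-code member is also a single-code member
  expect_equal(unname(overlap(c2, c1)["n_only_a"]), 0)
  dis_a <- data.frame(person_id = c("x1", "x2"))
  dis_b <- data.frame(person_id = "y1")
  expect_equal(unname(overlap(dis_a, dis_b)["n_both"]), 0)

  expect_equal(nrow(cohort_counts(list(c1[0, ], c2[0, ]))), 0)
})

test_that("incidence rates are events per 100,000 person-years at risk", {
  # 625 persons, each contributing exactly 20 years at risk after the
  # 365-day run-in; two of them enter the cohort on their last at-risk day
  n <- 625
  ids <- sprintf("i%03d", 1:n)
  start <- as.Date("1990-01-01")
  persons <- persons_df(ids)
  periods <- periods_df(ids, start, start + 365 + 7304)
  cohort <- data.frame(person_id = ids[1:2],
                       index_date = start + 365 + 7304)
  ir <- incidence_rate(cohort, persons, periods)
  expect_equal(ir$person_years, n * 7305 / 365.25)  # 12,500 PY
  expect_equal(ir$rate_per_100k, 16.0)

  # an empty cohort has rate zero
  ir0 <- incidence_rate(cohort[0, ], persons, periods)
  expect_equal(ir0$events, 0)
  expect_equal(ir0$rate_per_100k, 0)

  # a person observed under a year contributes nothing
  short <- periods_df("s1", start, start + 200)
  expect_warning(irs <- incidence_rate(cohort[0, ], persons_df("s1"), short),
                 "no person-time")
  expect_equal(nrow(irs), 0)
})

test_that("stratified person-time and events sum to their totals", {
  db <- simulate_population(simulation_config(
    n_persons = 5000, seed = 13, sle_incidence_per_100k_py = 2000))
  co <- build_cohort("incident_1x", db, registry)
  total <- incidence_rate(co, db$person, db$observation_period)
  by <- incidence_rate(co, db$person, db$observation_period,
                       strata = c("age_band", "sex", "year"))
  expect_equal(sum(by$events), total$events)
  expect_equal(sum(by$person_years), total$person_years, tolerance = 1e-8)
})

test_that("standardized differences reproduce published pairs and are
           antisymmetric", {
  expect_equal(round(smd_binary(0.27, 0.15), 2), 0.21)
  expect_equal(round(smd_binary(0.83, 0.49), 2), 0.54)
  expect_equal(round(smd_binary(0.29, 0.15), 2), 0.24)
  expect_equal(smd_binary(0.4, 0.4), 0)
  for (p in list(c(0.3, 0.6), c(0.01, 0.9), c(0.5, 0.5))) {
    expect_equal(smd_binary(p[1], p[2]), -smd_binary(p[2], p[1]))
  }
  # the textbook pooled denominator differs by sqrt(2)
  expect_equal(smd_binary(0.3, 0.1, pooled = TRUE),
               sqrt(2) * smd_binary(0.3, 0.1))
  expect_warning(v <- smd_binary(0, 0), "undefined")
  expect_true(is.na(v))
})

test_that("temporal characterization tallies persons per window and set", {
  origin <- as.Date("2015-06-01")
  co <- data.frame(person_id = c("a", "b"), index_date = origin)
  ev <- rbind(
    events_df("a", origin - 10, "ICD10CM", "R53.81"),  # [-30,-1]
    events_df("a", origin + 100, "ICD9CM", "710.0"),   # [31,365]
    events_df("b", origin + 100, "ICD9CM", "710.0"),
    events_df("b", origin, "RxNorm", "5521", domain = "drug"))  # [0,0]
  tc <- temporal_characterization(co, ev, registry)
  get <- function(w, s) tc$proportion[tc$window == w & tc$concept_set == s]
  expect_equal(get("[31,365]", "sle_diagnosis"), 1)
  expect_equal(get("[-30,-1]", "sle_signs_symptoms"), 0.5)
  expect_equal(get("[0,0]", "antimalarials"), 0.5)
  expect_equal(get("[0,0]", "sle_treatment_drugs"), 0.5)
  expect_equal(get("[-365,-31]", "sle_diagnosis"), 0)
  expect_true(all(tc$proportion >= 0 & tc$proportion <= 1))

  # a union window can only contain at least as many persons as its parts
  wide <- temporal_characterization(co, ev, registry,
                                    windows = data.frame(start = c(1, 31, 1),
                                                         end = c(30, 365, 365)))
  expect_gte(wide$proportion[wide$window == "[1,365]" &
                               wide$concept_set == "sle_diagnosis"],
             max(wide$proportion[wide$window != "[1,365]" &
                                   wide$concept_set == "sle_diagnosis"]))
})

test_that("entry-role breakdown sums to one and collapses without
           correction", {
  db <- simulate_population(simulation_config(
    n_persons = 20000, seed = 3, sle_incidence_per_100k_py = 2000))
  co <- build_cohort("prevalent_1x", db, registry)
  bd <- index_event_breakdown(co)
  expect_equal(sum(bd$fraction), 1)
  co_raw <- build_cohort("prevalent_1x", db, registry, correct_index = FALSE)
  bd_raw <- index_event_breakdown(co_raw)
  expect_equal(bd_raw$entry_event_role, "sle_diagnosis")
  expect_equal(bd_raw$fraction, 1)
})

test_that("index-date correction strictly reduces the mean onset error", {
  db <- simulate_population(simulation_config(
    n_persons = 30000, seed = 77, sle_incidence_per_100k_py = 1000))
  corrected <- build_cohort("prevalent_1x", db, registry)
  uncorrected <- build_cohort("prevalent_1x", db, registry,
                              correct_index = FALSE)
  e_c <- index_date_error(corrected, db$ground_truth)
  e_u <- index_date_error(uncorrected, db$ground_truth)
  expect_lt(e_c$mean_abs_days, e_u$mean_abs_days)
  expect_gte(e_c$fraction_exact, e_u$fraction_exact)
})

test_that("matching fills 1:10 with balanced matched variables", {
  db <- simulate_population(simulation_config(
    n_persons = 40000, seed = 21, sle_incidence_per_100k_py = 500))
  co <- build_cohort("incident_2x", db, registry)
  expect_gt(nrow(co), 5)
  m <- suppressWarnings(
    match_controls(co, db$person, db$observation_period, db$event,
                   ratio = 10, seed = 9))
  # determinism under the seed
  m2 <- suppressWarnings(
    match_controls(co, db$person, db$observation_period, db$event,
                   ratio = 10, seed = 9))
  expect_identical(m, m2)
  expect_lte(max(table(m$matched_case_id)), 10)
  # controls are unique and outside the cohort
  expect_false(any(duplicated(m$person_id)))
  expect_length(intersect(m$person_id, co$person_id), 0)
  # matched variables are balanced exactly: sex identical within pair sets
  sex_case <- db$person$sex[match(m$matched_case_id, db$person$person_id)]
  sex_ctrl <- db$person$sex[match(m$person_id, db$person$person_id)]
  expect_equal(sex_case, sex_ctrl)
  ym_case <- format(co$index_date[match(m$matched_case_id, co$person_id)],
                    "%Y-%m")
  expect_equal(ym_case, format(m$index_date, "%Y-%m"))
  # every control carries >= 365 days of prior observation
  i <- match(m$person_id, db$observation_period$person_id)
  lb <- as.integer(m$index_date -
    db$observation_period$observation_period_start_date[i])
  expect_true(all(lb >= 365))
})

test_that("a control with short look-back is never selected", {
  origin <- as.Date("2015-06-01")
  persons <- persons_df(c("case", "good", "bad"))
  periods <- rbind(periods_df("case", origin - 400, origin + 100),
                   periods_df("good", origin - 400, origin + 100),
                   periods_df("bad", origin - 200, origin + 100))
  co <- data.frame(person_id = "case", index_date = origin)
  ev <- rbind(events_df("good", origin + 3, "ICD10CM", "M54.5"),
              events_df("bad", origin + 3, "ICD10CM", "M54.5"))
  m <- suppressWarnings(match_controls(co, persons, periods, ev,
                                       ratio = 10, seed = 1))
  expect_equal(m$person_id, "good")
})
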