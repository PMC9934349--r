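registry <- default_concept_sets()
origin <- as.Date("2015-01-01")

test_that("first_sle_code_date takes the earliest diagnosis code", {
  db <- day_db(dx_days = c(100, 40))
  expect_equal(first_sle_code_date(db$event, registry), origin + 40)
  # ties on the earliest day are harmless
  db2 <- day_db(dx_days = c(40, 40, 100))
  expect_equal(first_sle_code_date(db2$event, registry), origin + 40)
  expect_true(is.na(first_sle_code_date(day_db(sign_days = 5)$event,
                                        registry)))
})

test_that("index correction re-anchors to qualifying precursors only", {
  # no precursors: index stays at the first diagnosis code
  db <- day_db(dx_days = 100)
  r <- correct_index_date(db$event, origin + 100, registry)
  expect_equal(r$index_date, origin + 100)
  expect_equal(r$entry_event_role, "sle_diagnosis")

  # malaise 60 days before the first code qualifies
  db <- day_db(dx_days = 100, sign_days = 40)
  r <- correct_index_date(db$event, origin + 100, registry)
  expect_equal(r$index_date, origin + 40)
  expect_equal(r$entry_event_role, "sle_sign_symptom")

  # a precursor 95 days out is beyond the window; the 50-day one anchors
  db <- day_db(dx_days = 100, sign_days = c(5, 50))
  r <- correct_index_date(db$event, origin + 100, registry)
  expect_equal(r$index_date, origin + 50)

  # drugs participate on equal footing with signs/symptoms
  db <- day_db(dx_days = 100, drug_days = 30)
  r <- correct_index_date(db$event, origin + 100, registry)
  expect_equal(r$index_date, origin + 30)
  expect_equal(r$entry_event_role, "sle_treatment_drug")

  # same-day event (gap 0) never moves the index
  db <- day_db(dx_days = 100, sign_days = 100)
  r <- correct_index_date(db$event, origin + 100, registry)
  expect_equal(r$index_date, origin + 100)
})

test_that("the confirmatory-code window is closed at 31 and 365 days", {
  first <- origin + 10
  present <- function(gap) {
    second_code_present(day_db(dx_days = c(10, 10 + gap))$event, first,
                        registry)
  }
  expect_true(present(31))
  expect_false(present(30))
  expect_true(present(365))
  expect_false(present(366))
  expect_false(second_code_present(day_db(dx_days = 10)$event, first,
                                   registry))
})

test_that("look-back boundary sits exactly at the washout length", {
  op <- list(observation_period_start_date = origin)
  expect_true(lookback_satisfied(origin + 400, op))
  expect_true(lookback_satisfied(origin + 365, op))
  expect_false(lookback_satisfied(origin + 364, op))
  expect_true(lookback_satisfied(origin, op, washout_days = 0))
})

test_that("build_cohort composes the entry rules as specified", {
  # one code 400 days in, no precursors: incident_1x and prevalent_1x only
  db <- day_db(dx_days = 400)
  expect_equal(nrow(build_cohort("incident_1x", db, registry)), 1)
  expect_equal(nrow(build_cohort("prevalent_1x", db, registry)), 1)
  expect_equal(nrow(build_cohort("incident_2x", db, registry)), 0)
  expect_equal(nrow(build_cohort("prevalent_2x", db, registry)), 0)

  # adding a second code 200 days later admits the 2x algorithms too
  db <- day_db(dx_days = c(400, 600))
  for (a in c("incident_1x", "incident_2x", "prevalent_1x", "prevalent_2x")) {
    co <- build_cohort(a, db, registry)
    expect_equal(co$person_id, "p1")
    expect_equal(co$index_date, origin + 400)
  }

  # a precursor pulling the index to day 350 breaks the incident washout
  # but not prevalent entry
  db <- day_db(dx_days = c(400, 600), sign_days = 350)
  expect_equal(nrow(build_cohort("incident_1x", db, registry)), 0)
  expect_equal(nrow(build_cohort("incident_2x", db, registry)), 0)
  co <- build_cohort("prevalent_2x", db, registry)
  expect_equal(co$index_date, origin + 350)
  expect_equal(co$entry_event_role, "sle_sign_symptom")
  expect_equal(co$first_dx_date, origin + 400)

  expect_error(build_cohort("nonsense", db, registry), "unknown algorithm_id")
})

test_that("comparator cohorts need 3 distinct-date codes plus antimalarial", {
  # three distinct days + hydroxychloroquine: included
  db <- day_db(dx_days = c(10, 50, 90), am_days = 200)
  co <- build_barnado_cohort("barnado_3x_am", db, registry)
  expect_equal(co$person_id, "p1")
  # index is the later of the third code and the first antimalarial
  expect_equal(co$index_date, origin + 200)
  expect_equal(co$first_dx_date, origin + 10)

  # antimalarial before the third code: index at the third code
  db <- day_db(dx_days = c(10, 50, 90), am_days = 5)
  co <- build_barnado_cohort("barnado_3x_am", db, registry)
  expect_equal(co$index_date, origin + 90)

  # three rows on two distinct days: excluded
  db <- day_db(dx_days = c(10, 10, 50), am_days = 200)
  expect_equal(nrow(build_barnado_cohort("barnado_3x_am", db, registry)), 0)

  # no antimalarial: excluded
  db <- day_db(dx_days = c(10, 50, 90))
  expect_equal(nrow(build_barnado_cohort("barnado_3x_am", db, registry)), 0)

  # dermatomyositis code drops the person from the exclusion variant only
  db <- day_db(dx_days = c(10, 50, 90), am_days = 200, excl_days = 500)
  expect_equal(nrow(build_barnado_cohort("barnado_3x_am", db, registry)), 1)
  expect_equal(nrow(build_barnado_cohort("barnado_3x_am_excl", db, registry)),
               0)
})

test_that("vectorised cohorts agree with the brute-force oracle and obey
           subset, nesting, index-bound and determinism invariants", {
  algos <- c("incident_1x", "incident_2x", "prevalent_1x", "prevalent_2x",
             "barnado_3x_am", "barnado_3x_am_excl")
  for (seed in 1:60) {
    db <- random_small_db(seed)
    cos <- lapply(algos, function(a) build_cohort(a, db, registry))
    names(cos) <- algos
    for (a in algos) {
      ref <- oracle_cohort(a, db, registry)
      got <- cos[[a]]
      expect_equal(got$person_id, ref$person_id,
                   info = paste("membership", a, "seed", seed))
      expect_equal(got$index_date, ref$index_date,
                   info = paste("index", a, "seed", seed))
      expect_equal(got$first_dx_date, ref$first_dx_date,
                   info = paste("first_dx", a, "seed", seed))
    }
    # 2x is a subset of 1x; incident nests inside prevalent
    expect_in(cos$incident_2x$person_id, cos$incident_1x$person_id)
    expect_in(cos$prevalent_2x$person_id, cos$prevalent_1x$person_id)
    expect_in(cos$incident_1x$person_id, cos$prevalent_1x$person_id)
    expect_in(cos$incident_2x$person_id, cos$prevalent_2x$person_id)
    # corrected index precedes the first code by at most 90 days
    for (a in algos[1:4]) {
      gap <- as.integer(cos[[a]]$first_dx_date - cos[[a]]$index_date)
      expect_true(all(gap >= 0 & gap <= 90), info = paste(a, "seed", seed))
    }
    # event order must not matter
    shuffled <- build_cohort("prevalent_2x", shuffle_events(db, seed + 1),
                             registry)
    expect_equal(shuffled, cos$prevalent_2x)
  }
})
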