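registry <- default_concept_sets()

test_that("an empty database with valid headers loads as empty collections", {
  dir <- withr::local_tempdir()
  writeLines("person_id,sex,birth_year", file.path(dir, "person.csv"))
  writeLines(paste0("person_id,observation_period_start_date,",
                    "observation_period_end_date"),
             file.path(dir, "observation_period.csv"))
  writeLines("person_id,condition_start_date,vocabulary,code,visit_context",
             file.path(dir, "condition_occurrence.csv"))
  writeLines("person_id,drug_exposure_start_date,vocabulary,code,visit_context",
             file.path(dir, "drug_exposure.csv"))
  db <- load_database(dir)
  expect_s3_class(db, "sle_database")
  expect_equal(nrow(db$person), 0)
  expect_equal(nrow(db$event), 0)
  expect_null(db$ground_truth)
})

test_that("write then load round-trips a simulated database exactly", {
  db <- simulate_population(simulation_config(n_persons = 300, seed = 5,
                                              sle_incidence_per_100k_py = 3000))
  dir <- withr::local_tempdir()
  write_database(db, dir)
  expect_setequal(list.files(dir),
                  c("person.csv", "observation_period.csv",
                    "condition_occurrence.csv", "drug_exposure.csv",
                    "ground_truth.csv"))
  back <- load_database(dir)
  # loader interleaves conditions and drugs differently; compare sorted
  canon <- function(ev) {
    ev <- ev[do.call(order, ev), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  }
  expect_equal(back$person, db$person)
  expect_equal(back$observation_period, db$observation_period)
  expect_equal(canon(back$event), canon(db$event))
  expect_equal(back$ground_truth, db$ground_truth)
})

test_that("referential and parse errors are fatal and name the offender", {
  db <- simulate_population(simulation_config(n_persons = 20, seed = 2))
  dir <- withr::local_tempdir()
  write_database(db, dir)
  cond <- read.csv(file.path(dir, "condition_occurrence.csv"),
                   colClasses = "character")
  cond <- rbind(cond, data.frame(person_id = "ghost_person",
                                 condition_start_date = "2015-01-01",
                                 vocabulary = "ICD9CM", code = "710.0",
                                 visit_context = "outpatient"))
  write.csv(cond, file.path(dir, "condition_occurrence.csv"),
            row.names = FALSE)
  expect_error(load_database(dir), "ghost_person")

  cond2 <- cond[1, , drop = FALSE]
  cond2$condition_start_date <- "not-a-date"
  write.csv(cond2, file.path(dir, "condition_occurrence.csv"),
            row.names = FALSE)
  expect_error(load_database(dir), "row 1")

  file.remove(file.path(dir, "drug_exposure.csv"))
  expect_error(load_database(dir), "drug_exposure.csv")
})

test_that("the shipped concept sets carry the documented roles and codes", {
  expect_setequal(
    classify_event(list(vocabulary = "ICD9CM", code = "710.0"), registry),
    "sle_diagnosis")
  expect_setequal(
    classify_event(list(vocabulary = "SNOMED", code = "257628"), registry),
    "sle_diagnosis")
  expect_setequal(
    classify_event(list(vocabulary = "ICD10CM", code = "M32.9"), registry),
    "sle_diagnosis")
  # hydroxychloroquine carries both drug roles
  expect_setequal(
    classify_event(list(vocabulary = "RxNorm", code = "5521"), registry),
    c("sle_treatment_drug", "antimalarial"))
  # unknown code has no role
  expect_length(
    classify_event(list(vocabulary = "ICD10CM", code = "nope"), registry), 0)
  roles <- vapply(registry$sets, `[[`, "", "role")
  expect_true(all(c("sle_diagnosis", "sle_sign_symptom", "sle_treatment_drug",
                    "antimalarial", "exclusion_dx") %in% roles))
  excl <- registry$sets$barnado_exclusions$codes
  expect_setequal(excl$code, c("710.3", "710.1"))
})

test_that("concept-set config validation catches structural problems", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cs.yaml")

  writeLines(c("concept_sets:",
               "  - name: a", "    role: sle_diagnosis", "    codes:",
               "      - {vocabulary: X, code: '1'}",
               "      - {vocabulary: X, code: '1'}"), p)
  expect_warning(reg <- load_concept_sets(p), "duplicate")
  expect_equal(nrow(reg$sets$a$codes), 1)

  writeLines(c("concept_sets:",
               "  - name: a", "    role: sle_diagnosis", "    codes:",
               "      - {vocabulary: X, code: '1'}",
               "  - name: a", "    role: other", "    codes:",
               "      - {vocabulary: X, code: '2'}"), p)
  expect_error(load_concept_sets(p), "duplicate concept set name")

  writeLines(c("concept_sets:",
               "  - name: a", "    role: not_a_role", "    codes:",
               "      - {vocabulary: X, code: '1'}"), p)
  expect_error(load_concept_sets(p), "unknown role")

  writeLines(c("concept_sets:",
               "  - name: empty_one", "    role: other", "    codes: []"), p)
  expect_warning(reg <- load_concept_sets(p), "empty")
  expect_equal(nrow(reg$sets$empty_one$codes), 0)
})
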