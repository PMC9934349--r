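#' @keywords internal
"_PACKAGE"

# Column contracts for the flat-file database. Only the columns the
# algorithms need are carried; names follow OMOP conventions so the files
# are recognisable to OHDSI users without implementing the full CDM.
.person_cols <- c("person_id", "sex", "birth_year")
.obs_cols    <- c("person_id", "observation_period_start_date",
                  "observation_period_end_date")
.cond_cols   <- c("person_id", "condition_start_date", "vocabulary", "code",
                  "visit_context")
.drug_cols   <- c("person_id", "drug_exposure_start_date", "vocabulary",
                  "code", "visit_context")
.truth_cols  <- c("person_id", "has_sle", "onset_date")

.sexes          <- c("female", "male")
.visit_contexts <- c("outpatient", "inpatient", "emergency", "none")
.domains        <- c("condition", "drug")

.concept_roles <- c("sle_diagnosis", "sle_sign_symptom", "sle_treatment_drug",
                    "antimalarial", "exclusion_dx", "comorbidity", "other")

.read_table <- function(path, col_classes) {
  if (!file.exists(path)) {
    stop("required table is missing: ", basename(path), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = col_classes,
                        stringsAsFactors = FALSE)
  missing <- setdiff(names(col_classes), names(df))
  if (length(missing) > 0) {
    stop(basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[names(col_classes)]
}

.parse_dates <- function(df, cols, table_name) {
  for (col in cols) {
    raw <- df[[col]]
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
    if (length(bad) > 0) {
      stop("unparseable date in ", table_name, " column '", col,
           "' at row ", bad[1], ": '", raw[bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}

#' Load a simplified OMOP-style database from a directory of CSV files
#'
#' Reads `person.csv`, `observation_period.csv`, `condition_occurrence.csv`
#' and `drug_exposure.csv` (plus `ground_truth.csv` when present, as written
#' by [simulate_population()]), parses all dates, merges conditions and
#' drugs into a single event table with a `domain` column, and checks
#' referential integrity: every event and observation period must reference
#' a known `person_id`.
#'
#' @param directory_path Directory containing the tables.
#' @return An object of class `sle_database`: a list with data frames
#'   `person` (`person_id`, `sex`, `birth_year`), `observation_period`
#'   (`person_id`, start/end dates), `event` (`person_id`, `event_date`,
#'   `domain`, `vocabulary`, `code`, `visit_context`) and `ground_truth`
#'   (`person_id`, `has_sle`, `onset_date`; `NULL` if no file).
#' @seealso [write_database()] for the inverse operation.
#' @export
load_database <- function(directory_path) {
  if (!dir.exists(directory_path)) {
    stop("database directory does not exist: ", directory_path, call. = FALSE)
  }
  person <- .read_table(file.path(directory_path, "person.csv"),
                        c(person_id = "character", sex = "character",
                          birth_year = "integer"))
  obs <- .read_table(file.path(directory_path, "observation_period.csv"),
                     c(person_id = "character",
                       observation_period_start_date = "character",
                       observation_period_end_date = "character"))
  cond <- .read_table(file.path(directory_path, "condition_occurrence.csv"),
                      c(person_id = "character",
                        condition_start_date = "character",
                        vocabulary = "character", code = "character",
                        visit_context = "character"))
  drug <- .read_table(file.path(directory_path, "drug_exposure.csv"),
                      c(person_id = "character",
                        drug_exposure_start_date = "character",
                        vocabulary = "character", code = "character",
                        visit_context = "character"))

  obs  <- .parse_dates(obs, .obs_cols[2:3], "observation_period.csv")
  cond <- .parse_dates(cond, "condition_start_date", "condition_occurrence.csv")
  drug <- .parse_dates(drug, "drug_exposure_start_date", "drug_exposure.csv")

  event <- rbind(
    data.frame(person_id = cond$person_id, event_date = cond$condition_start_date,
               domain = if (nrow(cond)) "condition" else character(0),
               vocabulary = cond$vocabulary, code = cond$code,
               visit_context = cond$visit_context, stringsAsFactors = FALSE),
    data.frame(person_id = drug$person_id, event_date = drug$drug_exposure_start_date,
               domain = if (nrow(drug)) "drug" else character(0),
               vocabulary = drug$vocabulary, code = drug$code,
               visit_context = drug$visit_context, stringsAsFactors = FALSE)
  )

  truth_path <- file.path(directory_path, "ground_truth.csv")
  ground_truth <- NULL
  if (file.exists(truth_path)) {
    ground_truth <- .read_table(truth_path,
                                c(person_id = "character", has_sle = "logical",
                                  onset_date = "character"))
    ground_truth <- .parse_dates(ground_truth, "onset_date", "ground_truth.csv")
  }

  db <- structure(list(person = person, observation_period = obs,
                       event = event, ground_truth = ground_truth),
                  class = "sle_database")
  .check_integrity(db)
  db
}

.check_integrity <- function(db) {
  known <- db$person$person_id
  if (anyDuplicated(known)) {
    stop("duplicate person_id in person table: ",
         paste(unique(known[duplicated(known)]), collapse = ", "),
         call. = FALSE)
  }
  for (tab in c("observation_period", "event", "ground_truth")) {
    df <- db[[tab]]
    if (is.null(df)) next
    orphans <- setdiff(df$person_id, known)
    if (length(orphans) > 0) {
      stop(tab, " references unknown person_id(s): ",
           paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
    }
  }
  bad <- with(db$observation_period,
              which(observation_period_end_date < observation_period_start_date))
  if (length(bad) > 0) {
    stop("observation period ends before it starts for person_id ",
         db$observation_period$person_id[bad[1]], call. = FALSE)
  }
  invisible(db)
}

#' Write a database to a directory of CSV files
#'
#' Emits `person.csv`, `observation_period.csv`, `condition_occurrence.csv`,
#' `drug_exposure.csv` and, when ground truth is present, `ground_truth.csv`.
#' Output round-trips through [load_database()] unchanged.
#'
#' @param db An `sle_database` (from [load_database()] or
#'   [simulate_population()]).
#' @param directory Output directory; created if absent.
#' @return The directory path, invisibly.
#' @export
write_database <- function(db, directory) {
  stopifnot(inherits(db, "sle_database"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  wr <- function(df, name) {
    utils::write.csv(df, file.path(directory, name), row.names = FALSE,
                     quote = TRUE, na = "")
  }
  wr(db$person, "person.csv")
  wr(db$observation_period, "observation_period.csv")
  is_cond <- db$event$domain == "condition"
  cond <- db$event[is_cond, c("person_id", "event_date", "vocabulary", "code",
                              "visit_context")]
  names(cond)[2] <- "condition_start_date"
  drug <- db$event[!is_cond, c("person_id", "event_date", "vocabulary", "code",
                               "visit_context")]
  names(drug)[2] <- "drug_exposure_start_date"
  wr(cond, "condition_occurrence.csv")
  wr(drug, "drug_exposure.csv")
  if (!is.null(db$ground_truth)) wr(db$ground_truth, "ground_truth.csv")
  invisible(directory)
}

#' @export
print.sle_database <- function(x, ...) {
  cat("<sle_database>\n")
  cat("  persons:            ", nrow(x$person), "\n")
  cat("  observation periods:", nrow(x$observation_period), "\n")
  cat("  clinical events:    ", nrow(x$event), "\n")
  if (!is.null(x$ground_truth)) {
    cat("  ground truth:       ", sum(x$ground_truth$has_sle), "cases /",
        nrow(x$ground_truth), "persons\n")
  }
  invisible(x)
}

.code_key <- function(vocabulary, code) paste(vocabulary, code, sep = "\r")

.build_registry <- function(sets) {
  lookup <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$codes) == 0) return(NULL)
    data.frame(vocabulary = s$codes$vocabulary, code = s$codes$code,
               role = s$role, set_name = s$name, stringsAsFactors = FALSE)
  }))
  if (is.null(lookup)) {
    lookup <- data.frame(vocabulary = character(0), code = character(0),
                         role = character(0), set_name = character(0))
  }
  lookup$key <- .code_key(lookup$vocabulary, lookup$code)
  structure(list(sets = sets, lookup = lookup,
                 role_keys = split(lookup$key, factor(lookup$role,
                                                      levels = .concept_roles)),
                 set_keys = split(lookup$key, lookup$set_name)),
            class = "concept_registry")
}

#' Load concept sets from a YAML configuration file
#'
#' The configuration holds a top-level `concept_sets:` list; each entry has
#' a unique `name`, a `role` (one of `sle_diagnosis`, `sle_sign_symptom`,
#' `sle_treatment_drug`, `antimalarial`, `exclusion_dx`, `comorbidity`,
#' `other`) and a `codes` list of `{vocabulary, code, label}` records.
#' Vocabulary matching downstream is exact string match on
#' `(vocabulary, code)`; no hierarchy expansion is performed, so code lists
#' must be literal. Duplicate codes within a set are dropped with a
#' warning; an empty set is allowed but flagged.
#'
#' @param config_path Path to the YAML file.
#' @return A `concept_registry` keyed by set name.
#' @seealso [default_concept_sets()] for the shipped registry,
#'   [classify_event()] for lookups.
#' @export
load_concept_sets <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("concept set config not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  raw <- cfg$concept_sets
  if (is.null(raw)) stop("config has no 'concept_sets' entry", call. = FALSE)
  sets <- list()
  for (entry in raw) {
    name <- entry$name
    if (is.null(name) || !nzchar(name)) {
      stop("concept set without a name", call. = FALSE)
    }
    if (name %in% names(sets)) {
      stop("duplicate concept set name: ", name, call. = FALSE)
    }
    role <- entry$role
    if (is.null(role) || !role %in% .concept_roles) {
      stop("unknown role '", role, "' in concept set '", name,
           "' (must be one of ", paste(.concept_roles, collapse = ", "), ")",
           call. = FALSE)
    }
    codes <- entry$codes
    if (length(codes) == 0) {
      warning("concept set '", name, "' is empty", call. = FALSE)
      codes_df <- data.frame(vocabulary = character(0), code = character(0),
                             label = character(0), stringsAsFactors = FALSE)
    } else {
      codes_df <- data.frame(
        vocabulary = vapply(codes, function(x) as.character(x$vocabulary), ""),
        code = vapply(codes, function(x) as.character(x$code), ""),
        label = vapply(codes, function(x) {
          if (is.null(x$label)) "" else as.character(x$label)
        }, ""),
        stringsAsFactors = FALSE)
      dup <- duplicated(.code_key(codes_df$vocabulary, codes_df$code))
      if (any(dup)) {
        warning("concept set '", name, "' contains duplicate codes; ",
                "de-duplicated", call. = FALSE)
        codes_df <- codes_df[!dup, , drop = FALSE]
      }
    }
    sets[[name]] <- list(name = name, role = role, codes = codes_df)
  }
  .build_registry(sets)
}

#' The concept-set registry shipped with the package
#'
#' A compact default covering the main-text codes of the algorithm
#' definitions: the SLE diagnosis set (SNOMED 257628, ICD-10-CM M32.9,
#' ICD-9-CM 710.0), prodromal signs and symptoms (malaise, fatigue, joint
#' pain, low back pain, anemia), SLE treatment drugs (prednisone,
#' methylprednisolone, hydroxychloroquine), antimalarials
#' (hydroxychloroquine, chloroquine), the comparator exclusion diagnoses
#' (dermatomyositis 710.3, systemic sclerosis 710.1) and three comorbidity
#' sets used by the simulator. Complete production code lists are expected
#' to be supplied by the user via [load_concept_sets()].
#'
#' @return A `concept_registry`.
#' @export
default_concept_sets <- function() {
  path <- system.file("extdata", "concept_sets.yaml",
                      package = "SlePhenotyper", mustWork = TRUE)
  suppressWarnings(load_concept_sets(path))
}

#' @export
print.concept_registry <- function(x, ...) {
  cat("<concept_registry>", length(x$sets), "sets,",
      nrow(x$lookup), "codes\n")
  for (s in x$sets) {
    cat(sprintf("  %-22s role=%-18s %d codes\n", s$name, s$role,
                nrow(s$codes)))
  }
  invisible(x)
}

#' Roles carried by a coded clinical event
#'
#' Pure function of `(vocabulary, code)` and the registry: returns every
#' role whose concept set contains the pair. A code may carry several roles
#' (hydroxychloroquine is both an SLE treatment drug and an antimalarial);
#' an unknown code returns an empty character vector.
#'
#' @param event A list or one-row data frame with `vocabulary` and `code`.
#' @param registry A `concept_registry`.
#' @return Character vector of roles (possibly empty).
#' @export
classify_event <- function(event, registry) {
  stopifnot(inherits(registry, "concept_registry"))
  key <- .code_key(as.character(event$vocabulary), as.character(event$code))
  unique(registry$lookup$role[registry$lookup$key == key])
}

# Vectorised role membership for an event table; returns a logical vector.
.has_role <- function(events, registry, roles) {
  keys <- unique(unlist(registry$role_keys[roles], use.names = FALSE))
  .code_key(events$vocabulary, events$code) %in% keys
}

# Codes (vocabulary, code, label) of one named set; used by the simulator.
.set_codes <- function(registry, name) {
  s <- registry$sets[[name]]
  if (is.null(s)) stop("no concept set named '", name, "'", call. = FALSE)
  s$codes
}
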