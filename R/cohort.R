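# Cohort container: a schema plus two tibbles, mirroring the two CSV files a
# trial data export comes in. `static` is wide (one row per patient);
# `temporal` is long (one row per patient-visit) with a `dropped_at_visit`
# flag that is 1 exactly at the final visit of a patient who left the trial
# early (administratively completed journeys carry all-zero flags).

new_cohort <- function(schema, static, temporal) {
  structure(
    list(schema = schema, static = static, temporal = temporal),
    class = "cohort"
  )
}

#' Assemble a cohort from in-memory tables
#'
#' @param schema A [cohort_schema()].
#' @param static Tibble with `patient_id` plus one column per static feature.
#' @param temporal Long tibble with `patient_id`, `visit` (consecutive
#'   integers from 1), `dropped_at_visit` (0/1) plus one column per temporal
#'   feature.
#' @param allow_unknown Accept the reserved `"(unknown)"` label in categorical
#'   columns (used by decoded cohorts).
#' @return A validated `cohort` object.
#' @export
as_cohort <- function(schema, static, temporal, allow_unknown = FALSE) {
  ch <- new_cohort(schema, tibble::as_tibble(static), tibble::as_tibble(temporal))
  validate_cohort(ch, allow_unknown = allow_unknown)
}

#' @export
print.cohort <- function(x, ...) {
  len <- cohort_lengths(x)
  cat(sprintf(
    "<cohort: %d patients, %d visits, lengths %d-%d (mean %.2f), %.1f%% dropped>\n",
    nrow(x$static), nrow(x$temporal), min(len$length), max(len$length),
    mean(len$length), 100 * mean(len$dropped)
  ))
  invisible(x)
}

#' Per-patient journey lengths and drop-off status
#'
#' @param cohort A `cohort`.
#' @return Tibble with `patient_id`, `length`, `dropped`.
#' @export
cohort_lengths <- function(cohort) {
  cohort$temporal |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      length = dplyr::n(),
      dropped = any(.data$dropped_at_visit == 1),
      .groups = "drop"
    ) |>
    # keep static-table order
    dplyr::left_join(x = dplyr::select(cohort$static, "patient_id"), by = "patient_id")
}

#' Number of patients in a cohort
#' @param cohort A `cohort`.
#' @export
n_patients <- function(cohort) nrow(cohort$static)

#' Validate a cohort against its schema
#'
#' Checks column presence, visit consecutiveness, absence of missing values,
#' category labels, and placement of the drop-off flag.
#'
#' @inheritParams as_cohort
#' @param cohort A `cohort`.
#' @return The cohort, invisibly usable in a pipe; errors describe the first
#'   violation found.
#' @export
validate_cohort <- function(cohort, allow_unknown = FALSE) {
  sch <- cohort$schema
  st <- cohort$static
  tm <- cohort$temporal

  need_s <- c("patient_id", schema_features(sch, "static")$name)
  miss <- setdiff(need_s, names(st))
  if (length(miss)) rlang::abort(sprintf("static table missing column(s): %s", toString(miss)))
  need_t <- c("patient_id", "visit", "dropped_at_visit", schema_features(sch, "temporal")$name)
  miss <- setdiff(need_t, names(tm))
  if (length(miss)) rlang::abort(sprintf("temporal table missing column(s): %s", toString(miss)))

  if (anyDuplicated(st$patient_id)) rlang::abort("duplicate patient_id in static table")
  if (nrow(tm) == 0) rlang::abort("temporal table has no visits")

  if (!setequal(st$patient_id, unique(tm$patient_id))) {
    rlang::abort("patient sets of static and temporal tables differ after alignment")
  }

  # visits must be 1,2,...,T per patient
  bad <- tm |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      ok = all(sort(as.numeric(.data$visit)) == seq_along(.data$visit)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    rlang::abort(sprintf(
      "non-consecutive visit indices for patient(s): %s",
      toString(utils::head(bad$patient_id, 5))
    ))
  }

  check_values <- function(tab, feats, where) {
    for (i in seq_len(nrow(feats))) {
      nm <- feats$name[i]
      v <- tab[[nm]]
      if (anyNA(v)) {
        rlang::abort(sprintf("missing values in %s feature '%s' are not supported", where, nm))
      }
      if (feats$kind[i] == "continuous") {
        if (!is.numeric(v)) rlang::abort(sprintf("continuous feature '%s' must be numeric", nm))
      } else {
        lev <- feats$levels[[i]]
        if (allow_unknown) lev <- c(lev, "(unknown)")
        unknown <- setdiff(unique(as.character(v)), lev)
        if (length(unknown)) {
          rlang::abort(sprintf(
            "unknown label(s) for feature '%s': %s", nm, toString(utils::head(unknown, 5))
          ))
        }
      }
    }
  }
  check_values(st, schema_features(sch, "static"), "static")
  check_values(tm, schema_features(sch, "temporal"), "temporal")

  if (!all(tm$dropped_at_visit %in% c(0, 1))) {
    rlang::abort("dropped_at_visit must be 0/1")
  }
  bad_drop <- tm |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      k = sum(.data$dropped_at_visit),
      at_end = all(.data$visit[.data$dropped_at_visit == 1] == max(.data$visit)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$k > 1 | !.data$at_end)
  if (nrow(bad_drop)) {
    rlang::abort(sprintf(
      "dropped_at_visit must be 1 at most once, at the final visit (patient %s)",
      bad_drop$patient_id[1]
    ))
  }
  cohort
}

#' Read a cohort from its two CSV files
#'
#' Patients present in only one of the two tables are excluded with a warning
#' reporting the count.
#'
#' @param static_csv,temporal_csv Paths to the wide static and long temporal
#'   CSV files (UTF-8, header row required).
#' @param schema A [cohort_schema()] (or path to a schema YAML).
#' @return A validated `cohort`.
#' @export
read_cohort <- function(static_csv, temporal_csv, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  for (p in c(static_csv, temporal_csv)) {
    if (!file.exists(p)) rlang::abort(sprintf("file not found: %s", p))
  }
  st <- readr::read_csv(static_csv, show_col_types = FALSE, progress = FALSE)
  tm <- readr::read_csv(temporal_csv, show_col_types = FALSE, progress = FALSE)
  if (!"patient_id" %in% names(st)) rlang::abort("static CSV lacks a patient_id column")
  if (!all(c("patient_id", "visit", "dropped_at_visit") %in% names(tm))) {
    rlang::abort("temporal CSV needs patient_id, visit and dropped_at_visit columns")
  }
  st$patient_id <- as.character(st$patient_id)
  tm$patient_id <- as.character(tm$patient_id)

  common <- intersect(st$patient_id, unique(tm$patient_id))
  n_excluded <- (nrow(st) - length(common)) +
    (length(unique(tm$patient_id)) - length(common))
  if (n_excluded > 0) {
    rlang::warn(sprintf(
      "%d patient(s) present in only one table were excluded", n_excluded
    ))
  }
  st <- dplyr::filter(st, .data$patient_id %in% common)
  tm <- tm |>
    dplyr::filter(.data$patient_id %in% common) |>
    dplyr::arrange(match(.data$patient_id, st$patient_id), .data$visit)

  # force label columns to character so e.g. numeric-looking levels survive
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] != "continuous") {
      if (nm %in% names(st)) st[[nm]] <- as.character(st[[nm]])
      if (nm %in% names(tm)) tm[[nm]] <- as.character(tm[[nm]])
    }
  }
  as_cohort(schema, st, tm)
}

#' Write a cohort to `static.csv`, `temporal.csv` and `schema.yaml`
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$static, file.path(dir, "static.csv"), progress = FALSE)
  readr::write_csv(cohort$temporal, file.path(dir, "temporal.csv"), progress = FALSE)
  write_schema(cohort$schema, file.path(dir, "schema.yaml"))
  invisible(dir)
}

#' Split a cohort into train and test partitions by patient
#'
#' The train partition gets `floor(n_patients * train_frac)` patients; the
#' split is deterministic given `seed` and patients never appear in both
#' partitions.
#'
#' @param cohort A `cohort`.
#' @param train_frac Fraction of patients for the training split, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both cohorts.
#' @export
split_cohort <- function(cohort, train_frac = 0.8, seed = 1) {
  if (!(train_frac > 0 && train_frac < 1)) rlang::abort("train_frac must be in (0, 1)")
  n <- n_patients(cohort)
  if (n < 2) rlang::abort("cannot split a cohort with fewer than 2 patients")
  ids <- cohort$static$patient_id
  n_train <- floor(n * train_frac)
  if (n_train < 1 || n_train >= n) rlang::abort("train_frac leaves an empty partition")
  train_ids <- withr::with_seed(seed, sample(ids, n_train))
  subset_by_id <- function(keep) {
    new_cohort(
      cohort$schema,
      dplyr::filter(cohort$static, .data$patient_id %in% keep),
      dplyr::filter(cohort$temporal, .data$patient_id %in% keep)
    )
  }
  list(train = subset_by_id(train_ids), test = subset_by_id(setdiff(ids, train_ids)))
}
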