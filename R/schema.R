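#' Declare a single cohort feature
#'
#' A feature is either a subject-level (`static`) covariate or a per-visit
#' (`temporal`) measurement, and carries one of three kinds: `continuous`,
#' `categorical` (unordered labels) or `ordinal` (ordered labels).
#'
#' @param name Feature name, unique within a schema.
#' @param role `"static"` or `"temporal"`.
#' @param kind `"continuous"`, `"categorical"` or `"ordinal"`.
#' @param levels Character vector of category/level labels, in order for
#'   ordinal features. Must be empty for continuous features and non-empty
#'   otherwise.
#' @param units Free-text units, e.g. `"years"`.
#' @return A one-row tibble describing the feature.
#' @export
feature_spec <- function(name, role, kind, levels = character(), units = "") {
  role <- rlang::arg_match(role, c("static", "temporal"))
  kind <- rlang::arg_match(kind, c("continuous", "categorical", "ordinal"))
  if (kind == "continuous" && length(levels) > 0) {
    rlang::abort(sprintf("feature '%s': continuous features take no levels", name))
  }
  if (kind != "continuous") {
    if (length(levels) == 0) {
      rlang::abort(sprintf("feature '%s': %s features need non-empty levels", name, kind))
    }
    if (anyDuplicated(levels)) {
      rlang::abort(sprintf("feature '%s': duplicated levels", name))
    }
  }
  tibble::tibble(
    name = as.character(name), role = role, kind = kind,
    levels = list(as.character(levels)), units = as.character(units)
  )
}

#' Build a cohort schema from feature specs
#'
#' @param features A tibble of features, typically built by row-binding
#'   [feature_spec()] calls.
#' @return A `cohort_schema` object (a tibble of features).
#' @examples
#' sch <- cohort_schema(dplyr::bind_rows(
#'   feature_spec("age", "static", "continuous", units = "years"),
#'   feature_spec("group", "static", "categorical", c("g0", "g1")),
#'   feature_spec("score", "temporal", "continuous")
#' ))
#' @export
cohort_schema <- function(features) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("name", "role", "kind", "levels", "units") %in% names(features)))
  if (anyDuplicated(features$name)) {
    rlang::abort("schema feature names must be unique")
  }
  # re-validate each row through feature_spec
  features <- purrr::pmap_dfr(features, function(name, role, kind, levels, units) {
    feature_spec(name, role, kind, levels, units)
  })
  if (!any(features$role == "static") || !any(features$role == "temporal")) {
    rlang::abort("a schema needs at least one static and one temporal feature")
  }
  structure(features, class = c("cohort_schema", class(tibble::tibble())))
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat(sprintf(
    "<cohort_schema: %d static + %d temporal features>\n",
    schema_static_dim(x), schema_temporal_dim(x)
  ))
  NextMethod()
}

#' Number of static / temporal features in a schema
#' @param schema A [cohort_schema()].
#' @return Integer count.
#' @export
schema_static_dim <- function(schema) sum(schema$role == "static")

#' @rdname schema_static_dim
#' @export
schema_temporal_dim <- function(schema) sum(schema$role == "temporal")

schema_features <- function(schema, role) {
  dplyr::filter(tibble::as_tibble(schema), .data$role == !!role)
}

#' Read / write a schema as YAML
#'
#' The file holds a list of features, each with `name`, `role`, `kind`,
#' `levels` and `units` entries.
#'
#' @param path Path to a `schema.yaml` file.
#' @return [read_schema()] returns a `cohort_schema`; [write_schema()] returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("schema file not found: %s", path))
  raw <- yaml::read_yaml(path)
  feats <- purrr::map_dfr(raw$features, function(f) {
    feature_spec(
      name = f$name, role = f$role, kind = f$kind,
      levels = as.character(f$levels %||% character()),
      units = f$units %||% ""
    )
  })
  cohort_schema(feats)
}

#' @rdname read_schema
#' @param schema A [cohort_schema()].
#' @export
write_schema <- function(schema, path) {
  feats <- purrr::pmap(tibble::as_tibble(schema), function(name, role, kind, levels, units) {
    list(name = name, role = role, kind = kind, levels = as.list(levels), units = units)
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}
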