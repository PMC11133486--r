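# Invertible numeric encoding of mixed-type cohorts.
#
# Continuous features are min-max scaled to [0,1] (so sigmoid decoder heads
# are range-valid), ordinal features become equally spaced scalars in [0,1]
# (decoded by nearest-level snap), and categorical features become one-hot
# blocks with one extra reserved "(unknown)" slot for labels unseen when the
# transform was fitted.

#' Fit the per-feature scaling transform on a training cohort
#'
#' @param cohort_train A `cohort`; the transform must be fitted on the
#'   training split only.
#' @return A `cohort_transform` holding min/max per continuous feature and
#'   level maps per categorical/ordinal feature.
#' @export
fit_transform <- function(cohort_train) {
  sch <- cohort_train$schema
  if (n_patients(cohort_train) == 0) rlang::abort("cannot fit a transform on an empty cohort")
  fit_one <- function(name, role, kind, levels, units) {
    tab <- if (role == "static") cohort_train$static else cohort_train$temporal
    v <- tab[[name]]
    if (kind == "continuous") {
      lo <- min(v); hi <- max(v)
      if (hi <= lo) {
        rlang::abort(sprintf("continuous feature '%s' is constant on the training data", name))
      }
      list(name = name, role = role, kind = kind, min = lo, max = hi, levels = NULL)
    } else {
      extra <- setdiff(unique(as.character(v)), levels)
      if (length(extra)) {
        rlang::abort(sprintf("feature '%s': training labels outside schema levels: %s",
                             name, toString(extra)))
      }
      list(name = name, role = role, kind = kind, min = NA_real_, max = NA_real_,
           levels = levels)
    }
  }
  feats <- purrr::pmap(tibble::as_tibble(sch), fit_one)
  names(feats) <- sch$name
  structure(
    list(features = feats, schema = sch, fitted_on = "train"),
    class = "cohort_transform"
  )
}

#' @export
print.cohort_transform <- function(x, ...) {
  cat(sprintf("<cohort_transform: %d features, fitted on %s split>\n",
              length(x$features), x$fitted_on))
  invisible(x)
}

# Column layout of the encoded representation for one role.
# Returns a tibble: feature, kind, ncol, start, end (1-based, inclusive).
transform_layout <- function(transform, role) {
  feats <- purrr::keep(transform$features, ~ .x$role == role)
  out <- purrr::map_dfr(feats, function(f) {
    k <- switch(f$kind,
      continuous = 1L, ordinal = 1L,
      categorical = length(f$levels) + 1L  # + reserved unknown slot
    )
    tibble::tibble(feature = f$name, kind = f$kind, ncol = k)
  })
  out$end <- cumsum(out$ncol)
  out$start <- out$end - out$ncol + 1L
  out
}

encoded_dim <- function(transform, role) sum(transform_layout(transform, role)$ncol)

encode_column <- function(f, v) {
  switch(f$kind,
    continuous = matrix((as.numeric(v) - f$min) / (f$max - f$min), ncol = 1),
    ordinal = {
      idx <- match(as.character(v), f$levels)
      if (anyNA(idx)) {
        rlang::abort(sprintf("feature '%s': label outside declared ordinal levels", f$name))
      }
      matrix((idx - 1) / max(length(f$levels) - 1, 1), ncol = 1)
    },
    categorical = {
      k <- length(f$levels) + 1L
      idx <- match(as.character(v), f$levels)
      unk <- is.na(idx)
      if (any(unk)) {
        rlang::warn(sprintf(
          "feature '%s': %d value(s) unseen at fit time mapped to the unknown slot",
          f$name, sum(unk)
        ))
        idx[unk] <- k
      }
      m <- matrix(0, length(v), k)
      m[cbind(seq_along(v), idx)] <- 1
      m
    }
  )
}

decode_column <- function(f, m) {
  switch(f$kind,
    continuous = as.numeric(m) * (f$max - f$min) + f$min,
    ordinal = {
      L <- length(f$levels)
      grid <- (seq_len(L) - 1) / max(L - 1, 1)
      f$levels[apply(outer(as.numeric(m), grid, function(a, b) abs(a - b)), 1, which.min)]
    },
    categorical = {
      # the reserved slot only decodes from a hard unknown one-hot; soft
      # probability vectors (decoder heads) decode to the best real level
      k <- length(f$levels) + 1L
      hard_unknown <- m[, k] >= 0.999
      out <- f$levels[max.col(m[, -k, drop = FALSE], ties.method = "first")]
      out[hard_unknown] <- "(unknown)"
      out
    }
  )
}

#' Encode a cohort into padded, masked numeric arrays
#'
#' @param cohort A `cohort`.
#' @param transform A fitted [fit_transform()] result.
#' @param t_max Pad/truncate sequences to this many visits; defaults to the
#'   longest journey in `cohort`. Truncation warns.
#' @return An `encoded_batch`: list with `s` (N x d_s matrix), `x`
#'   (N x t_max x d_x array), `mask` and `drop_labels` (N x t_max, 0/1),
#'   `lengths`, `patient_ids`. `drop_labels` is 1 exactly at the final
#'   observed visit of a dropped patient. Padded positions carry 0.
#' @export
encode_batch <- function(cohort, transform, t_max = NULL) {
  sch <- cohort$schema
  len <- cohort_lengths(cohort)
  n <- nrow(len)
  if (is.null(t_max)) t_max <- max(len$length)
  if (t_max < max(len$length)) {
    rlang::warn(sprintf("truncating %d sequence(s) longer than t_max = %d",
                        sum(len$length > t_max), t_max))
  }
  lay_s <- transform_layout(transform, "static")
  lay_t <- transform_layout(transform, "temporal")

  s <- matrix(0, n, sum(lay_s$ncol))
  for (i in seq_len(nrow(lay_s))) {
    f <- transform$features[[lay_s$feature[i]]]
    s[, lay_s$start[i]:lay_s$end[i]] <- encode_column(f, cohort$static[[f$name]])
  }

  tm <- dplyr::arrange(cohort$temporal,
                       match(.data$patient_id, cohort$static$patient_id), .data$visit)
  tm <- dplyr::filter(tm, .data$visit <= t_max)
  row_of <- match(tm$patient_id, cohort$static$patient_id)
  x <- array(0, dim = c(n, t_max, sum(lay_t$ncol)))
  for (i in seq_len(nrow(lay_t))) {
    f <- transform$features[[lay_t$feature[i]]]
    enc <- encode_column(f, tm[[f$name]])
    for (k in seq_len(ncol(enc))) {
      x[cbind(row_of, tm$visit, lay_t$start[i] + k - 1L)] <- enc[, k]
    }
  }

  lengths <- pmin(len$length, t_max)
  mask <- outer(lengths, seq_len(t_max), `>=`) * 1
  drop_labels <- matrix(0, n, t_max)
  dropped <- len$dropped & (len$length <= t_max)  # truncation removes the terminal visit
  drop_labels[cbind(which(dropped), lengths[dropped])] <- 1

  if (any(!is.finite(s)) || any(!is.finite(x))) rlang::abort("non-finite encoded values")
  structure(
    list(
      s = s, x = x, mask = mask, lengths = lengths, drop_labels = drop_labels,
      patient_ids = len$patient_id
    ),
    class = "encoded_batch"
  )
}

#' Decode an encoded batch back to a cohort
#'
#' Inverse of [encode_batch()]: continuous values are unscaled, ordinal values
#' snap to the nearest level, categorical blocks decode by arg-max (one-hot or
#' probability vectors alike).
#'
#' @param batch An `encoded_batch` (or a compatible list with `s`, `x`,
#'   `mask`, `lengths`, `drop_labels`, `patient_ids`).
#' @param transform The transform used to encode.
#' @param schema The cohort schema.
#' @return A `cohort`.
#' @export
decode_batch <- function(batch, transform, schema) {
  lay_s <- transform_layout(transform, "static")
  lay_t <- transform_layout(transform, "temporal")
  n <- nrow(batch$s)

  st <- tibble::tibble(patient_id = batch$patient_ids)
  for (i in seq_len(nrow(lay_s))) {
    f <- transform$features[[lay_s$feature[i]]]
    st[[f$name]] <- decode_column(f, batch$s[, lay_s$start[i]:lay_s$end[i], drop = FALSE])
  }

  idx <- purrr::map_dfr(seq_len(n), function(p) {
    tibble::tibble(row = p, visit = seq_len(batch$lengths[p]))
  })
  tm <- tibble::tibble(
    patient_id = batch$patient_ids[idx$row],
    visit = idx$visit,
    dropped_at_visit = batch$drop_labels[cbind(idx$row, idx$visit)]
  )
  for (i in seq_len(nrow(lay_t))) {
    f <- transform$features[[lay_t$feature[i]]]
    cols <- lay_t$start[i]:lay_t$end[i]
    flat <- matrix(0, nrow(idx), length(cols))
    for (k in seq_along(cols)) {
      flat[, k] <- batch$x[cbind(idx$row, idx$visit, cols[k])]
    }
    tm[[f$name]] <- decode_column(f, flat)
  }
  as_cohort(schema, st, tm, allow_unknown = TRUE)
}
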