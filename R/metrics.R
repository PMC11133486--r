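# Generation-quality metrics: mixed-type correlation structure, Frechet
# distance on sequence embeddings, alpha-precision, and Jensen-Shannon
# distances between pooled value distributions.

#' Mixed-type association between two pooled value vectors
#'
#' Dispatches on the kind pair: Pearson correlation for continuous pairs,
#' the correlation ratio (weighted between-category variance over total
#' variance, in `[0, 1]`) for continuous-categorical pairs, and Theil's U
#' (uncertainty coefficient, `1 - H(x|y) / H(x)`, in `[0, 1]`) for
#' categorical pairs. Ordinal values are treated as continuous.
#'
#' @param values_i,values_j Equal-length pooled value vectors (all observed
#'   visits of all patients pooled).
#' @param kind_i,kind_j `"continuous"`, `"ordinal"` or `"categorical"`. For
#'   the asymmetric Theil's U the value returned is `U(i | j)`.
#' @return A single association value; zero-variance continuous input gives
#'   0 with a warning.
#' @export
mixed_correlation <- function(values_i, values_j, kind_i, kind_j) {
  stopifnot(length(values_i) == length(values_j))
  num <- function(k) k %in% c("continuous", "ordinal")
  if (num(kind_i) && num(kind_j)) {
    if (stats::sd(values_i) == 0 || stats::sd(values_j) == 0) {
      rlang::warn("zero-variance continuous input; association set to 0")
      return(0)
    }
    stats::cor(as.numeric(values_i), as.numeric(values_j))
  } else if (num(kind_i) && !num(kind_j)) {
    correlation_ratio(as.numeric(values_i), as.character(values_j))
  } else if (!num(kind_i) && num(kind_j)) {
    correlation_ratio(as.numeric(values_j), as.character(values_i))
  } else {
    theils_u(as.character(values_i), as.character(values_j))
  }
}

#' @rdname mixed_correlation
#' @param x Numeric vector (continuous values).
#' @param g Category labels of the same length.
#' @export
correlation_ratio <- function(x, g) {
  tot <- sum((x - mean(x))^2)
  if (tot == 0) {
    rlang::warn("zero-variance continuous input; correlation ratio set to 0")
    return(0)
  }
  means <- tapply(x, g, mean)
  ns <- tapply(x, g, length)
  sqrt(sum(ns * (means - mean(x))^2) / tot)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname mixed_correlation
#' @param y Conditioning category labels for Theil's U, `U(x | y)`.
#' @export
theils_u <- function(x, y) {
  hx <- entropy_nat(prop.table(table(x)))
  if (hx == 0) return(1)  # x is constant: fully determined
  tab <- prop.table(table(y, x))
  py <- rowSums(tab)
  hxy <- sum(purrr::map_dbl(seq_along(py), function(i) {
    if (py[i] == 0) 0 else py[i] * entropy_nat(tab[i, ] / py[i])
  }))
  (hx - hxy) / hx
}

# pool a cohort into one row-per-visit table over all features (static values
# repeated across the patient's visits), with a kind per column; ordinal
# labels become their numeric level ranks so they can enter Pearson terms
pooled_table <- function(cohort) {
  sch <- cohort$schema
  joined <- dplyr::left_join(cohort$temporal, cohort$static, by = "patient_id")
  vals <- joined[, sch$name, drop = FALSE]
  for (i in seq_len(nrow(sch))) {
    if (sch$kind[i] == "ordinal") {
      vals[[sch$name[i]]] <- match(vals[[sch$name[i]]], sch$levels[[i]])
    }
  }
  list(values = vals, kinds = stats::setNames(sch$kind, sch$name))
}

#' Average absolute correlation difference between two cohorts
#'
#' Builds the mixed-type association matrix of each cohort over all feature
#' pairs (pooled over observed visits, static features repeated per visit)
#' and averages the absolute differences over the upper triangle:
#' `(1/p) * sum_{i<j} | corr_R[f_i, f_j] - corr_G[f_i, f_j] |`.
#' The asymmetric Theil's U cell `(i, j)`, `i < j`, uses `U(f_i | f_j)`.
#'
#' @param cohort_real,cohort_gen Two cohorts sharing one schema.
#' @param schema Optional schema (defaults to the real cohort's); a mismatch
#'   with the generated cohort's feature set errors.
#' @return Mean absolute association difference, >= 0; 0 for identical
#'   pooled tables.
#' @export
avg_corr_diff <- function(cohort_real, cohort_gen, schema = NULL) {
  schema <- schema %||% cohort_real$schema
  if (!identical(sort(schema$name), sort(cohort_gen$schema$name))) {
    rlang::abort("cohorts do not share a feature set")
  }
  pr <- pooled_table(cohort_real)
  pg <- pooled_table(cohort_gen)
  nm <- schema$name
  p <- 0; acc <- 0
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i >= j) next
      ci <- suppressWarnings(mixed_correlation(
        pr$values[[nm[i]]], pr$values[[nm[j]]], pr$kinds[[nm[i]]], pr$kinds[[nm[j]]]))
      cj <- suppressWarnings(mixed_correlation(
        pg$values[[nm[i]]], pg$values[[nm[j]]], pg$kinds[[nm[i]]], pg$kinds[[nm[j]]]))
      acc <- acc + abs(ci - cj)
      p <- p + 1
    }
  }
  acc / p
}

#' Sequence embeddings of a cohort
#'
#' Embeds each patient journey as the final observed hidden state of the
#' fitted temporal encoder (the shared encoder of the autoencoder).
#'
#' @param fit A trained `cohort_gan`.
#' @param cohort A `cohort` (encoded through the fit's transform).
#' @return N x d_ht matrix, one row per patient.
#' @export
sequence_embeddings <- function(fit, cohort) {
  batch <- encode_batch(cohort, fit$transform)
  h_s <- encode_static(fit$model, batch$s)
  h <- encode_sequence(fit$model, h_s, batch$x)
  final_state(array_to_list(h), batch$lengths)
}

mat_sqrt_sym <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two embedding sets
#'
#' Gaussian-fit distance
#' `||mu_R - mu_G||^2 + Tr(S_R + S_G - 2 (S_R S_G)^{1/2})`, computed via a
#' symmetric eigendecomposition of `S_R^{1/2} S_G S_R^{1/2}`; covariances get
#' a small ridge (`shrink`) so rank-deficient small samples stay stable.
#' Symmetric in its arguments; tiny negative numerical results clamp to 0.
#'
#' @param emb_real,emb_gen N x d embedding matrices (N may differ).
#' @param shrink Ridge added to the covariance diagonals.
#' @return Non-negative distance.
#' @export
fid_score <- function(emb_real, emb_gen, shrink = 1e-6) {
  if (any(!is.finite(emb_real)) || any(!is.finite(emb_gen))) {
    rlang::abort("non-finite embeddings")
  }
  emb_real <- as.matrix(emb_real); emb_gen <- as.matrix(emb_gen)
  mu_r <- colMeans(emb_real); mu_g <- colMeans(emb_gen)
  s_r <- stats::cov(emb_real) + diag(shrink, ncol(emb_real))
  s_g <- stats::cov(emb_gen) + diag(shrink, ncol(emb_gen))
  sr_half <- mat_sqrt_sym(s_r)
  cross <- mat_sqrt_sym(sr_half %*% s_g %*% sr_half)
  val <- sum((mu_r - mu_g)^2) + sum(diag(s_r)) + sum(diag(s_g)) - 2 * sum(diag(cross))
  max(val, 0)
}

#' Alpha-precision of generated embeddings
#'
#' Fraction of generated embeddings lying inside the alpha-support of the
#' real embedding distribution, estimated as the Euclidean ball centred at
#' the real-embedding mean with radius the empirical alpha-quantile of real
#' distances to that centre (a one-sphere approximation of the alpha-mass
#' support).
#'
#' @param emb_real,emb_gen N x d embedding matrices.
#' @param alpha Mass of the real support, in (0, 1].
#' @return Fraction in `[0, 1]`; higher means better coverage of the typical
#'   real region.
#' @export
alpha_precision <- function(emb_real, emb_gen, alpha = 0.95) {
  stopifnot(alpha > 0, alpha <= 1)
  if (nrow(emb_real) == 0 || nrow(emb_gen) == 0) rlang::abort("empty embedding set")
  ctr <- colMeans(emb_real)
  d_real <- sqrt(rowSums(sweep(emb_real, 2, ctr)^2))
  radius <- stats::quantile(d_real, alpha, names = FALSE, type = 7)
  d_gen <- sqrt(rowSums(sweep(emb_gen, 2, ctr)^2))
  mean(d_gen <= radius)
}

#' Jensen-Shannon distance between two samples of one variable
#'
#' Square root of the Jensen-Shannon divergence (base-2 logs, so the distance
#' lives in `[0, 1]`), estimated over 16 equal-width histogram bins spanning
#' the pooled real range for continuous variables, or the native categories
#' otherwise; `eps` smooths empty bins.
#'
#' @param values_real,values_gen Value vectors.
#' @param kind Variable kind (`"continuous"`, `"ordinal"`, `"categorical"`).
#' @param bins Histogram bins for continuous variables.
#' @param eps Smoothing mass added to each bin.
#' @return Distance in `[0, 1]`.
#' @export
js_distance <- function(values_real, values_gen, kind = "continuous",
                        bins = 16, eps = 1e-12) {
  if (kind == "categorical") {
    lev <- union(unique(values_real), unique(values_gen))
    p <- table(factor(values_real, levels = lev))
    q <- table(factor(values_gen, levels = lev))
  } else {
    vr <- as.numeric(values_real); vg <- as.numeric(values_gen)
    rng <- range(c(vr, vg))  # pooled range keeps the distance symmetric
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    cutf <- function(v) {
      idx <- findInterval(v, brk, rightmost.closed = TRUE)
      pmin(pmax(idx, 1), bins)
    }
    p <- tabulate(cutf(vr), bins)
    q <- tabulate(cutf(vg), bins)
  }
  p <- p / sum(p) + eps; p <- p / sum(p)
  q <- q / sum(q) + eps; q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(pmin(pmax(jsd, 0), 1))
}

# multivariate JS distance: per-variable distances averaged to one scalar;
# label-valued (categorical/ordinal) variables use their native categories
multivariate_jsd <- function(df_real, df_gen, kinds, bins = 16) {
  mean(purrr::map_dbl(names(kinds), function(nm) {
    kind <- if (kinds[[nm]] == "continuous") "continuous" else "categorical"
    js_distance(df_real[[nm]], df_gen[[nm]], kind, bins = bins)
  }))
}

#' Look-ahead simulation accuracy over forecast horizons
#'
#' For each prefix length `i`, feeds the first `i` real visits of every
#' held-out patient to the generator (Type B) and simulates the remainder;
#' at every later step `s` the pooled distribution of simulated values is
#' compared with the pooled real values at `s` via the multivariate
#' Jensen-Shannon distance, labelled with its look-ahead horizon `s - i`.
#'
#' @param fit A trained `cohort_gan`.
#' @param cohort_test Held-out `cohort`.
#' @param prefix_lengths Prefix lengths `i` to evaluate.
#' @param n_sims Simulations per patient per prefix.
#' @param seed Integer seed.
#' @param bins Histogram bins of the distance estimate.
#' @return Tibble with `prefix`, `step`, `horizon`, `jsd` and the patient
#'   count behind each cell.
#' @export
lookahead_jsd <- function(fit, cohort_test, prefix_lengths = 1:4, n_sims = 20,
                          seed = 1, bins = 16) {
  len <- cohort_lengths(cohort_test)
  t_kinds <- stats::setNames(
    schema_features(cohort_test$schema, "temporal")$kind,
    schema_features(cohort_test$schema, "temporal")$name
  )
  max_len <- fit$t_max
  if (any(prefix_lengths >= max_len)) rlang::abort("prefix length must be below max_len")
  purrr::map_dfr(prefix_lengths, function(i) {
    keep <- len$patient_id[len$length > i]
    if (length(keep) < 2) return(NULL)
    prefix <- new_cohort(
      cohort_test$schema,
      dplyr::filter(cohort_test$static, .data$patient_id %in% keep),
      cohort_test$temporal |>
        dplyr::filter(.data$patient_id %in% keep, .data$visit <= i) |>
        dplyr::mutate(dropped_at_visit = 0)
    )
    sims <- simulate_type_b(fit, prefix,
                            sim_config(n_sims = n_sims, max_len = max_len,
                                       seed = seed + i))
    steps <- sort(unique(len$length[len$length > i]))
    steps <- setdiff(seq(i + 1, max(steps)), integer(0))
    purrr::map_dfr(steps, function(s) {
      real_s <- cohort_test$temporal |>
        dplyr::filter(.data$patient_id %in% keep, .data$visit == s)
      gen_s <- dplyr::filter(tibble::as_tibble(sims), .data$visit == s)
      if (nrow(real_s) < 2 || nrow(gen_s) < 2) return(NULL)
      tibble::tibble(
        prefix = i, step = s, horizon = s - i,
        jsd = multivariate_jsd(real_s, gen_s, t_kinds, bins = bins),
        n_real = nrow(real_s), n_gen = nrow(gen_s)
      )
    })
  })
}

#' Drop-off visit MAPE by number of known visits
#'
#' Mean absolute percentage error `|pred - actual| / actual` between
#' predicted and actual drop-off visits, grouped by how many historical
#' visits were known at prediction time, plus an `"all"` aggregate row.
#'
#' @param predicted,actual Numeric vectors of predicted / actual drop-off
#'   visits (actual >= 1).
#' @param known_visits Integer vector: visits known at prediction time.
#' @return Tibble with `known_visits` (character; includes `"all"`), `mape`,
#'   `n`.
#' @export
dropoff_mape <- function(predicted, actual, known_visits) {
  stopifnot(length(predicted) == length(actual), length(actual) == length(known_visits))
  if (any(actual < 1)) rlang::abort("actual drop-off visits must be >= 1")
  ape <- abs(predicted - actual) / actual
  per <- tibble::tibble(known_visits = known_visits, ape = ape) |>
    dplyr::group_by(.data$known_visits) |>
    dplyr::summarise(mape = mean(.data$ape), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(known_visits = as.character(.data$known_visits))
  dplyr::bind_rows(
    per,
    tibble::tibble(known_visits = "all", mape = mean(ape), n = length(ape))
  )
}
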