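# Seeded synthetic-cohort generator with known ground truth.
#
# Each patient carries a scalar latent disease state following a random walk
# whose drift depends on a binary group covariate; temporal features are noisy
# loadings of that state, and a per-visit drop-off hazard depends on the state
# and its most recent increment. Because every generative rule is explicit,
# correlations, hazards and group effects are all oracle-checkable, which is
# what the downstream model-recovery tests rely on.

#' Configuration of the synthetic cohort generator
#'
#' The latent state follows `s_1 = 0; s_t = s_{t-1} + mu + beta_g * g + e_t`,
#' `e_t ~ N(0, sigma_s^2)`. Continuous temporal feature `j` is
#' `w[j] * s_t + N(0, sigma_e^2)`; the adverse-event flag is
#' `Bernoulli(plogis(kappa * s_t))`; the ordinal temporal feature thresholds
#' `s_t + N(0, sigma_e^2)` at `ord_cuts`. The per-visit drop-off hazard is
#' `plogis(a + b * s_t + c * (s_t - s_{t-1}))`, active from visit `len_min`
#' onwards so journey lengths stay within `[len_min, len_max]`; patients not
#' stopped by the hazard end administratively at a length drawn uniformly from
#' `len_min:len_max` (and get `dropped = FALSE`).
#'
#' @param n_patients Number of patients (>= 2).
#' @param len_min,len_max Journey length bounds (visits).
#' @param n_cont_temporal Number of continuous temporal features (loadings `w`).
#' @param n_cat_temporal,n_ord_temporal 0/1 switches for the adverse-event flag
#'   and the ordinal severity-like temporal feature.
#' @param n_sites Number of site labels in the static site covariate.
#' @param mu Baseline per-visit latent drift.
#' @param beta_g Additional drift for group `g1` (the group effect).
#' @param sigma_s Latent innovation standard deviation.
#' @param sigma_e Observation noise standard deviation.
#' @param w Loadings of the continuous temporal features on the latent state;
#'   recycled/truncated to `n_cont_temporal`.
#' @param kappa Logistic slope of the adverse-event flag on the latent state.
#' @param ord_cuts Two thresholds for the ordinal temporal feature.
#' @param a,b,c Hazard intercept, level slope, and increment slope.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 200, len_min = 2, len_max = 12,
                         n_cont_temporal = 3, n_cat_temporal = 1, n_ord_temporal = 1,
                         n_sites = 3,
                         mu = 0.08, beta_g = 0.35, sigma_s = 0.25, sigma_e = 0.35,
                         w = c(1, 0.8, -0.6), kappa = 1.5, ord_cuts = c(0.4, 1.2),
                         a = -4, b = 1.6, c = 1.6, seed = 1) {
  stopifnot(n_patients >= 2, len_min >= 1, len_max >= len_min, sigma_e > 0,
            sigma_s >= 0, n_cont_temporal >= 1)
  w <- rep_len(w, n_cont_temporal)
  structure(
    list(
      n_patients = as.integer(n_patients), len_min = as.integer(len_min),
      len_max = as.integer(len_max), n_cont_temporal = as.integer(n_cont_temporal),
      n_cat_temporal = as.integer(n_cat_temporal), n_ord_temporal = as.integer(n_ord_temporal),
      n_sites = as.integer(n_sites), mu = mu, beta_g = beta_g, sigma_s = sigma_s,
      sigma_e = sigma_e, w = w, kappa = kappa, ord_cuts = ord_cuts,
      a = a, b = b, c = c, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

synth_schema <- function(config) {
  feats <- dplyr::bind_rows(
    feature_spec("age", "static", "continuous", units = "years"),
    feature_spec("group", "static", "categorical", c("g0", "g1")),
    feature_spec("site", "static", "categorical", paste0("site_", LETTERS[seq_len(config$n_sites)])),
    feature_spec("severity", "static", "ordinal", c("mild", "moderate", "severe")),
    purrr::map_dfr(seq_len(config$n_cont_temporal), function(j) {
      feature_spec(paste0("marker_", j), "temporal", "continuous")
    })
  )
  if (config$n_cat_temporal > 0) {
    feats <- dplyr::bind_rows(feats,
      feature_spec("adverse_event", "temporal", "categorical", c("ae_no", "ae_yes")))
  }
  if (config$n_ord_temporal > 0) {
    feats <- dplyr::bind_rows(feats,
      feature_spec("impairment", "temporal", "ordinal", c("low", "medium", "high")))
  }
  cohort_schema(feats)
}

# Core generative rules, vectorised over patients. Used by both generate() and
# the Monte-Carlo oracles, so oracle and generator share one implementation of
# the *rules* but oracles re-derive expectations by brute-force sampling.
synth_draw <- function(config, n, g = NULL) {
  cf <- config
  if (is.null(g)) g <- stats::rbinom(n, 1, 0.5)
  l_admin <- sample(seq(cf$len_min, cf$len_max), n, replace = TRUE)
  tmax <- cf$len_max
  s <- matrix(0, n, tmax)
  haz <- matrix(0, n, tmax)
  drift <- cf$mu + cf$beta_g * g
  for (t in seq_len(tmax)) {
    prev <- if (t == 1) rep(0, n) else s[, t - 1]
    s[, t] <- if (t == 1) rep(0, n) else prev + drift + stats::rnorm(n, 0, cf$sigma_s)
    haz[, t] <- stats::plogis(cf$a + cf$b * s[, t] + cf$c * (s[, t] - prev))
  }
  u <- matrix(stats::runif(n * tmax), n, tmax)
  trigger <- (u < haz)
  trigger[, seq_len(min(cf$len_min - 1, tmax))] <- FALSE  # hazard active from len_min on
  first_trig <- apply(trigger, 1, function(r) if (any(r)) which(r)[1] else Inf)
  len <- pmin(first_trig, l_admin)
  dropped <- first_trig <= l_admin
  list(g = g, l_admin = l_admin, s = s, haz = haz, len = as.integer(len),
       dropped = dropped, drift = drift)
}

#' Generate a synthetic clinical-trial cohort with ground truth
#'
#' @param config A [synth_config()].
#' @return A list with `cohort` (a validated `cohort`) and `ground_truth`
#'   (class `cohort_ground_truth`): per patient-visit latent states and true
#'   hazards plus per-patient drift, aligned by `patient_id`, and a copy of
#'   the config.
#' @examples
#' gen <- generate_cohort(synth_config(n_patients = 20, seed = 7))
#' gen$cohort
#' @export
generate_cohort <- function(config = synth_config()) {
  cf <- config
  schema <- synth_schema(cf)
  withr::with_seed(cf$seed, {
    n <- cf$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    draw <- synth_draw(cf, n)
    age <- round(pmin(pmax(stats::rnorm(n, 70, 8), 50), 92), 1)
    site <- sample(paste0("site_", LETTERS[seq_len(cf$n_sites)]), n, replace = TRUE)
    severity <- sample(c("mild", "moderate", "severe"), n, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2))
    static <- tibble::tibble(
      patient_id = ids, age = age,
      group = c("g0", "g1")[draw$g + 1], site = site, severity = severity
    )

    idx <- purrr::map_dfr(seq_len(n), function(p) {
      tibble::tibble(row = p, visit = seq_len(draw$len[p]))
    })
    sv <- draw$s[cbind(idx$row, idx$visit)]
    tm <- tibble::tibble(
      patient_id = ids[idx$row], visit = idx$visit,
      dropped_at_visit = as.integer(draw$dropped[idx$row] &
                                      idx$visit == draw$len[idx$row])
    )
    for (j in seq_len(cf$n_cont_temporal)) {
      tm[[paste0("marker_", j)]] <- round(
        cf$w[j] * sv + stats::rnorm(nrow(idx), 0, cf$sigma_e), 6)
    }
    if (cf$n_cat_temporal > 0) {
      tm$adverse_event <- c("ae_no", "ae_yes")[
        1 + stats::rbinom(nrow(idx), 1, stats::plogis(cf$kappa * sv))]
    }
    if (cf$n_ord_temporal > 0) {
      z <- sv + stats::rnorm(nrow(idx), 0, cf$sigma_e)
      tm$impairment <- cut(z, c(-Inf, cf$ord_cuts, Inf),
                           labels = c("low", "medium", "high")) |> as.character()
    }

    cohort <- as_cohort(schema, static, tm)
    gt <- structure(
      list(
        states = tibble::tibble(
          patient_id = ids[idx$row], visit = idx$visit, state = sv,
          hazard = draw$haz[cbind(idx$row, idx$visit)]
        ),
        patients = tibble::tibble(
          patient_id = ids, group = draw$g, drift = draw$drift,
          admin_length = draw$l_admin, length = draw$len, dropped = draw$dropped
        ),
        config = cf
      ),
      class = "cohort_ground_truth"
    )
    list(cohort = cohort, ground_truth = gt)
  })
}

#' Monte-Carlo expected pooled correlation between two continuous temporal features
#'
#' Estimates, by simulating the generative rules at scale under a fixed oracle
#' seed, the pooled Pearson correlation between two continuous temporal
#' features implied by a [synth_config()]. Used to validate the correlation
#' pipeline end to end.
#'
#' @param config A [synth_config()].
#' @param feature_i,feature_j Names (`"marker_1"`, ...) or indices of
#'   continuous temporal features.
#' @param n_visits Approximate number of pooled visits to simulate.
#' @param oracle_seed Seed of the oracle draw (fixed, distinct from cohort seeds).
#' @return A single correlation estimate.
#' @export
expected_correlation <- function(config, feature_i, feature_j,
                                 n_visits = 1e6, oracle_seed = 990001) {
  to_idx <- function(f) {
    if (is.character(f)) {
      if (!grepl("^marker_", f)) rlang::abort("expected_correlation needs continuous temporal features")
      as.integer(sub("marker_", "", f))
    } else as.integer(f)
  }
  i <- to_idx(feature_i); j <- to_idx(feature_j)
  if (i > config$n_cont_temporal || j > config$n_cont_temporal) {
    rlang::abort("feature index outside the continuous temporal features")
  }
  withr::with_seed(oracle_seed, {
    n <- ceiling(n_visits / mean(seq(config$len_min, config$len_max)))
    draw <- synth_draw(config, n)
    keep <- which(outer(seq_len(config$len_max), draw$len, function(t, l) t <= l), arr.ind = TRUE)
    sv <- t(draw$s)[keep[, 1] + (keep[, 2] - 1) * config$len_max]
    xi <- config$w[i] * sv + stats::rnorm(length(sv), 0, config$sigma_e)
    xj <- config$w[j] * sv + stats::rnorm(length(sv), 0, config$sigma_e)
    stats::cor(xi, xj)
  })
}
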