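# Termination-aware journey simulation.
#
# Type A generates whole journeys from static conditionals alone; Type B
# continues a partially observed journey from its encoded prefix. Both run
# the generator and termination network step by step in latent space and
# decode visits through the temporal decoder. Simulations are vectorised
# across the `n_sims` replicates of one patient.

#' Simulation configuration
#'
#' @param n_sims Simulated journeys per patient.
#' @param max_len Maximum journey length (visits).
#' @param rule How the per-step drop-off probability becomes a stop event:
#'   `"bernoulli"` samples it (stochastic journeys, the default) or
#'   `"threshold"` stops deterministically once it exceeds `tau`.
#' @param tau Threshold of the deterministic rule, in (0, 1).
#' @param count_max_len Count journeys stopped by `max_len` at `max_len` when
#'   averaging drop-off visits (`FALSE` excludes them).
#' @param seed Integer seed; per-patient, per-replicate sub-streams are
#'   derived from it so results are reproducible patient by patient.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sims = 1000, max_len = 12, rule = c("bernoulli", "threshold"),
                       tau = 0.5, count_max_len = TRUE, seed = 1) {
  stopifnot(n_sims >= 1, max_len >= 1, tau > 0, tau < 1)
  structure(
    list(n_sims = as.integer(n_sims), max_len = as.integer(max_len),
         rule = rlang::arg_match(rule), tau = tau,
         count_max_len = count_max_len, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# simulate the generated portion for one patient: all replicates as batch rows.
# h_s: n_sims x d_hs; h_prev, term state u carried across steps; t0 = first
# generated visit index. Returns visits long tibble + lengths + cause.
run_sim_loop <- function(fit, h_s, h_prev, u_state, t0, cfg, z_last) {
  model <- fit$model
  p <- model$params
  w_pos <- fit$weights$w_pos %||% 1
  n <- nrow(h_s)
  d_ht <- model$config$d_ht
  active <- rep(TRUE, n)
  len <- rep(cfg$max_len, n)
  cause <- rep("max_len", n)
  rows <- vector("list", cfg$max_len)
  z_prev <- z_last
  t <- t0
  while (t <= cfg$max_len && any(active)) {
    z_t <- z_prev + matrix(stats::rnorm(n * model$config$d_z), n)
    u_state <- f_gru_step(p$term, cbind(h_s, h_prev), u_state)
    p_t <- as.numeric(plogis(ad_value(op_addb(op_mm(u_state, p$term$Wo), p$term$bo))))
    # the termination net is trained with positive-class weight w_pos, which
    # scales the predicted odds by w_pos; map back to the data frequency scale
    p_t <- p_t / (p_t + w_pos * (1 - p_t))
    h_t <- f_gen_step(p$gen, h_s, h_prev, z_t)
    x_t <- ad_value(f_mixed_head(f_mlp(p$dec_t, h_t), model$layout_t))
    stop_now <- if (cfg$rule == "bernoulli") stats::runif(n) < p_t else p_t >= cfg$tau
    stop_now <- stop_now & active
    rows[[t - t0 + 1L]] <- list(visit = t, active = active, drop_prob = p_t, x = x_t)
    len[stop_now] <- t
    cause[stop_now] <- "dropped"
    active <- active & !stop_now
    if (t == cfg$max_len) active[] <- FALSE
    h_prev <- h_t
    z_prev <- z_t
    t <- t + 1L
  }
  list(rows = rows, lengths = len, cause = cause)
}

sim_rows_to_tibble <- function(fit, patient_id, sim_res, prefix_rows = NULL) {
  model <- fit$model
  lay <- model$layout_t
  keep <- purrr::compact(sim_res$rows)
  out <- purrr::map_dfr(keep, function(r) {
    sims <- which(r$active & sim_res$lengths >= r$visit)
    if (!length(sims)) return(NULL)
    df <- tibble::tibble(
      patient_id = patient_id, sim_id = sims, visit = r$visit,
      drop_prob = r$drop_prob[sims]
    )
    for (i in seq_len(nrow(lay))) {
      f <- fit$transform$features[[lay$feature[i]]]
      df[[f$name]] <- decode_column(f, r$x[sims, lay$start[i]:lay$end[i], drop = FALSE])
    }
    df
  })
  dplyr::bind_rows(prefix_rows, out) |>
    dplyr::arrange(.data$sim_id, .data$visit)
}

#' Simulate full journeys from static conditionals (Type A)
#'
#' Encodes each patient's static row, then rolls the generator and the
#' termination network forward from the zero initial latent until the stop
#' rule triggers or `max_len` is reached; every visited step is decoded back
#' to the feature space.
#'
#' @param fit A trained `cohort_gan`.
#' @param static_rows Tibble with `patient_id` plus static feature columns
#'   (schema-valid labels).
#' @param config A [sim_config()].
#' @return A `simulation_set`: long tibble with `patient_id`, `sim_id`,
#'   `visit`, `drop_prob` and decoded temporal features; attributes `lengths`
#'   (tibble patient_id / sim_id / length / cause) and `config`.
#' @export
simulate_type_a <- function(fit, static_rows, config = sim_config()) {
  if (!inherits(fit, "cohort_gan")) rlang::abort("fit must be a cohort_gan")
  model <- fit$model
  lay_s <- transform_layout(fit$transform, "static")
  n_sims <- config$n_sims
  res <- purrr::map(seq_len(nrow(static_rows)), function(i) {
    pid <- static_rows$patient_id[i]
    withr::with_seed(patient_seed(config$seed, pid, 0L), {
      s <- matrix(0, 1, encoded_dim(fit$transform, "static"))
      for (k in seq_len(nrow(lay_s))) {
        f <- fit$transform$features[[lay_s$feature[k]]]
        s[, lay_s$start[k]:lay_s$end[k]] <- encode_column(f, static_rows[[f$name]][i])
      }
      h_s <- encode_static(model, s)[rep(1, n_sims), , drop = FALSE]
      sim <- run_sim_loop(
        fit, h_s,
        h_prev = matrix(0, n_sims, model$config$d_ht),
        u_state = matrix(0, n_sims, model$config$d_term),
        t0 = 1L, cfg = config,
        z_last = matrix(0, n_sims, model$config$d_z)
      )
      list(
        tab = sim_rows_to_tibble(fit, pid, sim),
        len = tibble::tibble(patient_id = pid, sim_id = seq_len(n_sims),
                             length = sim$lengths, cause = sim$cause)
      )
    })
  })
  new_simulation_set(purrr::map_dfr(res, "tab"), purrr::map_dfr(res, "len"), config)
}

#' Forecast journey continuations from observed prefixes (Type B)
#'
#' The observed visits of each patient are teacher-forced through the
#' temporal encoder (and the termination GRU state is advanced through them);
#' generation then continues from the final real latent at visit
#' `T_obs + 1`. The observed prefix is echoed unmodified in every simulated
#' trajectory, with the termination network's fitted per-step probabilities
#' attached.
#'
#' @param fit A trained `cohort_gan`.
#' @param partial_records A `cohort` whose temporal table holds the observed
#'   prefixes (each patient needs `1 <= T_obs < max_len` visits).
#' @param config A [sim_config()].
#' @return A `simulation_set` as in [simulate_type_a()]; prefix visits carry
#'   the real observed values.
#' @export
simulate_type_b <- function(fit, partial_records, config = sim_config()) {
  if (!inherits(fit, "cohort_gan")) rlang::abort("fit must be a cohort_gan")
  model <- fit$model
  p <- model$params
  len <- cohort_lengths(partial_records)
  if (any(len$length >= config$max_len)) {
    rlang::abort("each prefix needs fewer than max_len observed visits")
  }
  if (any(len$length < 1)) rlang::abort("empty prefix: use simulate_type_a")
  batch <- encode_batch(partial_records, fit$transform)
  h_s_all <- encode_static(model, batch$s)
  n_sims <- config$n_sims
  d_ht <- model$config$d_ht

  res <- purrr::map(seq_len(nrow(batch$s)), function(i) {
    pid <- batch$patient_ids[i]
    t_obs <- batch$lengths[i]
    withr::with_seed(patient_seed(config$seed, pid, 1L), {
      h_s1 <- h_s_all[i, , drop = FALSE]
      xl <- purrr::map(seq_len(t_obs), ~ matrix(batch$x[i, .x, ], nrow = 1))
      h_list <- f_encode_seq(p$enc_t, h_s1, xl)
      # advance the termination state through the prefix, collecting its
      # fitted probabilities for the observed visits
      u <- matrix(0, 1, model$config$d_term)
      p_pre <- numeric(t_obs)
      prev <- c(list(matrix(0, 1, d_ht)), h_list[seq_len(t_obs - 1)])
      for (t in seq_len(t_obs)) {
        u <- f_gru_step(p$term, cbind(h_s1, prev[[t]]), u)
        pr <- plogis(ad_value(op_addb(op_mm(u, p$term$Wo), p$term$bo)))[1]
        w_pos <- fit$weights$w_pos %||% 1
        p_pre[t] <- pr / (pr + w_pos * (1 - pr))
      }
      rep_n <- function(m) m[rep(1, n_sims), , drop = FALSE]
      sim <- run_sim_loop(
        fit, rep_n(h_s1),
        h_prev = rep_n(h_list[[t_obs]]),
        u_state = rep_n(u),
        t0 = t_obs + 1L, cfg = config,
        z_last = matrix(0, n_sims, model$config$d_z)
      )
      pre_tab <- partial_records$temporal |>
        dplyr::filter(.data$patient_id == pid) |>
        dplyr::select(-"dropped_at_visit") |>
        dplyr::slice(rep(seq_len(t_obs), n_sims)) |>
        dplyr::mutate(
          sim_id = rep(seq_len(n_sims), each = t_obs),
          drop_prob = rep(p_pre, n_sims), .after = "visit"
        )
      list(
        tab = sim_rows_to_tibble(fit, pid, sim, prefix_rows = pre_tab),
        len = tibble::tibble(patient_id = pid, sim_id = seq_len(n_sims),
                             length = sim$lengths, cause = sim$cause)
      )
    })
  })
  new_simulation_set(purrr::map_dfr(res, "tab"), purrr::map_dfr(res, "len"), config)
}

patient_seed <- function(seed, patient_id, salt) {
  h <- sum(utf8ToInt(as.character(patient_id)) * (31^(seq_len(nchar(as.character(patient_id))) %% 7)))
  (seed * 1000003L + as.integer(h %% 1000003) * 7L + salt * 13L) %% .Machine$integer.max
}

new_simulation_set <- function(visits, lengths, config) {
  structure(visits, class = c("simulation_set", class(visits)),
            lengths = lengths, config = config)
}

#' @export
print.simulation_set <- function(x, ...) {
  len <- attr(x, "lengths")
  cat(sprintf(
    "<simulation_set: %d patients x %d sims, mean length %.2f, %.1f%% dropped>\n",
    dplyr::n_distinct(len$patient_id), attr(x, "config")$n_sims,
    mean(len$length), 100 * mean(len$cause == "dropped")
  ))
  NextMethod()
}

#' Simulation lengths and termination causes
#'
#' @param sims A `simulation_set`.
#' @return Tibble with `patient_id`, `sim_id`, `length`, `cause`.
#' @export
simulation_lengths <- function(sims) attr(sims, "lengths")

#' Simulation-averaged predicted drop-off visit per patient
#'
#' Averages the realised termination visit across a patient's simulated
#' journeys; journeys stopped by the length cap contribute `max_len` unless
#' the configuration excludes them.
#'
#' @param sims A `simulation_set`.
#' @return Tibble with `patient_id` and `predicted_visit`.
#' @export
predict_dropoff_visit <- function(sims) {
  len <- attr(sims, "lengths")
  cfg <- attr(sims, "config")
  if (is.null(len) || nrow(len) == 0) rlang::abort("empty simulation set")
  if (!cfg$count_max_len) len <- dplyr::filter(len, .data$cause == "dropped")
  len |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(predicted_visit = mean(.data$length), .groups = "drop")
}
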