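# Report assembly and reference baselines for generation quality.

#' Convert simulated journeys into a cohort
#'
#' Each (patient, simulation) pair becomes one synthetic patient whose
#' static row is copied from the source patient; the drop-off flag is set at
#' the final visit of trajectories ended by the termination rule.
#'
#' @param sims A `simulation_set`.
#' @param static_rows Static tibble of the simulated patients.
#' @param schema The cohort schema.
#' @param max_sims Keep at most this many simulations per patient.
#' @return A `cohort` of simulated journeys.
#' @export
simulation_cohort <- function(sims, static_rows, schema, max_sims = Inf) {
  len <- simulation_lengths(sims)
  keep <- dplyr::filter(len, .data$sim_id <= max_sims)
  tab <- tibble::as_tibble(sims) |>
    dplyr::filter(.data$sim_id <= max_sims) |>
    dplyr::mutate(new_id = paste0(.data$patient_id, "_s", .data$sim_id))
  keep$new_id <- paste0(keep$patient_id, "_s", keep$sim_id)
  tab <- dplyr::left_join(
    tab,
    dplyr::select(keep, "new_id", final = "length", "cause"),
    by = "new_id"
  )
  temporal <- tab |>
    dplyr::mutate(
      dropped_at_visit = as.integer(.data$cause == "dropped" & .data$visit == .data$final)
    ) |>
    dplyr::select("new_id", "visit", "dropped_at_visit",
                  dplyr::all_of(schema_features(schema, "temporal")$name)) |>
    dplyr::rename(patient_id = "new_id")
  static <- dplyr::left_join(
    dplyr::distinct(dplyr::select(tab, "new_id", src = "patient_id")),
    static_rows, by = c(src = "patient_id")
  ) |>
    dplyr::select(-"src") |>
    dplyr::rename(patient_id = "new_id")
  as_cohort(schema, static, temporal, allow_unknown = TRUE)
}

#' Reference baselines: feature-shuffled real data and Gaussian noise
#'
#' `baseline_shuffled()` permutes each feature column independently (within
#' the pooled visit table and the static table), destroying cross-feature
#' and cross-step structure while keeping every marginal distribution.
#' `baseline_noise()` replaces continuous values with Gaussian noise matched
#' to each feature's moments and labels with uniform draws.
#'
#' @param cohort A `cohort`.
#' @param seed Integer seed.
#' @return A `cohort` of the same shape.
#' @export
baseline_shuffled <- function(cohort, seed = 1) {
  withr::with_seed(seed, {
    st <- cohort$static
    tm <- cohort$temporal
    for (nm in schema_features(cohort$schema, "static")$name) {
      st[[nm]] <- sample(st[[nm]])
    }
    for (nm in schema_features(cohort$schema, "temporal")$name) {
      tm[[nm]] <- sample(tm[[nm]])
    }
    as_cohort(cohort$schema, st, tm)
  })
}

#' @rdname baseline_shuffled
#' @export
baseline_noise <- function(cohort, seed = 1) {
  withr::with_seed(seed, {
    st <- cohort$static
    tm <- cohort$temporal
    sch <- tibble::as_tibble(cohort$schema)
    for (i in seq_len(nrow(sch))) {
      nm <- sch$name[i]
      tab <- if (sch$role[i] == "static") st else tm
      v <- tab[[nm]]
      newv <- if (sch$kind[i] == "continuous") {
        stats::rnorm(length(v), mean(v), stats::sd(v))
      } else {
        sample(sch$levels[[i]], length(v), replace = TRUE)
      }
      if (sch$role[i] == "static") st[[nm]] <- newv else tm[[nm]] <- newv
    }
    as_cohort(cohort$schema, st, tm)
  })
}

#' Full generation-quality report
#'
#' Computes the fidelity, diversity and utility suite for a generated cohort
#' against held-out real data: average correlation difference, Frechet
#' distance and alpha-precision on sequence embeddings, the post-hoc
#' discriminator score, and next-step prediction utility.
#'
#' @param fit A trained `cohort_gan` (supplies the embedding encoder).
#' @param cohort_real_train Real training cohort (for the utility metric).
#' @param cohort_real_test Held-out real cohort.
#' @param cohort_gen Generated cohort.
#' @param alpha Alpha-precision mass.
#' @param seed Seed of the post-hoc models.
#' @param include_utility Compute the (slower) next-step utility metric.
#' @return A `metric_report` list with `acd`, `fid`, `alpha_precision`,
#'   `d_score` (auroc/prauc/f1), `nxsp` (real_mse/gen_mse) and the estimator
#'   `settings`.
#' @export
evaluate_generation <- function(fit, cohort_real_train, cohort_real_test, cohort_gen,
                                alpha = 0.95, seed = 1, include_utility = TRUE) {
  emb_r <- sequence_embeddings(fit, cohort_real_test)
  emb_g <- sequence_embeddings(fit, cohort_gen)
  rep <- list(
    acd = avg_corr_diff(cohort_real_test, cohort_gen),
    fid = fid_score(emb_r, emb_g),
    alpha_precision = alpha_precision(emb_r, emb_g, alpha),
    d_score = discriminator_score(cohort_real_test, cohort_gen, seed = seed,
                                  transform = fit$transform),
    nxsp = if (include_utility) {
      next_step_utility(cohort_real_train, cohort_gen, cohort_real_test,
                        seed = seed, transform = fit$transform)
    },
    settings = list(alpha = alpha, seed = seed, posthoc = posthoc_defaults(),
                    embedding = "final hidden state of the fitted temporal encoder")
  )
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  ACD             %.4f\n", x$acd))
  cat(sprintf("  FID             %.4f\n", x$fid))
  cat(sprintf("  alpha-precision %.4f (alpha = %.2f)\n", x$alpha_precision,
              x$settings$alpha))
  cat(sprintf("  D-score         AUROC %.3f, PRAUC %.3f, F1 %.3f\n",
              x$d_score$auroc, x$d_score$prauc, x$d_score$f1))
  if (!is.null(x$nxsp)) {
    cat(sprintf("  next-step MSE   real %.4f, generated %.4f\n",
                x$nxsp$real_mse, x$nxsp$gen_mse))
  }
  invisible(x)
}
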