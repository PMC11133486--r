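# ggplot2 diagnostics.

#' Loss curves of a training run
#'
#' @param object A `train_log`.
#' @param ... Unused.
#' @return A ggplot: one facet per phase, one line per loss.
#' @export
autoplot.train_log <- function(object, ...) {
  tidy.train_log(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase), scales = "free_x") +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' Simulated trajectory fan for one feature
#'
#' Spaghetti of simulated journeys (thin lines) per patient, with the mean
#' trajectory overlaid.
#'
#' @param object A `simulation_set`.
#' @param feature Temporal feature to plot (continuous).
#' @param patients Optional subset of patient ids.
#' @param max_sims Thin to at most this many simulations per patient.
#' @param ... Unused.
#' @return A ggplot faceted by patient.
#' @export
autoplot.simulation_set <- function(object, feature, patients = NULL, max_sims = 50, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(patients)) df <- dplyr::filter(df, .data$patient_id %in% patients)
  df <- dplyr::filter(df, .data$sim_id <= max_sims)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$visit, y = .data[[feature]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sim_id), alpha = 0.15) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$patient_id)) +
    ggplot2::theme_minimal()
}

#' Real-versus-generated density overlay for each continuous temporal feature
#'
#' @param cohort_real,cohort_gen Cohorts sharing a schema.
#' @return A ggplot of overlaid densities over pooled visits, one facet per
#'   feature.
#' @export
plot_density_overlay <- function(cohort_real, cohort_gen) {
  feats <- schema_features(cohort_real$schema, "temporal")
  feats <- feats$name[feats$kind == "continuous"]
  long <- function(cohort, src) {
    cohort$temporal |>
      dplyr::select(dplyr::all_of(feats)) |>
      tidyr::pivot_longer(dplyr::everything(), names_to = "feature") |>
      dplyr::mutate(source = src)
  }
  dplyr::bind_rows(long(cohort_real, "real"), long(cohort_gen, "generated")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value, fill = .data$source)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free") +
    ggplot2::theme_minimal()
}

#' Look-ahead distance profile
#'
#' @param jsd_table Output of [lookahead_jsd()].
#' @return A ggplot of mean JS distance against look-ahead horizon.
#' @export
plot_lookahead <- function(jsd_table) {
  jsd_table |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(jsd = mean(.data$jsd), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$horizon, y = .data$jsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "look-ahead horizon (steps)", y = "mean JS distance") +
    ggplot2::theme_minimal()
}
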