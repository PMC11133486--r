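# broom-style methods for the package's result types.

#' Tidy the per-epoch loss series of a training log
#'
#' @param x A `train_log`.
#' @param ... Unused.
#' @return Long tibble with `phase`, `epoch`, `loss`, `value`.
#' @export
tidy.train_log <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(c("l_r", "l_s", "l_tr", "l_d", "l_g", "l_auxc")),
                        names_to = "loss", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("phase", "epoch", "loss", "value")
}

#' One-row summary of a training log
#'
#' @param x A `train_log`.
#' @param ... Unused.
#' @return Tibble with final losses and elapsed time.
#' @export
glance.train_log <- function(x, ...) {
  last <- dplyr::slice_tail(tibble::as_tibble(x), n = 1)
  dplyr::select(last, "phase", "epoch", dplyr::all_of(c("l_r", "l_s", "l_tr")),
                dplyr::any_of(c("l_d", "l_g", "l_auxc")), "seconds")
}

#' Tidy a fitted journey model
#'
#' @param x A `cohort_gan`.
#' @param ... Unused.
#' @return Tibble with one row per network component and its parameter count.
#' @export
tidy.cohort_gan <- function(x, ...) {
  count <- function(p) {
    if (is.list(p)) sum(purrr::map_dbl(p, count)) else length(p)
  }
  tibble::tibble(
    component = names(x$model$params),
    parameters = purrr::map_dbl(x$model$params, count)
  )
}

#' One-row summary of a fitted journey model
#'
#' @param x A `cohort_gan`.
#' @param ... Unused.
#' @return Tibble with dimensions, epochs, calibrated loss weights and final
#'   losses.
#' @export
glance.cohort_gan <- function(x, ...) {
  last <- dplyr::slice_tail(dplyr::filter(x$log, .data$phase == "joint"), n = 1)
  tibble::tibble(
    d_hs = x$model$config$d_hs, d_ht = x$model$config$d_ht,
    pretrain_epochs = x$train_config$pretrain_epochs,
    joint_epochs = x$train_config$joint_epochs,
    lambda = x$weights$lambda, eta = x$weights$eta, delta = x$weights$delta,
    w_pos = x$weights$w_pos,
    l_r = last$l_r, l_d = last$l_d, l_g = last$l_g
  )
}

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Long tibble with `metric`, `value`.
#' @export
tidy.metric_report <- function(x, ...) {
  vals <- c(
    acd = x$acd, fid = x$fid, alpha_precision = x$alpha_precision,
    d_auroc = x$d_score$auroc, d_prauc = x$d_score$prauc, d_f1 = x$d_score$f1
  )
  if (!is.null(x$nxsp)) {
    vals <- c(vals, nxsp_real_mse = x$nxsp$real_mse, nxsp_gen_mse = x$nxsp$gen_mse)
  }
  tibble::tibble(metric = names(vals), value = unname(vals))
}

#' Tidy a simulation set
#'
#' @param x A `simulation_set`.
#' @param ... Unused.
#' @return The underlying long visit tibble.
#' @export
tidy.simulation_set <- function(x, ...) tibble::as_tibble(x)

#' One-row-per-patient summary of a simulation set
#'
#' @param x A `simulation_set`.
#' @param ... Unused.
#' @return Tibble with mean simulated length, drop fraction and predicted
#'   drop-off visit.
#' @export
glance.simulation_set <- function(x, ...) {
  simulation_lengths(x) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      mean_length = mean(.data$length),
      drop_rate = mean(.data$cause == "dropped"),
      .groups = "drop"
    ) |>
    dplyr::left_join(predict_dropoff_visit(x), by = "patient_id")
}
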