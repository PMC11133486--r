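# Post-hoc evaluation models: a fresh recurrent sequence classifier for the
# discriminator score and fresh recurrent next-step regressors for the
# utility metric. These are independent of the training discriminator; they
# are small single-layer GRUs with fixed hyper-parameters and seeds, trained
# full-batch with the package's own autodiff.

posthoc_defaults <- function() {
  list(hidden = 8, epochs = 150, lr = 5e-3)
}

# GRU over the raw encoded sequence; returns final observed hidden states
posthoc_embed <- function(p, x_arr, lengths) {
  xl <- array_to_list(x_arr)
  h <- matrix(0, nrow(ad_value(xl[[1]])), gru_dim(p$gru))
  hs <- vector("list", length(xl))
  for (t in seq_along(xl)) {
    h <- f_gru_step(p$gru, xl[[t]], h)
    hs[[t]] <- h
  }
  final_state(hs, lengths)
}

posthoc_init <- function(d_in, hidden, d_out, seed) {
  withr::with_seed(seed, list(
    gru = init_gru(d_in, hidden),
    Wo = glorot(hidden, d_out), bo = rep(0, d_out)
  ))
}

# binary sequence classifier: P(real) from the final hidden state
posthoc_classifier <- function(x_arr, lengths, labels, seed,
                               hp = posthoc_defaults()) {
  d_in <- dim(x_arr)[3]
  params <- posthoc_init(d_in, hp$hidden, 1, seed)
  opt <- adam_init(params)
  y <- matrix(labels, ncol = 1)
  for (ep in seq_len(hp$epochs)) {
    tp <- ad_tape()
    pn <- wrap_params(tp, params)
    hT <- posthoc_embed(pn, x_arr, lengths)
    pr <- op_clamp(op_sigmoid(op_addb(op_mm(hT, pn$Wo), pn$bo)), EPS_PROB, 1 - EPS_PROB)
    loss <- op_scale(op_sum(op_sub(op_scale(op_mul(y, op_log(pr)), -1),
                                   op_mul(1 - y, op_log(op_sub(1, pr))))),
                     1 / length(labels))
    ad_backward(loss)
    up <- adam_apply(list(p = unwrap_values(pn)), list(p = unwrap_grads(pn)),
                     list(p = opt), hp$lr, ep)
    params <- up$params$p; opt <- up$state$p
  }
  list(
    params = params,
    predict = function(x_arr, lengths) {
      hT <- posthoc_embed(params, x_arr, lengths)
      as.numeric(plogis(ad_value(op_addb(op_mm(hT, params$Wo), params$bo))))
    }
  )
}

# next-step regressor: predict x_{t+1} from the hidden state after x_t
posthoc_regressor <- function(x_arr, mask, seed, hp = posthoc_defaults()) {
  d_in <- dim(x_arr)[3]
  params <- posthoc_init(d_in, hp$hidden, d_in, seed)
  opt <- adam_init(params)
  t_max <- dim(x_arr)[2]
  forward_mse <- function(p, x_arr, mask, collect_node = TRUE) {
    xl <- array_to_list(x_arr)
    h <- matrix(0, dim(x_arr)[1], gru_dim(p$gru))
    total <- NULL; denom <- 0
    for (t in seq_len(t_max - 1)) {
      h <- f_gru_step(p$gru, xl[[t]], h)
      pred <- op_addb(op_mm(h, p$Wo), p$bo)
      m <- mask[, t + 1, drop = FALSE]
      diff <- op_sub(pred, xl[[t + 1]])
      total_t <- op_mul(op_rowsums(op_mul(diff, diff)), m)
      total <- if (is.null(total)) total_t else op_add(total, total_t)
      denom <- denom + sum(m) * d_in
    }
    op_scale(op_sum(total), 1 / denom)
  }
  for (ep in seq_len(hp$epochs)) {
    tp <- ad_tape()
    pn <- wrap_params(tp, params)
    loss <- forward_mse(pn, x_arr, mask)
    ad_backward(loss)
    up <- adam_apply(list(p = unwrap_values(pn)), list(p = unwrap_grads(pn)),
                     list(p = opt), hp$lr, ep)
    params <- up$params$p; opt <- up$state$p
  }
  list(
    params = params,
    mse = function(x_arr, mask) as.numeric(ad_value(forward_mse(params, x_arr, mask)))
  )
}

#' Area under the ROC curve (rank statistic)
#'
#' Exact Mann-Whitney AUROC with midrank tie handling.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
binary_auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) rlang::abort("AUROC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_prauc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  # step integration over recall
  sum(diff(c(0, rec)) * prec)
}

binary_f1 <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  if (tp == 0) return(0)
  prec <- tp / sum(pred == 1)
  rec <- tp / sum(labels == 1)
  2 * prec * rec / (prec + rec)
}

#' Post-hoc discriminator score between real and generated cohorts
#'
#' Trains a fresh single-layer recurrent sequence classifier (never the
#' model's own discriminator) on a stratified 70/30 split of the pooled
#' real + generated journeys and reports its held-out classification
#' quality. Values near 0.5 AUROC mean the generated data is
#' indistinguishable from real.
#'
#' @param cohort_real,cohort_gen Cohorts sharing a feature set.
#' @param seed Seed of the split and classifier initialisation.
#' @param transform Optional transform; defaults to a fresh fit on the real
#'   cohort.
#' @return List with `auroc`, `prauc`, `f1`.
#' @export
discriminator_score <- function(cohort_real, cohort_gen, seed = 1, transform = NULL) {
  transform <- transform %||% fit_transform(cohort_real)
  t_max <- max(cohort_lengths(cohort_real)$length, cohort_lengths(cohort_gen)$length)
  br <- encode_batch(cohort_real, transform, t_max)
  bg <- suppressWarnings(encode_batch(cohort_gen, transform, t_max))
  x <- abind3(br$x, bg$x)
  lengths <- c(br$lengths, bg$lengths)
  labels <- c(rep(1, nrow(br$s)), rep(0, nrow(bg$s)))
  n <- length(labels)
  idx_tr <- withr::with_seed(seed, {
    pos <- sample(which(labels == 1), floor(0.7 * sum(labels == 1)))
    neg <- sample(which(labels == 0), floor(0.7 * sum(labels == 0)))
    c(pos, neg)
  })
  idx_te <- setdiff(seq_len(n), idx_tr)
  if (length(unique(labels[idx_te])) < 2) rlang::abort("single-class evaluation fold")
  cls <- posthoc_classifier(x[idx_tr, , , drop = FALSE], lengths[idx_tr],
                            labels[idx_tr], seed)
  sc <- cls$predict(x[idx_te, , , drop = FALSE], lengths[idx_te])
  list(
    auroc = binary_auroc(sc, labels[idx_te]),
    prauc = binary_prauc(sc, labels[idx_te]),
    f1 = binary_f1(sc, labels[idx_te])
  )
}

abind3 <- function(a, b) {
  stopifnot(dim(a)[2] == dim(b)[2], dim(a)[3] == dim(b)[3])
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Next-step prediction utility of generated data
#'
#' Trains two identical post-hoc recurrent next-step predictors — one on the
#' real training cohort, one on the generated cohort — and evaluates both on
#' the common real test cohort. Close MSEs mean the generated data supports
#' the downstream task as well as real data.
#'
#' @param cohort_real_train,cohort_gen,cohort_real_test Cohorts sharing a
#'   feature set.
#' @param seed Seed of both predictors (identical hyper-parameters and
#'   initialisation).
#' @param transform Optional transform; defaults to a fresh fit on the real
#'   training cohort.
#' @return List with `real_mse` and `gen_mse` on the common test set.
#' @export
next_step_utility <- function(cohort_real_train, cohort_gen, cohort_real_test,
                              seed = 1, transform = NULL) {
  transform <- transform %||% fit_transform(cohort_real_train)
  t_max <- max(cohort_lengths(cohort_real_train)$length,
               cohort_lengths(cohort_gen)$length,
               cohort_lengths(cohort_real_test)$length)
  btr <- encode_batch(cohort_real_train, transform, t_max)
  bg <- suppressWarnings(encode_batch(cohort_gen, transform, t_max))
  bte <- suppressWarnings(encode_batch(cohort_real_test, transform, t_max))
  if (all(bte$lengths < 2)) rlang::abort("test set has no next step to predict")
  m_r <- posthoc_regressor(btr$x, btr$mask, seed)
  m_g <- posthoc_regressor(bg$x, bg$mask, seed)
  list(real_mse = m_r$mse(bte$x, bte$mask), gen_mse = m_g$mse(bte$x, bte$mask))
}

#' Gradient-boosted baseline for drop-off visit prediction
#'
#' The predictive comparator: for each number of known visits `k`, an
#' `xgboost` regressor is trained on per-patient features (static encoding
#' plus the mean of each temporal feature over the first `k` visits) to
#' predict the final visit number, and evaluated on the held-out patients
#' who are still enrolled after `k` visits.
#'
#' @param cohort_train,cohort_test Cohorts sharing a feature set.
#' @param known_visits Integer vector of history lengths to evaluate.
#' @param seed Seed.
#' @param nrounds Boosting rounds.
#' @return Tibble with `patient_id`, `known_visits`, `predicted_visit`,
#'   `actual_visit`.
#' @export
baseline_dropoff_xgb <- function(cohort_train, cohort_test, known_visits = 1:4,
                                 seed = 1, nrounds = 50) {
  rlang::check_installed("xgboost")
  transform <- fit_transform(cohort_train)
  feats_at <- function(cohort, k) {
    b <- suppressWarnings(encode_batch(cohort, transform))
    len <- cohort_lengths(cohort)
    keep <- which(len$length > k)
    xm <- t(vapply(keep, function(i) {
      colMeans(matrix(b$x[i, seq_len(k), ], nrow = k), na.rm = TRUE)
    }, numeric(dim(b$x)[3])))
    list(x = cbind(b$s[keep, , drop = FALSE], xm),
         y = len$length[keep], ids = len$patient_id[keep])
  }
  purrr::map_dfr(known_visits, function(k) {
    tr <- feats_at(cohort_train, k)
    te <- feats_at(cohort_test, k)
    if (!nrow(te$x) || !nrow(tr$x)) return(NULL)
    fit <- withr::with_seed(seed, xgboost::xgboost(
      x = tr$x, y = tr$y, nrounds = nrounds, max_depth = 3,
      learning_rate = 0.1, nthread = 1
    ))
    tibble::tibble(
      patient_id = te$ids, known_visits = k,
      predicted_visit = as.numeric(stats::predict(fit, te$x)),
      actual_visit = te$y
    )
  })
}
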