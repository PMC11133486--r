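# Training objectives as pure functions of network outputs. Every loss works
# on plain arrays (for users and tests) and on autodiff tape nodes (for the
# trainer), because all arithmetic goes through the op_* helpers. Norms are
# the non-squared Euclidean norm by default, as the objectives are written;
# `squared = TRUE` switches to the common squared-norm variant.

EPS_PROB <- 1e-7

as_step_list <- function(x) {
  if (is.list(x)) x else array_to_list(x)
}

# row-wise Euclidean norm of (a - b) as an N x 1 column; eps guards the
# gradient of sqrt at zero on the tape path only.
rownorm <- function(a, b, squared = FALSE) {
  d <- op_sub(a, b)
  q <- op_rowsums(op_mul(d, d))
  if (squared) return(q)
  op_sqrt(q, eps = if (ad_is_node(q)) 1e-12 else 0)
}

#' Autoencoder reconstruction loss
#'
#' Mean over patients of the static reconstruction norm plus the sum of
#' per-visit reconstruction norms over observed visits:
#' `E[ ||s - s_hat|| + sum_t ||x_t - x_hat_t|| ]`.
#'
#' @param s,s_hat N x d_s encoded static matrices (real, reconstructed).
#' @param x,x_hat N x T x d_x encoded temporal arrays (or lists of per-step
#'   matrices).
#' @param mask N x T observation mask; padded steps contribute nothing.
#' @param squared Use squared norms instead.
#' @return Scalar loss, >= 0; 0 iff reconstruction is exact on observed
#'   positions.
#' @export
loss_reconstruction <- function(s, s_hat, x, x_hat, mask, squared = FALSE) {
  xl <- as_step_list(x); xhl <- as_step_list(x_hat)
  stopifnot(length(xl) == length(xhl), ncol(mask) == length(xl))
  total <- rownorm(s, s_hat, squared)
  for (t in seq_along(xl)) {
    total <- op_add(total, op_mul(rownorm(xl[[t]], xhl[[t]], squared),
                                  mask[, t, drop = FALSE]))
  }
  scalarize(op_scale(op_sum(total), 1 / nrow(ad_value(s))))
}

#' Termination binary cross-entropy with positive-class weighting
#'
#' Weighted mean over observed steps of
#' `-[w_pos * y * log p + (1 - y) * log(1 - p)]`; probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param p N x T predicted drop-off probabilities (or list of N x 1 columns).
#' @param drop_labels N x T 0/1 labels (1 at the terminal visit of a dropped
#'   patient).
#' @param mask N x T observation mask.
#' @param w_pos Positive-class weight (> 0); the default leaves classes
#'   unweighted.
#' @return Scalar loss >= 0.
#' @export
loss_termination_bce <- function(p, drop_labels, mask, w_pos = 1) {
  if (is.list(p)) p <- purrr::reduce(p, op_cbind)
  if (!all(ad_value(drop_labels) %in% c(0, 1))) rlang::abort("drop labels must be 0/1")
  stopifnot(w_pos > 0)
  pc <- op_clamp(p, EPS_PROB, 1 - EPS_PROB)
  y <- drop_labels
  per <- op_sub(
    op_scale(op_mul(y, op_log(pc)), -w_pos),
    op_mul(1 - y, op_log(op_sub(1, pc)))
  )
  scalarize(op_scale(op_sum(op_mul(per, mask)), 1 / sum(mask)))
}

#' Termination cross-entropy (multi-class drop-off reasons)
#'
#' Per-class weighted mean over observed steps of `-w[y] * log softmax(x)[y]`.
#' With `C = 2` and `w_c = c(1, w_pos)` this reproduces
#' [loss_termination_bce()] when the class-2 logit minus the class-1 logit
#' equals the log-odds of `p`.
#'
#' @param logits N x T x C array (or list of N x C matrices) of class logits.
#' @param class_labels N x T integer matrix with values in `1:C`.
#' @param mask N x T observation mask.
#' @param w_c Length-C class weights.
#' @return Scalar loss >= 0.
#' @export
loss_termination_ce <- function(logits, class_labels, mask, w_c = NULL) {
  ll <- as_step_list(logits)
  C <- ncol(ad_value(ll[[1]]))
  if (C < 2) rlang::abort("need at least 2 classes")
  if (is.null(w_c)) w_c <- rep(1, C)
  lab <- ad_value(class_labels)
  if (any(lab < 1 | lab > C)) rlang::abort(sprintf("class labels must lie in 1..%d", C))
  total <- NULL
  for (t in seq_along(ll)) {
    pr <- op_clamp(op_softmax(ll[[t]]), EPS_PROB, 1)
    onehot <- matrix(0, nrow(lab), C)
    onehot[cbind(seq_len(nrow(lab)), lab[, t])] <- 1
    wrow <- w_c[lab[, t]]
    term <- op_mul(op_rowsums(op_mul(op_log(pr), onehot)),
                   -wrow * mask[, t, drop = FALSE])
    total <- if (is.null(total)) term else op_add(total, term)
  }
  scalarize(op_scale(op_sum(total), 1 / sum(mask)))
}

#' Relativistic (RSGAN) adversarial losses
#'
#' Scores whether real latents look more realistic than generated ones:
#' `L_D = E[ sum_t -log sigmoid(y_t - y_fake_t) ]` and `L_G` with the roles
#' swapped; per-patient sums run over observed steps, then average over the
#' batch. An optional static-level relativistic term is added with weight
#' `static_weight`.
#'
#' @param y_real,y_fake N x T pre-sigmoid discriminator logits for real and
#'   generated sequences, paired by position.
#' @param mask N x T observation mask.
#' @param static_real,static_fake Optional length-N static-level logits.
#' @param static_weight Weight of the static term.
#' @return List with scalars `l_d` and `l_g`, both >= 0. Swapping real and
#'   fake swaps the two.
#' @export
loss_rsgan <- function(y_real, y_fake, mask, static_real = NULL, static_fake = NULL,
                       static_weight = 1) {
  if (is.list(y_real)) y_real <- purrr::reduce(y_real, op_cbind)
  if (is.list(y_fake)) y_fake <- purrr::reduce(y_fake, op_cbind)
  n <- nrow(ad_value(y_real))
  one_side <- function(adv, dis, s_adv, s_dis) {
    per <- op_rowsums(op_mul(op_scale(op_logsigmoid(op_sub(adv, dis)), -1), mask))
    if (!is.null(s_adv)) {
      st <- op_scale(op_logsigmoid(op_sub(s_adv, s_dis)), -static_weight)
      per <- op_add(per, st)
    }
    op_scale(op_sum(per), 1 / n)
  }
  list(
    l_d = scalarize(one_side(y_real, y_fake, static_real, static_fake)),
    l_g = scalarize(one_side(y_fake, y_real, static_fake, static_real))
  )
}

#' Auxiliary-classifier conditional reconstruction loss
#'
#' Mean over real-derived and generated-derived predictions of the norm to
#' the true static latent:
#' `E[ (||h_s - pred_real|| + ||h_s - pred_fake||) / 2 ]`.
#'
#' @param h_s_true N x d_hs true static latents.
#' @param pred_real,pred_fake N x d_hs predictions from the final real /
#'   generated sequence latents. Pass one of them as `NULL` to use a single
#'   source.
#' @param squared Use squared norms.
#' @return Scalar loss >= 0; 0 iff both predictions equal the target.
#' @export
loss_auxc <- function(h_s_true, pred_real, pred_fake = NULL, squared = FALSE) {
  terms <- purrr::compact(list(pred_real, pred_fake))
  per <- purrr::reduce(purrr::map(terms, ~ rownorm(h_s_true, .x, squared)), op_add)
  scalarize(op_scale(op_sum(per), 1 / (length(terms) * nrow(ad_value(h_s_true)))))
}

#' Latent next-step supervised loss
#'
#' `E[ sum_t ||h_t - pred_t|| ]` over observed steps, where `pred_t` is the
#' supervisor's (or generator's, in the joint phase) prediction of `h_t` made
#' from `(h_s, h_{t-1})`; step 1 is predicted from the zero initial state.
#'
#' @param h N x T x d_ht target latents (or per-step list).
#' @param pred Same shape, aligned so `pred[, t, ]` targets `h[, t, ]`.
#' @param mask N x T observation mask.
#' @param squared Use squared norms.
#' @return Scalar loss >= 0.
#' @export
loss_supervised <- function(h, pred, mask, squared = FALSE) {
  hl <- as_step_list(h); pl <- as_step_list(pred)
  stopifnot(length(hl) == length(pl))
  total <- NULL
  for (t in seq_along(hl)) {
    term <- op_mul(rownorm(hl[[t]], pl[[t]], squared), mask[, t, drop = FALSE])
    total <- if (is.null(total)) term else op_add(total, term)
  }
  scalarize(op_scale(op_sum(total), 1 / nrow(ad_value(hl[[1]]))))
}

# collapse a 1 x 1 result to a bare double on the plain path; keep the node
# on the tape path so gradients can flow.
scalarize <- function(x) {
  if (ad_is_node(x)) x else as.numeric(x)
}
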