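# The seven parameterised components of the journey GAN:
#   enc_s  static encoder      MLP   X_s -> H_s
#   enc_t  temporal encoder    GRU   (h_s, h_{t-1}, x_t) -> h_t       (causal)
#   dec_s  static decoder      MLP   H_s -> X_s
#   dec_t  temporal decoder    MLP   H_t -> X_t            (stepwise, no cross-step input)
#   gen    conditional generator GRU (h_s, hhat_{t-1}, z_t) -> hhat_t (causal)
#   sup    supervisor          GRU   (h_s, h_{t-1}) -> hbar_t         (causal)
#   term   termination network GRU   (h_s, h_{t-1}) -> p_t in [0,1]   (causal)
#   disc   discriminator       bi-GRU + MLP heads; sees the whole sequence
#
# All forwards are written against the op_* helpers, so the same code runs on
# plain matrices (inference) and on autodiff tape nodes (training). Latent
# vectors live in (-1, 1): GRU hidden states natively, the static encoder via
# a tanh head. All initial recurrent states are zero vectors.

#' Network configuration
#'
#' @param d_hs Static latent dimension.
#' @param d_ht Temporal latent dimension (also the default noise dimension).
#' @param d_z Noise dimension of the generator (defaults to `d_ht`).
#' @param hidden_mlp Hidden width of the MLP components (encoders/decoders
#'   heads, auxiliary classifier).
#' @param d_disc Hidden width of each direction of the discriminator GRU.
#' @param d_term Hidden width of the termination GRU.
#' @param seed Seed of the parameter initialisation.
#' @return A `net_config` list.
#' @export
net_config <- function(d_hs = 8, d_ht = 16, d_z = d_ht, hidden_mlp = 32,
                       d_disc = 16, d_term = 8, seed = 1) {
  stopifnot(d_hs >= 1, d_ht >= 1, d_z >= 1, hidden_mlp >= 1, d_disc >= 1, d_term >= 1)
  structure(
    list(d_hs = as.integer(d_hs), d_ht = as.integer(d_ht), d_z = as.integer(d_z),
         hidden_mlp = as.integer(hidden_mlp), d_disc = as.integer(d_disc),
         d_term = as.integer(d_term), seed = as.integer(seed)),
    class = "net_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# gate weights fused: Wx maps input to [update | reset | candidate] pre-acts,
# Whzr maps hidden to [update | reset], Whc to the candidate
init_gru <- function(d_in, d_h) {
  list(
    Wx = cbind(glorot(d_in, d_h), glorot(d_in, d_h), glorot(d_in, d_h)),
    Whzr = cbind(glorot(d_h, d_h), glorot(d_h, d_h)),
    Whc = glorot(d_h, d_h),
    b = rep(0, 3 * d_h)
  )
}

gru_dim <- function(p) ncol(ad_value(p$Whc))

init_mlp <- function(d_in, d_hidden, d_out) {
  list(W1 = glorot(d_in, d_hidden), b1 = rep(0, d_hidden),
       W2 = glorot(d_hidden, d_out), b2 = rep(0, d_out))
}

#' Initialise the model from a fitted transform
#'
#' Builds all seven components with dimensionally compatible parameter shapes;
#' two models built from the same `net_config` seed and transform are
#' parameter-identical.
#'
#' @param transform A fitted [fit_transform()] (defines the encoded input and
#'   output dimensions and decoder head layout).
#' @param config A [net_config()].
#' @return A `gan_model`: list with `params` (per component), `config`,
#'   `layout_s`/`layout_t` decoder head layouts and input dims.
#' @export
init_model <- function(transform, config = net_config()) {
  d_s <- encoded_dim(transform, "static")
  d_x <- encoded_dim(transform, "temporal")
  cf <- config
  params <- withr::with_seed(cf$seed, list(
    enc_s = init_mlp(d_s, cf$hidden_mlp, cf$d_hs),
    enc_t = init_gru(cf$d_hs + d_x, cf$d_ht),
    dec_s = init_mlp(cf$d_hs, cf$hidden_mlp, d_s),
    dec_t = init_mlp(cf$d_ht, cf$hidden_mlp, d_x),
    gen = init_gru(cf$d_hs + cf$d_z, cf$d_ht),
    sup = init_gru(cf$d_hs, cf$d_ht),
    term = c(init_gru(cf$d_hs + cf$d_ht, cf$d_term),
             list(Wo = glorot(cf$d_term, 1), bo = 0)),
    disc = list(
      fw = init_gru(cf$d_hs + cf$d_ht, cf$d_disc),
      bw = init_gru(cf$d_hs + cf$d_ht, cf$d_disc),
      head = init_mlp(2 * cf$d_disc, cf$hidden_mlp, 1),
      static_head = init_mlp(cf$d_hs + 2 * cf$d_disc, cf$hidden_mlp, 1)
    ),
    auxc = init_mlp(cf$d_ht, cf$hidden_mlp, cf$d_hs)
  ))
  structure(
    list(params = params, config = cf, d_s = d_s, d_x = d_x,
         layout_s = transform_layout(transform, "static"),
         layout_t = transform_layout(transform, "temporal"),
         phase = "init"),
    class = "gan_model"
  )
}

#' @export
print.gan_model <- function(x, ...) {
  np <- sum(purrr::map_dbl(unlist(x$params, recursive = FALSE, use.names = FALSE),
                           ~ length(ad_value(.x))))
  cat(sprintf("<gan_model: d_hs=%d d_ht=%d, %d parameters, phase=%s>\n",
              x$config$d_hs, x$config$d_ht, np, x$phase))
  invisible(x)
}

# ---- primitive forwards ------------------------------------------------------

f_gru_step <- function(p, x, h) {
  d <- gru_dim(p)
  xa <- op_addb(op_mm(x, p$Wx), p$b)                  # N x 3d pre-activations
  zr <- op_sigmoid(op_add(op_cols(xa, seq_len(2 * d)), op_mm(h, p$Whzr)))
  z <- op_cols(zr, seq_len(d))
  r <- op_cols(zr, d + seq_len(d))
  cand <- op_tanh(op_add(op_cols(xa, 2 * d + seq_len(d)), op_mm(op_mul(r, h), p$Whc)))
  op_add(h, op_mul(z, op_sub(cand, h)))
}

f_mlp <- function(p, x) {
  op_addb(op_mm(op_tanh(op_addb(op_mm(x, p$W1), p$b1)), p$W2), p$b2)
}

# apply sigmoid / per-block softmax heads according to a decoder layout
f_mixed_head <- function(raw, layout) {
  parts <- purrr::map(seq_len(nrow(layout)), function(i) {
    cols <- layout$start[i]:layout$end[i]
    blk <- op_cols(raw, cols)
    if (layout$kind[i] == "categorical") op_softmax(blk) else op_sigmoid(blk)
  })
  purrr::reduce(parts, op_cbind)
}

# x given as list of T matrices (N x d). Returns list of T hidden states.
f_encode_seq <- function(p, h_s, x_list, h0 = NULL) {
  n <- nrow(ad_value(h_s))
  h <- h0 %||% matrix(0, n, gru_dim(p))
  out <- vector("list", length(x_list))
  for (t in seq_along(x_list)) {
    h <- f_gru_step(p, op_cbind(h_s, x_list[[t]]), h)
    out[[t]] <- h
  }
  out
}

f_enc_s <- function(p, s) op_tanh(f_mlp(p, s))
f_aux <- function(p, h) op_tanh(f_mlp(p, h))

# supervisor / generator single steps
f_sup_step <- function(p, h_s, h_prev) f_gru_step(p, h_s, h_prev)
f_gen_step <- function(p, h_s, h_prev, z) f_gru_step(p, op_cbind(h_s, z), h_prev)

# termination probabilities for a latent sequence; input at step t is
# (h_s, h_{t-1}) with h_0 = 0, run through the termination GRU + sigmoid head.
# Returns list of T N x 1 probability matrices.
f_term_seq <- function(p, h_s, h_list_prev) {
  n <- nrow(ad_value(h_s))
  u <- matrix(0, n, gru_dim(p))
  out <- vector("list", length(h_list_prev))
  for (t in seq_along(h_list_prev)) {
    u <- f_gru_step(p, op_cbind(h_s, h_list_prev[[t]]), u)
    out[[t]] <- op_sigmoid(op_addb(op_mm(u, p$Wo), p$bo))
  }
  out
}

# discriminator: per-step logits + one static-level logit.
# h_list must already be masked (padded steps zeroed).
f_disc <- function(p, h_s, h_list) {
  tt <- length(h_list)
  n <- nrow(ad_value(h_s))
  ins <- purrr::map(h_list, ~ op_cbind(h_s, .x))
  hf <- matrix(0, n, gru_dim(p$fw))
  fw <- vector("list", tt)
  for (t in seq_len(tt)) { hf <- f_gru_step(p$fw, ins[[t]], hf); fw[[t]] <- hf }
  hb <- matrix(0, n, gru_dim(p$bw))
  bw <- vector("list", tt)
  for (t in rev(seq_len(tt))) { hb <- f_gru_step(p$bw, ins[[t]], hb); bw[[t]] <- hb }
  step_logits <- purrr::map(seq_len(tt), function(t) f_mlp(p$head, op_cbind(fw[[t]], bw[[t]])))
  static_logit <- f_mlp(p$static_head, op_cbind(op_cbind(h_s, fw[[tt]]), bw[[1]]))
  list(step = step_logits, static = static_logit)
}

# ---- array <-> step-list helpers --------------------------------------------

array_to_list <- function(x) {
  stopifnot(length(dim(x)) == 3)
  purrr::map(seq_len(dim(x)[2]), ~ matrix(x[, .x, ], nrow = dim(x)[1]))
}

list_to_array <- function(lst) {
  n <- nrow(ad_value(lst[[1]])); d <- ncol(ad_value(lst[[1]]))
  out <- array(0, dim = c(n, length(lst), d))
  for (t in seq_along(lst)) out[, t, ] <- ad_value(lst[[t]])
  out
}

mask_cols <- function(mask) purrr::map(seq_len(ncol(mask)), ~ mask[, .x, drop = FALSE])

# select, per patient, the step-t element of a list of matrices at
# t = lengths[n]; gradient-preserving on the tape path (indicator masking)
final_state <- function(h_list, lengths) {
  if (any(purrr::map_lgl(h_list, ad_is_node))) {
    total <- NULL
    for (t in seq_along(h_list)) {
      sel <- as.numeric(lengths == t)
      if (!any(sel > 0)) next
      term <- op_mul(h_list[[t]], sel)
      total <- if (is.null(total)) term else op_add(total, term)
    }
    return(total)
  }
  arr <- list_to_array(h_list)
  n <- dim(arr)[1]; d <- dim(arr)[3]
  out <- matrix(0, n, d)
  for (k in seq_len(d)) out[, k] <- arr[cbind(seq_len(n), lengths, k)]
  out
}

# ---- user-facing forwards ----------------------------------------------------

#' Encode static covariates into the static latent space
#'
#' @param model A `gan_model`.
#' @param s_batch N x d_s encoded static matrix (see [encode_batch()]).
#' @return N x d_hs latent matrix in (-1, 1).
#' @export
encode_static <- function(model, s_batch) {
  ad_value(f_enc_s(model$params$enc_s, s_batch))
}

#' Encode a temporal sequence batch into per-step latents
#'
#' Causal: the step-`t` output depends only on `h_s` and `x[ , 1:t, ]`.
#'
#' @param model A `gan_model`.
#' @param h_s N x d_hs static latents.
#' @param x_batch N x T x d_x encoded temporal array.
#' @param mask Ignored for the forward pass (kept for interface symmetry);
#'   padded steps are excluded by downstream reductions.
#' @return N x T x d_ht latent array.
#' @export
encode_sequence <- function(model, h_s, x_batch, mask = NULL) {
  hs <- f_encode_seq(model$params$enc_t, h_s, array_to_list(x_batch))
  list_to_array(hs)
}

#' Decode latents back to the encoded feature space
#'
#' Continuous/ordinal heads are sigmoids (values in `[0, 1]`); each
#' categorical block is a softmax (probabilities summing to 1). Temporal
#' decoding is stepwise: step `t` outputs depend only on `h[, t, ]`.
#'
#' @param model A `gan_model`.
#' @param h_s N x d_hs static latents.
#' @param h_seq N x T x d_ht temporal latents.
#' @return List with `s_hat` (N x d_s) and `x_hat` (N x T x d_x).
#' @export
decode_latent <- function(model, h_s, h_seq) {
  s_hat <- ad_value(f_mixed_head(f_mlp(model$params$dec_s, h_s), model$layout_s))
  x_hat <- list_to_array(purrr::map(
    array_to_list(h_seq),
    ~ f_mixed_head(f_mlp(model$params$dec_t, .x), model$layout_t)
  ))
  list(s_hat = s_hat, x_hat = x_hat)
}

#' One autoregressive generator step
#'
#' @param model A `gan_model`.
#' @param h_s N x d_hs static latents.
#' @param h_prev N x d_ht previous generated latent (zero matrix at t = 1).
#' @param z N x d_z noise (a Wiener-path increment state, see [wiener_path()]).
#' @return N x d_ht generated latent.
#' @export
generate_step <- function(model, h_s, h_prev, z) {
  ad_value(f_gen_step(model$params$gen, h_s, h_prev, z))
}

#' One supervisor step (next-latent prediction, no noise)
#'
#' @inheritParams generate_step
#' @return N x d_ht predicted next latent.
#' @export
supervise_step <- function(model, h_s, h_prev) {
  ad_value(f_sup_step(model$params$sup, h_s, h_prev))
}

#' Per-step drop-off probabilities along a latent trajectory
#'
#' The step-`t` probability conditions on `(h_s, h_{t-1})` (with `h_0 = 0`),
#' so it is causal in the latent sequence.
#'
#' @param model A `gan_model`.
#' @param h_s N x d_hs static latents.
#' @param h_seq N x T x d_ht latent trajectory (`h_1, ..., h_T`).
#' @return N x T matrix of probabilities in `[0, 1]`; column `t` is the
#'   probability that visit `t` is the journey's last.
#' @export
termination_prob <- function(model, h_s, h_seq) {
  tt <- dim(h_seq)[2]
  prev <- c(list(matrix(0, dim(h_seq)[1], dim(h_seq)[3])),
            array_to_list(h_seq)[seq_len(tt - 1)])
  ps <- f_term_seq(model$params$term, h_s, prev)
  do.call(cbind, purrr::map(ps, ad_value))
}

#' Discriminator scores for a (static, sequence) latent pair
#'
#' Bi-directional, so a step score may depend on future steps. Padded steps
#' are zeroed out of the inputs via `mask`.
#'
#' @param model A `gan_model`.
#' @param h_s N x d_hs static latents.
#' @param h_seq N x T x d_ht latent sequence (real or generated).
#' @param mask N x T observation mask.
#' @return List with `static` (length-N vector) and `step` (N x T matrix) of
#'   scores in `[0, 1]`.
#' @export
discriminate <- function(model, h_s, h_seq, mask) {
  h_list <- purrr::map2(array_to_list(h_seq), mask_cols(mask),
                        ~ .x * as.numeric(.y))
  out <- f_disc(model$params$disc, h_s, h_list)
  list(
    static = as.numeric(stats::plogis(ad_value(out$static))),
    step = stats::plogis(do.call(cbind, purrr::map(out$step, ad_value)))
  )
}

#' Predict the static latent from a final-step sequence latent
#'
#' @param model A `gan_model`.
#' @param h_final N x d_ht final observed-step latents (select them with the
#'   per-patient `lengths`, e.g. via [sequence_embeddings()]).
#' @return N x d_hs prediction of the static latent.
#' @export
aux_predict <- function(model, h_final) {
  ad_value(f_aux(model$params$auxc, h_final))
}

#' Draw a Wiener noise path
#'
#' Cumulative standard-normal increments: `z_0 = 0`,
#' `z_t = z_{t-1} + N(0, I)` (unit time step).
#'
#' @param n Number of paths (batch rows).
#' @param d Noise dimension.
#' @param t_max Number of steps.
#' @return N x t_max x d array of noise states.
#' @export
wiener_path <- function(n, d, t_max) {
  incr <- array(stats::rnorm(n * t_max * d), dim = c(n, t_max, d))
  z <- array(0, dim = c(n, t_max, d))
  z[, 1, ] <- incr[, 1, ]
  if (t_max > 1) for (t in 2:t_max) z[, t, ] <- z[, t - 1, ] + incr[, t, ]
  z
}
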