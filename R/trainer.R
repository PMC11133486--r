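# Two-phase optimisation: supervised pre-training of the autoencoder,
# supervisor and termination network, then joint adversarial training of all
# components. Each update builds a fresh autodiff tape over the component
# being updated (other components enter as constants), so no gradient ever
# reaches a component outside its own update step.

#' Training configuration
#'
#' Desk-scale defaults (200 / 500 epochs) train the model on a few hundred
#' patients in minutes on one CPU; the original-scale schedule (2500
#' pre-training epochs per component, 10000 joint epochs) is a matter of
#' raising the two epoch counts.
#'
#' @param pretrain_epochs,joint_epochs Epochs of the two phases (>= 1).
#' @param batch_size Minibatch size (patients).
#' @param lr_supervised Learning rate of autoencoder, supervisor and
#'   termination updates.
#' @param lr_adversarial Learning rate of generator, discriminator and
#'   auxiliary-classifier updates.
#' @param lambda,eta,delta Relative weights of the supervised loss in the
#'   autoencoder objective, and of the supervised and auxiliary terms in the
#'   generator objective. `NULL` auto-calibrates each at the start of the
#'   joint phase so its weighted loss matches the adversarial loss magnitude
#'   (calibrated values are logged); during pre-training `lambda` falls back
#'   to 1.
#' @param sup_emphasis Multiplier applied to the adversarial loss magnitude
#'   when auto-calibrating `eta`: the supervised next-latent term is weighted
#'   to dominate the adversarial signal by this factor, anchoring the level
#'   and drift of free-running generation. Ignored when `eta` is given.
#' @param w_pos Positive-class weight of the termination loss; `NULL`
#'   computes (non-terminal observed steps) / (terminal steps) on the
#'   training split.
#' @param static_score_weight Weight of the discriminator's static-level
#'   relativistic term.
#' @param loop_mode `"open"` (generator conditioned on its own previous
#'   generation), `"closed"` (teacher-forced on ground truth) or
#'   `"alternating"` (per-epoch alternation, the default).
#' @param auxc_target `"h_s"` (predict the static conditional latent) or
#'   `"h_T"` (match real and generated final sequence latents).
#' @param squared_norm Use squared Euclidean norms in the MSE-type losses.
#' @param seed Seed governing shuffling, noise draws and initial states.
#' @param log_every Record the loss series every this many epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(pretrain_epochs = 200, joint_epochs = 500, batch_size = 64,
                         lr_supervised = 1e-3, lr_adversarial = 5e-4,
                         lambda = NULL, eta = NULL, delta = NULL,
                         sup_emphasis = 5, w_pos = NULL,
                         static_score_weight = 1,
                         loop_mode = c("alternating", "open", "closed"),
                         auxc_target = c("h_s", "h_T"),
                         squared_norm = FALSE, seed = 1, log_every = 1) {
  stopifnot(pretrain_epochs >= 1, joint_epochs >= 1, batch_size >= 1)
  structure(
    list(pretrain_epochs = as.integer(pretrain_epochs),
         joint_epochs = as.integer(joint_epochs), batch_size = as.integer(batch_size),
         lr_supervised = lr_supervised, lr_adversarial = lr_adversarial,
         lambda = lambda, eta = eta, delta = delta,
         sup_emphasis = sup_emphasis, w_pos = w_pos,
         static_score_weight = static_score_weight,
         loop_mode = rlang::arg_match(loop_mode),
         auxc_target = rlang::arg_match(auxc_target),
         squared_norm = squared_norm, seed = as.integer(seed),
         log_every = as.integer(log_every)),
    class = "train_config"
  )
}

# ---- parameter plumbing ------------------------------------------------------

wrap_params <- function(tape, p) {
  if (is.list(p)) lapply(p, function(q) wrap_params(tape, q)) else ad_param(tape, p)
}

unwrap_grads <- function(p) {
  if (is.list(p)) lapply(p, unwrap_grads)
  else if (is.null(p$grad)) p$value * 0 else p$grad
}

unwrap_values <- function(p) {
  if (is.list(p)) lapply(p, unwrap_values) else p$value
}

adam_init <- function(p) {
  if (is.list(p)) lapply(p, adam_init) else list(m = p * 0, v = p * 0)
}

adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p) && !identical(names(p), c("m", "v"))) {
    out <- purrr::pmap(list(p, g, st), adam_step, lr = lr, t = t, b1 = b1, b2 = b2, eps = eps)
    return(list(params = purrr::map(out, "params"), state = purrr::map(out, "state")))
  }
  m <- b1 * st$m + (1 - b1) * g
  v <- b2 * st$v + (1 - b2) * g * g
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  r <- p - lr * mh / (sqrt(vh) + eps)
  # keep the parameter's own shape; gradients may carry stray dimnames
  r <- if (is.matrix(p)) structure(as.numeric(r), dim = dim(p)) else as.numeric(r)
  list(params = r, state = list(m = m, v = v))
}

# leaf test for adam_step recursion: a raw parameter is numeric, a component
# is a list; adam state leaves are list(m, v) which the identical() guard spots
adam_apply <- function(params, grads, state, lr, t) {
  out <- purrr::pmap(list(params, grads, state), function(p, g, s) {
    if (is.list(p)) adam_apply(p, g, s, lr, t) else {
      r <- adam_step(p, g, s, lr, t)
      list(params = r$params, state = r$state)
    }
  })
  list(params = purrr::map(out, "params"), state = purrr::map(out, "state"))
}

grad_norm <- function(g) {
  if (is.list(g)) sqrt(sum(purrr::map_dbl(g, ~ grad_norm(.x)^2))) else sqrt(sum(g * g))
}

check_finite <- function(value, component, epoch) {
  if (!is.finite(value)) {
    rlang::abort(sprintf(
      "non-finite loss (%s) in component '%s' at epoch %d; try a lower learning rate",
      format(value), component, epoch
    ))
  }
  value
}

slice_batch <- function(batch, idx) {
  list(
    s = batch$s[idx, , drop = FALSE],
    x = batch$x[idx, , , drop = FALSE],
    mask = batch$mask[idx, , drop = FALSE],
    lengths = batch$lengths[idx],
    drop_labels = batch$drop_labels[idx, , drop = FALSE],
    patient_ids = batch$patient_ids[idx]
  )
}

default_w_pos <- function(batch) {
  pos <- sum(batch$drop_labels)
  neg <- sum(batch$mask) - pos
  if (pos == 0) 1 else neg / pos
}

# ---- shared forward fragments ------------------------------------------------

fwd_latents <- function(p_enc_s, p_enc_t, mb) {
  h_s <- f_enc_s(p_enc_s, mb$s)
  h_list <- f_encode_seq(p_enc_t, h_s, array_to_list(mb$x))
  list(h_s = h_s, h_list = h_list)
}

prev_list <- function(h_list, n, d) {
  c(list(matrix(0, n, d)), h_list[seq_len(length(h_list) - 1)])
}

sup_predictions <- function(p_sup, h_s, h_list, n, d) {
  purrr::map(prev_list(h_list, n, d), ~ f_sup_step(p_sup, h_s, .x))
}

gen_sequence <- function(p_gen, h_s, z_list, mode, h_list_real, n, d) {
  out <- vector("list", length(z_list))
  prev <- matrix(0, n, d)
  for (t in seq_along(z_list)) {
    out[[t]] <- f_gen_step(p_gen, h_s, prev, z_list[[t]])
    prev <- if (mode == "closed" && t <= length(h_list_real)) h_list_real[[t]] else out[[t]]
  }
  out
}

masked_lat <- function(h_list, mask) {
  purrr::map2(h_list, mask_cols(mask), ~ op_mul(.x, as.numeric(.y)))
}

# ---- pre-training ------------------------------------------------------------

#' Pre-train the supervised components (autoencoder, supervisor, termination)
#'
#' Minimises `lambda * L_S + L_R` over the autoencoder, `L_S` over the
#' supervisor, and the weighted termination cross-entropy over the
#' termination network, leaving the generator, discriminator and auxiliary
#' classifier untouched. Deterministic given the seed.
#'
#' @param model A `gan_model` from [init_model()].
#' @param batch An `encoded_batch` of the training split.
#' @param config A [train_config()].
#' @return List with the updated `model` and a `train_log` tibble of
#'   per-epoch losses.
#' @export
pretrain <- function(model, batch, config = train_config()) {
  cf <- config
  d_ht <- model$config$d_ht
  lambda <- cf$lambda %||% 1
  w_pos <- cf$w_pos %||% default_w_pos(batch)
  params <- model$params
  opt <- list(ae = NULL, sup = NULL, term = NULL)
  steps <- c(ae = 0, sup = 0, term = 0)
  n_all <- nrow(batch$s)
  logs <- vector("list", cf$pretrain_epochs)
  t0 <- Sys.time()

  withr::with_seed(cf$seed, {
    for (epoch in seq_len(cf$pretrain_epochs)) {
      idx <- sample(n_all)
      chunks <- split(idx, ceiling(seq_along(idx) / cf$batch_size))
      ep <- c(l_r = 0, l_s = 0, l_tr = 0)
      for (ch in chunks) {
        mb <- slice_batch(batch, ch)
        n <- length(ch)
        xl <- array_to_list(mb$x)

        # autoencoder update (supervisor and termination are constants)
        tp <- ad_tape()
        pe <- list(enc_s = wrap_params(tp, params$enc_s),
                   enc_t = wrap_params(tp, params$enc_t),
                   dec_s = wrap_params(tp, params$dec_s),
                   dec_t = wrap_params(tp, params$dec_t))
        lat <- fwd_latents(pe$enc_s, pe$enc_t, mb)
        s_hat <- f_mixed_head(f_mlp(pe$dec_s, lat$h_s), model$layout_s)
        x_hat <- purrr::map(lat$h_list, ~ f_mixed_head(f_mlp(pe$dec_t, .x), model$layout_t))
        l_r <- loss_reconstruction(mb$s, s_hat, xl, x_hat, mb$mask, cf$squared_norm)
        preds <- sup_predictions(params$sup, lat$h_s, lat$h_list, n, d_ht)
        l_s <- loss_supervised(lat$h_list, preds, mb$mask, cf$squared_norm)
        total <- op_add(l_r, op_scale(l_s, lambda))
        ad_backward(total)
        check_finite(ad_value(l_r)[1], "autoencoder", epoch)
        if (is.null(opt$ae)) opt$ae <- adam_init(unwrap_values(pe))
        steps["ae"] <- steps["ae"] + 1
        up <- adam_apply(unwrap_values(pe), unwrap_grads(pe), opt$ae,
                         cf$lr_supervised, steps["ae"])
        params[c("enc_s", "enc_t", "dec_s", "dec_t")] <- up$params
        opt$ae <- up$state

        # supervisor update on the refreshed latents
        lat_p <- fwd_latents(params$enc_s, params$enc_t, mb)
        tp <- ad_tape()
        ps <- wrap_params(tp, params$sup)
        preds <- sup_predictions(ps, lat_p$h_s, lat_p$h_list, n, d_ht)
        l_s2 <- loss_supervised(lat_p$h_list, preds, mb$mask, cf$squared_norm)
        ad_backward(l_s2)
        check_finite(ad_value(l_s2)[1], "supervisor", epoch)
        if (is.null(opt$sup)) opt$sup <- adam_init(unwrap_values(ps))
        steps["sup"] <- steps["sup"] + 1
        up <- adam_apply(list(sup = unwrap_values(ps)), list(sup = unwrap_grads(ps)),
                         list(sup = opt$sup), cf$lr_supervised, steps["sup"])
        params$sup <- up$params$sup
        opt$sup <- up$state$sup

        # termination update
        tp <- ad_tape()
        pt <- wrap_params(tp, params$term)
        p_seq <- f_term_seq(pt, lat_p$h_s, prev_list(lat_p$h_list, n, d_ht))
        l_tr <- loss_termination_bce(p_seq, mb$drop_labels, mb$mask, w_pos)
        ad_backward(l_tr)
        check_finite(ad_value(l_tr)[1], "termination", epoch)
        if (is.null(opt$term)) opt$term <- adam_init(unwrap_values(pt))
        steps["term"] <- steps["term"] + 1
        up <- adam_apply(list(term = unwrap_values(pt)), list(term = unwrap_grads(pt)),
                         list(term = opt$term), cf$lr_supervised, steps["term"])
        params$term <- up$params$term
        opt$term <- up$state$term

        w <- length(ch) / n_all
        ep <- ep + w * c(ad_value(l_r)[1], ad_value(l_s2)[1], ad_value(l_tr)[1])
      }
      logs[[epoch]] <- tibble::tibble(
        phase = "pretrain", epoch = epoch, l_r = ep["l_r"], l_s = ep["l_s"],
        l_tr = ep["l_tr"], l_d = NA_real_, l_g = NA_real_, l_auxc = NA_real_,
        seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
    }
  })
  model$params <- params
  model$phase <- "pretrained"
  keep <- seq(1, cf$pretrain_epochs, by = cf$log_every)
  list(model = model, log = new_train_log(dplyr::bind_rows(logs[keep]), cf))
}

# ---- joint training ----------------------------------------------------------

#' Jointly train all components adversarially
#'
#' Per minibatch: (1) discriminator and auxiliary classifier on real and
#' generated latents; (2) generator on its relativistic term plus
#' `eta * L_S + delta * L_AuxC`; (3) autoencoder fine-tuning on
#' `lambda * L_S + L_R`; (4) supervisor and (5) termination fine-tuning on
#' the updated latent space. The generator's adversarial pass is conditioned
#' on its own previous generation (open loop), on ground truth (closed), or
#' alternates per epoch.
#'
#' @inheritParams pretrain
#' @return List with the updated `model`, a `train_log`, and the calibrated
#'   `weights` (lambda, eta, delta, w_pos).
#' @export
joint_train <- function(model, batch, config = train_config()) {
  cf <- config
  d_ht <- model$config$d_ht
  w_pos <- cf$w_pos %||% default_w_pos(batch)
  params <- model$params
  n_all <- nrow(batch$s)
  logs <- vector("list", cf$joint_epochs)
  t0 <- Sys.time()
  sat_count <- 0L; sat_warned <- FALSE

  # one full-batch pass to calibrate loss weights to the adversarial magnitude
  cal <- withr::with_seed(cf$seed + 1L, {
    mb <- batch
    n <- n_all
    lat <- fwd_latents(params$enc_s, params$enc_t, mb)
    z <- array_to_list(wiener_path(n, model$config$d_z, ncol(mb$mask)))
    fake <- gen_sequence(params$gen, lat$h_s, z, "open", lat$h_list, n, d_ht)
    dr <- f_disc(params$disc, lat$h_s, masked_lat(lat$h_list, mb$mask))
    df <- f_disc(params$disc, lat$h_s, masked_lat(fake, mb$mask))
    adv <- loss_rsgan(dr$step, df$step, mb$mask, dr$static, df$static,
                      cf$static_score_weight)
    dec <- decode_latent(model, ad_value(lat$h_s), list_to_array(lat$h_list))
    l_r0 <- loss_reconstruction(mb$s, dec$s_hat, mb$x, dec$x_hat, mb$mask, cf$squared_norm)
    preds <- sup_predictions(params$sup, lat$h_s, lat$h_list, n, d_ht)
    l_s0 <- loss_supervised(lat$h_list, preds, mb$mask, cf$squared_norm)
    aux_r <- f_aux(params$auxc, final_state(lat$h_list, mb$lengths))
    aux_f <- f_aux(params$auxc, final_state(fake, mb$lengths))
    l_a0 <- loss_auxc(lat$h_s, aux_r, aux_f, cf$squared_norm)
    ref <- abs(ad_value(adv$l_g)[1])
    # the supervised term is calibrated to dominate the adversarial signal
    # (sup_emphasis x its magnitude): one-step supervision anchors the level
    # and drift of free-running rollouts, which pure adversarial feedback
    # controls only weakly at this scale
    list(
      lambda = cf$lambda %||% max(abs(l_r0) / max(l_s0, 1e-8), 1e-4),
      eta = cf$eta %||% max(cf$sup_emphasis * ref / max(l_s0, 1e-8), 1e-4),
      delta = cf$delta %||% max(ref / max(l_a0, 1e-8), 1e-4)
    )
  })

  opt <- list()
  steps <- c(disc = 0, gen = 0, ae = 0, sup = 0, term = 0)

  withr::with_seed(cf$seed + 2L, {
    for (epoch in seq_len(cf$joint_epochs)) {
      mode <- switch(cf$loop_mode,
        open = "open", closed = "closed",
        alternating = if (epoch %% 2 == 1) "open" else "closed")
      idx <- sample(n_all)
      chunks <- split(idx, ceiling(seq_along(idx) / cf$batch_size))
      ep <- c(l_r = 0, l_s = 0, l_tr = 0, l_d = 0, l_g = 0, l_auxc = 0)
      for (ch in chunks) {
        mb <- slice_batch(batch, ch)
        n <- length(ch)
        t_max <- ncol(mb$mask)
        z <- array_to_list(wiener_path(n, model$config$d_z, t_max))

        lat <- fwd_latents(params$enc_s, params$enc_t, mb)
        h_s_v <- ad_value(lat$h_s)

        # (1) discriminator + auxiliary classifier (fakes held constant)
        fake_v <- gen_sequence(params$gen, h_s_v, z, mode, lat$h_list, n, d_ht)
        tp <- ad_tape()
        pd <- wrap_params(tp, params$disc)
        pa <- wrap_params(tp, params$auxc)
        dr <- f_disc(pd, h_s_v, masked_lat(lat$h_list, mb$mask))
        df <- f_disc(pd, h_s_v, masked_lat(fake_v, mb$mask))
        adv <- loss_rsgan(dr$step, df$step, mb$mask, dr$static, df$static,
                          cf$static_score_weight)
        if (cf$auxc_target == "h_s") {
          aux_r <- f_aux(pa, final_state(lat$h_list, mb$lengths))
          aux_f <- f_aux(pa, final_state(fake_v, mb$lengths))
          l_aux <- loss_auxc(h_s_v, aux_r, aux_f, cf$squared_norm)
        } else {
          aux_f <- f_aux(pa, final_state(fake_v, mb$lengths))
          l_aux <- loss_auxc(final_state(lat$h_list, mb$lengths), aux_f, NULL,
                             cf$squared_norm)
        }
        total_d <- op_add(adv$l_d, l_aux)
        ad_backward(total_d)
        check_finite(ad_value(adv$l_d)[1], "discriminator", epoch)
        check_finite(ad_value(l_aux)[1], "auxiliary classifier", epoch)
        if (is.null(opt$disc)) {
          opt$disc <- adam_init(unwrap_values(pd)); opt$auxc <- adam_init(unwrap_values(pa))
        }
        steps["disc"] <- steps["disc"] + 1
        up <- adam_apply(list(d = unwrap_values(pd)), list(d = unwrap_grads(pd)),
                         list(d = opt$disc), cf$lr_adversarial, steps["disc"])
        params$disc <- up$params$d; opt$disc <- up$state$d
        up <- adam_apply(list(a = unwrap_values(pa)), list(a = unwrap_grads(pa)),
                         list(a = opt$auxc), cf$lr_adversarial, steps["disc"])
        params$auxc <- up$params$a; opt$auxc <- up$state$a

        # (2) generator (discriminator/auxc constant)
        tp <- ad_tape()
        pg <- wrap_params(tp, params$gen)
        fake <- gen_sequence(pg, h_s_v, z, mode, lat$h_list, n, d_ht)
        df <- f_disc(params$disc, h_s_v, masked_lat(fake, mb$mask))
        dr_v <- f_disc(params$disc, h_s_v, masked_lat(lat$h_list, mb$mask))
        adv_g <- loss_rsgan(dr_v$step, df$step, mb$mask, dr_v$static, df$static,
                            cf$static_score_weight)
        # supervised term: teacher-forced next-latent predictions of G
        gen_tf <- purrr::map2(prev_list(lat$h_list, n, d_ht), z,
                              ~ f_gen_step(pg, h_s_v, .x, .y))
        l_s_g <- loss_supervised(lat$h_list, gen_tf, mb$mask, cf$squared_norm)
        if (cf$auxc_target == "h_s") {
          aux_fake <- f_aux(params$auxc, final_state(fake, mb$lengths))
          l_aux_g <- loss_auxc(h_s_v, aux_fake, NULL, cf$squared_norm)
        } else {
          aux_fake <- f_aux(params$auxc, final_state(fake, mb$lengths))
          l_aux_g <- loss_auxc(final_state(lat$h_list, mb$lengths), aux_fake, NULL,
                               cf$squared_norm)
        }
        total_g <- op_add(adv_g$l_g,
                          op_add(op_scale(l_s_g, cal$eta), op_scale(l_aux_g, cal$delta)))
        ad_backward(total_g)
        check_finite(ad_value(adv_g$l_g)[1], "generator", epoch)
        if (is.null(opt$gen)) opt$gen <- adam_init(unwrap_values(pg))
        steps["gen"] <- steps["gen"] + 1
        gn <- grad_norm(unwrap_grads(pg))
        sat_count <- if (gn < 1e-12) sat_count + 1L else 0L
        if (sat_count >= 50 && !sat_warned) {
          rlang::warn("discriminator saturation: generator gradient ~ 0 for 50 steps")
          sat_warned <- TRUE
        }
        up <- adam_apply(list(g = unwrap_values(pg)), list(g = unwrap_grads(pg)),
                         list(g = opt$gen), cf$lr_adversarial, steps["gen"])
        params$gen <- up$params$g; opt$gen <- up$state$g

        # (3) autoencoder fine-tuning
        tp <- ad_tape()
        pe <- list(enc_s = wrap_params(tp, params$enc_s),
                   enc_t = wrap_params(tp, params$enc_t),
                   dec_s = wrap_params(tp, params$dec_s),
                   dec_t = wrap_params(tp, params$dec_t))
        lat2 <- fwd_latents(pe$enc_s, pe$enc_t, mb)
        s_hat <- f_mixed_head(f_mlp(pe$dec_s, lat2$h_s), model$layout_s)
        x_hat <- purrr::map(lat2$h_list, ~ f_mixed_head(f_mlp(pe$dec_t, .x), model$layout_t))
        l_r <- loss_reconstruction(mb$s, s_hat, array_to_list(mb$x), x_hat, mb$mask,
                                   cf$squared_norm)
        preds <- sup_predictions(params$sup, lat2$h_s, lat2$h_list, n, d_ht)
        l_s <- loss_supervised(lat2$h_list, preds, mb$mask, cf$squared_norm)
        ad_backward(op_add(l_r, op_scale(l_s, cal$lambda)))
        check_finite(ad_value(l_r)[1], "autoencoder", epoch)
        if (is.null(opt$ae)) opt$ae <- adam_init(unwrap_values(pe))
        steps["ae"] <- steps["ae"] + 1
        up <- adam_apply(unwrap_values(pe), unwrap_grads(pe), opt$ae,
                         cf$lr_supervised, steps["ae"])
        params[c("enc_s", "enc_t", "dec_s", "dec_t")] <- up$params
        opt$ae <- up$state

        # (4) supervisor and (5) termination on the refreshed latent space
        lat3 <- fwd_latents(params$enc_s, params$enc_t, mb)
        tp <- ad_tape()
        ps <- wrap_params(tp, params$sup)
        preds <- sup_predictions(ps, lat3$h_s, lat3$h_list, n, d_ht)
        l_s2 <- loss_supervised(lat3$h_list, preds, mb$mask, cf$squared_norm)
        ad_backward(l_s2)
        check_finite(ad_value(l_s2)[1], "supervisor", epoch)
        if (is.null(opt$sup)) opt$sup <- adam_init(unwrap_values(ps))
        steps["sup"] <- steps["sup"] + 1
        up <- adam_apply(list(s = unwrap_values(ps)), list(s = unwrap_grads(ps)),
                         list(s = opt$sup), cf$lr_supervised, steps["sup"])
        params$sup <- up$params$s; opt$sup <- up$state$s

        tp <- ad_tape()
        pt <- wrap_params(tp, params$term)
        p_seq <- f_term_seq(pt, lat3$h_s, prev_list(lat3$h_list, n, d_ht))
        l_tr <- loss_termination_bce(p_seq, mb$drop_labels, mb$mask, w_pos)
        ad_backward(l_tr)
        check_finite(ad_value(l_tr)[1], "termination", epoch)
        if (is.null(opt$term)) opt$term <- adam_init(unwrap_values(pt))
        steps["term"] <- steps["term"] + 1
        up <- adam_apply(list(t = unwrap_values(pt)), list(t = unwrap_grads(pt)),
                         list(t = opt$term), cf$lr_supervised, steps["term"])
        params$term <- up$params$t; opt$term <- up$state$t

        w <- length(ch) / n_all
        ep <- ep + w * c(ad_value(l_r)[1], ad_value(l_s2)[1], ad_value(l_tr)[1],
                         ad_value(adv$l_d)[1], ad_value(adv_g$l_g)[1],
                         ad_value(l_aux)[1])
      }
      logs[[epoch]] <- tibble::tibble(
        phase = "joint", epoch = epoch, l_r = ep["l_r"], l_s = ep["l_s"],
        l_tr = ep["l_tr"], l_d = ep["l_d"], l_g = ep["l_g"], l_auxc = ep["l_auxc"],
        seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
      )
    }
  })
  model$params <- params
  model$phase <- "trained"
  keep <- seq(1, cf$joint_epochs, by = cf$log_every)
  list(model = model, log = new_train_log(dplyr::bind_rows(logs[keep]), cf),
       weights = c(cal, list(w_pos = w_pos)))
}

new_train_log <- function(df, config) {
  structure(df, class = c("train_log", class(df)),
            config_hash = rlang::hash(config), seed = config$seed)
}

#' Fit the full journey model on a cohort
#'
#' Convenience wrapper: fits the scaling transform, encodes the cohort,
#' initialises the networks, pre-trains and jointly trains them.
#'
#' @param cohort_train Training `cohort`.
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param t_max Pad length; defaults to the longest training journey.
#' @param transform Optionally a pre-fitted transform.
#' @return A `cohort_gan` fit: list with `model`, `transform`, `schema`,
#'   `log` (both phases), `weights`, `config`.
#' @export
train_cohort_gan <- function(cohort_train, net = net_config(), train = train_config(),
                             t_max = NULL, transform = NULL) {
  transform <- transform %||% fit_transform(cohort_train)
  batch <- encode_batch(cohort_train, transform, t_max)
  model <- init_model(transform, net)
  pre <- pretrain(model, batch, train)
  joint <- joint_train(pre$model, batch, train)
  structure(
    list(model = joint$model, transform = transform, schema = cohort_train$schema,
         log = dplyr::bind_rows(pre$log, joint$log), weights = joint$weights,
         net_config = net, train_config = train,
         t_max = ncol(batch$mask)),
    class = "cohort_gan"
  )
}

#' @export
print.cohort_gan <- function(x, ...) {
  last <- dplyr::slice_tail(dplyr::filter(x$log, .data$phase == "joint"), n = 1)
  cat(sprintf(
    "<cohort_gan: d_ht=%d, %d+%d epochs, final L_R=%.4f L_D=%.4f L_G=%.4f>\n",
    x$model$config$d_ht, x$train_config$pretrain_epochs, x$train_config$joint_epochs,
    last$l_r, last$l_d, last$l_g
  ))
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint bundles parameters, configurations, the fitted transform
#' and a package version tag in one file.
#'
#' @param fit A `cohort_gan`.
#' @param path Checkpoint file path.
#' @return [load_cohort_gan()] returns the `cohort_gan`.
#' @export
save_cohort_gan <- function(fit, path) {
  fit$version <- as.character(utils::packageVersion("cohortwin"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_cohort_gan
#' @export
load_cohort_gan <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "cohort_gan")) rlang::abort("not a cohort_gan checkpoint")
  fit
}
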