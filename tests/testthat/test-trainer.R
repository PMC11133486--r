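trainer_fixture <- function(n = 30, seed = 13) {
  gen <- small_synth(n, seed = seed)
  tr <- fit_transform(gen$cohort)
  list(
    batch = encode_batch(gen$cohort, tr),
    model = init_model(tr, net_config(d_hs = 4, d_ht = 8, hidden_mlp = 12,
                                      d_disc = 6, d_term = 4, seed = 2)),
    tr = tr
  )
}

test_that("pre-training reduces its objectives and leaves adversarial parts alone", {
  fx <- trainer_fixture()
  res <- pretrain(fx$model, fx$batch, train_config(pretrain_epochs = 25, seed = 1))
  log <- res$log
  expect_gt(log$l_r[1], 0)
  expect_lt(dplyr::last(log$l_r), log$l_r[1])
  expect_lt(dplyr::last(log$l_tr), log$l_tr[1])
  # phase separation: generator, discriminator, auxiliary classifier untouched
  expect_identical(res$model$params$gen, fx$model$params$gen)
  expect_identical(res$model$params$disc, fx$model$params$disc)
  expect_identical(res$model$params$auxc, fx$model$params$auxc)
  expect_false(identical(res$model$params$enc_t, fx$model$params$enc_t))
})

test_that("training is deterministic given seed and config", {
  fx <- trainer_fixture()
  cfg <- train_config(pretrain_epochs = 4, joint_epochs = 4, batch_size = 16, seed = 11)
  r1 <- pretrain(fx$model, fx$batch, cfg)
  r2 <- pretrain(fx$model, fx$batch, cfg)
  expect_equal(tibble::as_tibble(r1$log)[, c("l_r", "l_s", "l_tr")],
               tibble::as_tibble(r2$log)[, c("l_r", "l_s", "l_tr")],
               tolerance = 1e-6)
  j1 <- joint_train(r1$model, fx$batch, cfg)
  j2 <- joint_train(r2$model, fx$batch, cfg)
  expect_equal(tibble::as_tibble(j1$log)[, c("l_r", "l_d", "l_g", "l_auxc")],
               tibble::as_tibble(j2$log)[, c("l_r", "l_d", "l_g", "l_auxc")],
               tolerance = 1e-6)
  r3 <- pretrain(fx$model, fx$batch,
                 train_config(pretrain_epochs = 4, joint_epochs = 4,
                              batch_size = 16, seed = 12))
  expect_false(isTRUE(all.equal(r1$log$l_r, r3$log$l_r)))
})

test_that("a zero supervised weight makes the autoencoder update purely reconstructive", {
  fx <- trainer_fixture(n = 12)
  mb <- fx$batch
  d_ht <- 8
  grads_for <- function(include_sup) {
    tp <- cohortwin:::ad_tape()
    pe <- list(enc_s = cohortwin:::wrap_params(tp, fx$model$params$enc_s),
               enc_t = cohortwin:::wrap_params(tp, fx$model$params$enc_t),
               dec_s = cohortwin:::wrap_params(tp, fx$model$params$dec_s),
               dec_t = cohortwin:::wrap_params(tp, fx$model$params$dec_t))
    lat <- cohortwin:::fwd_latents(pe$enc_s, pe$enc_t, mb)
    s_hat <- cohortwin:::f_mixed_head(cohortwin:::f_mlp(pe$dec_s, lat$h_s),
                                      fx$model$layout_s)
    x_hat <- purrr::map(lat$h_list, ~ cohortwin:::f_mixed_head(
      cohortwin:::f_mlp(pe$dec_t, .x), fx$model$layout_t))
    l_r <- loss_reconstruction(mb$s, s_hat, cohortwin:::array_to_list(mb$x),
                               x_hat, mb$mask)
    total <- if (include_sup) {
      preds <- cohortwin:::sup_predictions(fx$model$params$sup, lat$h_s,
                                           lat$h_list, nrow(mb$s), d_ht)
      l_s <- loss_supervised(lat$h_list, preds, mb$mask)
      cohortwin:::op_add(l_r, cohortwin:::op_scale(l_s, 0))
    } else l_r
    cohortwin:::ad_backward(total)
    cohortwin:::unwrap_grads(pe)
  }
  expect_equal(grads_for(TRUE), grads_for(FALSE), tolerance = 1e-12)
})

test_that("each component moves only under its own optimizer", {
  fx <- trainer_fixture(n = 16)
  pre <- pretrain(fx$model, fx$batch, train_config(pretrain_epochs = 3, seed = 4))
  # freeze adversarial updates: supervised parts still move, G/D/AuxC do not
  j0 <- joint_train(pre$model, fx$batch,
                    train_config(joint_epochs = 2, seed = 4, lr_adversarial = 0))
  expect_identical(j0$model$params$gen, pre$model$params$gen)
  expect_identical(j0$model$params$disc, pre$model$params$disc)
  expect_identical(j0$model$params$auxc, pre$model$params$auxc)
  expect_false(identical(j0$model$params$enc_t, pre$model$params$enc_t))
  # freeze supervised updates: the reverse
  j1 <- joint_train(pre$model, fx$batch,
                    train_config(joint_epochs = 2, seed = 4, lr_supervised = 0))
  expect_identical(j1$model$params$enc_t, pre$model$params$enc_t)
  expect_identical(j1$model$params$dec_t, pre$model$params$dec_t)
  expect_identical(j1$model$params$sup, pre$model$params$sup)
  expect_identical(j1$model$params$term, pre$model$params$term)
  expect_false(identical(j1$model$params$gen, pre$model$params$gen))
  expect_false(identical(j1$model$params$disc, pre$model$params$disc))
})

test_that("a non-finite loss aborts with a diagnostic naming the component", {
  fx <- trainer_fixture(n = 12)
  fx$model$params$enc_s$W1[1, 1] <- NaN
  expect_error(
    pretrain(fx$model, fx$batch, train_config(pretrain_epochs = 2, seed = 1)),
    "non-finite loss.*autoencoder.*epoch 1"
  )
})

test_that("the full wrapper trains, logs both phases and calibrates weights", {
  gen <- small_synth(24, seed = 30)
  fit <- train_cohort_gan(
    gen$cohort, net_config(d_hs = 3, d_ht = 6, hidden_mlp = 8, d_disc = 4,
                           d_term = 3, seed = 1),
    train_config(pretrain_epochs = 3, joint_epochs = 3, batch_size = 16, seed = 1)
  )
  expect_s3_class(fit, "cohort_gan")
  expect_setequal(unique(fit$log$phase), c("pretrain", "joint"))
  expect_true(all(c("lambda", "eta", "delta", "w_pos") %in% names(fit$weights)))
  expect_gt(fit$weights$w_pos, 0)
  g <- glance(fit)
  expect_equal(g$joint_epochs, 3)
  td <- tidy(fit)
  expect_setequal(td$component, c("enc_s", "enc_t", "dec_s", "dec_t", "gen",
                                  "sup", "term", "disc", "auxc"))
  lt <- tidy(fit$log)
  expect_true(all(c("phase", "epoch", "loss", "value") %in% names(lt)))

  path <- withr::local_tempfile(fileext = ".ckpt")
  save_cohort_gan(fit, path)
  back <- load_cohort_gan(path)
  expect_identical(back$model$params, fit$model$params)
})
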