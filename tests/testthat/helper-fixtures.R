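# Shared fixtures, all built in code.

tiny_schema <- function() {
  cohort_schema(dplyr::bind_rows(
    feature_spec("age", "static", "continuous", units = "years"),
    feature_spec("group", "static", "categorical", c("g0", "g1")),
    feature_spec("score", "temporal", "continuous"),
    feature_spec("flag", "temporal", "categorical", c("no", "yes")),
    feature_spec("grade", "temporal", "ordinal", c("lo", "mid", "hi"))
  ))
}

# three patients with journey lengths 2, 1, 3; patient B dropped at visit 1
tiny_cohort <- function() {
  as_cohort(
    tiny_schema(),
    static = tibble::tibble(
      patient_id = c("A", "B", "C"),
      age = c(60, 70, 80), group = c("g0", "g1", "g0")
    ),
    temporal = tibble::tibble(
      patient_id = c("A", "A", "B", "C", "C", "C"),
      visit = c(1, 2, 1, 1, 2, 3),
      dropped_at_visit = c(0, 0, 1, 0, 0, 0),
      score = c(0.1, 0.4, 0.9, 0.2, 0.3, 0.5),
      flag = c("no", "yes", "yes", "no", "no", "yes"),
      grade = c("lo", "mid", "hi", "lo", "lo", "mid")
    )
  )
}

small_synth <- function(n = 40, seed = 7, ...) {
  generate_cohort(synth_config(n_patients = n, seed = seed, ...))
}

# a tiny untrained-but-structured fit for simulator stubs: real init, weights
# marker set so no recalibration is applied
stub_fit <- function(cohort = small_synth(20, seed = 9)$cohort,
                     net = net_config(d_hs = 4, d_ht = 6, hidden_mlp = 8,
                                      d_term = 4, d_disc = 6, seed = 2)) {
  transform <- fit_transform(cohort)
  model <- init_model(transform, net)
  structure(
    list(model = model, transform = transform, schema = cohort$schema,
         weights = list(w_pos = 1), t_max = max(cohort_lengths(cohort)$length),
         net_config = net, train_config = NULL, log = NULL),
    class = "cohort_gan"
  )
}

stub_static_rows <- function(n = 3) {
  tibble::tibble(
    patient_id = sprintf("S%02d", seq_len(n)),
    age = seq(60, 80, length.out = n),
    group = rep(c("g0", "g1"), length.out = n),
    site = rep(c("site_A", "site_B", "site_C"), length.out = n),
    severity = rep(c("mild", "moderate", "severe"), length.out = n)
  )
}

# force the termination head to emit a constant probability p
with_constant_hazard <- function(fit, p) {
  fit$model$params$term$Wo[] <- 0
  fit$model$params$term$bo <- qlogis(p)
  fit
}

# cache one short-trained model across a test file
.trained_env <- new.env(parent = emptyenv())
short_trained_fit <- function() {
  if (is.null(.trained_env$fit)) {
    gen <- small_synth(60, seed = 21)
    .trained_env$cohort <- gen$cohort
    .trained_env$fit <- train_cohort_gan(
      gen$cohort, net_config(d_hs = 4, d_ht = 8, hidden_mlp = 16, seed = 3),
      train_config(pretrain_epochs = 8, joint_epochs = 8, seed = 3)
    )
  }
  list(fit = .trained_env$fit, cohort = .trained_env$cohort)
}
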