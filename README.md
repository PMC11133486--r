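# cohortwin

Termination-aware conditional generative modelling of clinical-trial patient
journeys — *patient digital twins* — in R.

Clinical-trial panel data pair one static record per patient (demographics,
history) with a variable-length sequence of visit records that ends either
administratively or by early drop-off. `cohortwin` learns the joint law of
`(x_s, x_{1:T})` with a conditional sequence GAN and uses it to simulate
patient journeys: given a patient's static covariates (Type A), or their
covariates plus the visits observed so far (Type B), it samples plausible
continuations together with a per-visit drop-off probability. The intended
users are biostatisticians and trial-monitoring teams who need stochastic,
personalised journey forecasts rather than single point predictions.

## The model

All learning happens in a latent space. A shared autoencoder maps the static
vector to `h_s = Enc_s(s)` and the visit sequence to causal latents
`h_t = Enc_t(h_s, h_{t-1}, x_t)` (GRU). On top of it:

* a GRU generator `hhat_t = G(h_s, hhat_{t-1}, z_t)` with Wiener-path noise,
* a bi-directional GRU discriminator scoring per-step and static-level
  realism, trained with the relativistic objective
  `L_D = -E[sum_t log sigma(y_t - yhat_t)]`,
  `L_G = -E[sum_t log sigma(yhat_t - y_t)]`,
* an auxiliary classifier predicting `h_s` back from the final sequence
  latent (against conditional mode collapse),
* a supervisor providing the next-latent supervised loss
  `L_S = E[sum_t ||h_t - G(h_s, h_{t-1}, z_t)||]`,
* a termination GRU emitting the per-visit drop-off probability
  `p_t = T_r(h_s, h_{t-1})`, trained with positive-class-weighted
  cross-entropy.

Training is two-phase: supervised pre-training of autoencoder, supervisor and
termination network (`min (lambda L_S + L_R)`; `min L_Tr`), then joint
adversarial training
(`min_G (eta L_S + delta L_AuxC + L_G)` against `min_{D} L_D`), with
open-loop (own previous generation) and closed-loop (teacher-forced)
generator passes alternating per epoch. The networks and their gradients are
implemented in-package on a small reverse-mode autodiff tape — there is no
deep-learning framework dependency — and all analytic gradients are verified
against finite differences in the test suite.

Because the trial datasets this family of models is usually fitted to are
access-restricted, the package ships a seeded synthetic-cohort generator
with known ground truth (latent disease state with a group-dependent drift,
mixed-type visit features, state-dependent drop-off hazard) so the whole
pipeline is testable end to end; see the methods vignette
(`vignettes/journey-gan-methods.Rmd`).

## Worked example

```r
library(cohortwin)

# a 200-patient synthetic trial cohort with known ground truth
gen <- generate_cohort(synth_config(n_patients = 200, seed = 1))
gen$cohort
#> <cohort: 200 patients, 1059 visits, lengths 2-12 (mean 5.29), 48.0% dropped>

sp  <- split_cohort(gen$cohort, train_frac = 0.8, seed = 1)
fit <- train_cohort_gan(
  sp$train,
  net   = net_config(d_ht = 16, seed = 1),
  train = train_config(pretrain_epochs = 200, joint_epochs = 500, seed = 1)
)
glance(fit)[, c("lambda", "eta", "delta", "w_pos", "l_r")]
#> # A tibble: 1 × 5
#>   lambda   eta delta w_pos   l_r
#>    <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   1.84  26.4  2.04  9.85 0.736
```

The weights are calibrated at the start of the joint phase against the
adversarial loss magnitude (the supervised generator term deliberately
dominates it, `sup_emphasis = 5`, to anchor free-running generation);
`w_pos` is the non-terminal/terminal step ratio of the training split, and
`l_r` is the final masked reconstruction loss.

```r
# Type A: simulate whole journeys for held-out patients
sims <- simulate_type_a(fit, sp$test$static,
                        sim_config(n_sims = 1000, max_len = 12, seed = 2))
predict_dropoff_visit(sims)
#> # A tibble: 40 x 2
#>    patient_id predicted_visit
#>    <chr>                <dbl>
#>  1 P0003                 5.41
#>  2 P0004                 6.30
#> # ...

# generation quality against held-out real data
gen_cohort <- simulation_cohort(sims, sp$test$static, fit$schema, max_sims = 10)
avg_corr_diff(sp$test, gen_cohort)
#> [1] 0.167
```

The average correlation difference of 0.167 beats both reference baselines
(feature-shuffled real data: 0.223; Gaussian noise: 0.231), i.e. the fitted
model reproduces the pooled mixed-type correlation structure better than
marginal-preserving noise does. `evaluate_generation()` assembles the full
fidelity/diversity/utility report, `lookahead_jsd()` the per-horizon
Jensen-Shannon distances, and `autoplot()` methods cover training logs and
simulation fans.

A command-line interface wrapping the same functions is installed at
`inst/scripts/cohortwin` (subcommands `synth`, `train`, `simulate`,
`evaluate`, `e2e`).

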