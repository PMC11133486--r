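test_that("mixed-type associations hit their definitional extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(mixed_correlation(x, 2 * x + 1, "continuous", "continuous"), 1)
  expect_equal(mixed_correlation(x, -x, "continuous", "continuous"), -1)
  expect_warning(
    z <- mixed_correlation(rep(1, 5), x, "continuous", "continuous"),
    "zero-variance"
  )
  expect_equal(z, 0)

  # correlation ratio: identical category means -> 0; pure separation -> 1
  expect_equal(correlation_ratio(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  expect_equal(correlation_ratio(c(1, 1, 5, 5), c("a", "a", "b", "b")), 1)

  # Theil's U: y determines x -> 1; independence -> 0
  expect_equal(theils_u(c("a", "a", "b", "b"), c(0, 0, 1, 1)), 1)
  expect_equal(theils_u(c("a", "b", "a", "b"), c(0, 0, 1, 1)), 0)
})

test_that("average correlation difference matches a hand-computed oracle", {
  ch <- tiny_cohort()
  expect_equal(avg_corr_diff(ch, ch), 0)

  # independent oracle over the pooled 6-visit table: direct formulas per pair
  ch2 <- tiny_cohort()
  ch2$temporal$score <- rev(ch2$temporal$score)
  ch2$temporal$flag <- c("yes", "no", "no", "yes", "yes", "no")
  ch2$temporal$grade <- c("hi", "lo", "mid", "mid", "lo", "hi")

  pool <- function(ch) {
    j <- dplyr::left_join(ch$temporal, ch$static, by = "patient_id")
    j$grade_num <- match(j$grade, c("lo", "mid", "hi"))
    j
  }
  eta <- function(x, g) {
    sqrt(sum(tapply(x, g, length) * (tapply(x, g, mean) - mean(x))^2) /
           sum((x - mean(x))^2))
  }
  u <- function(x, y) {
    hx <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    H <- hx(prop.table(table(x)))
    if (H == 0) return(1)
    tab <- prop.table(table(y, x))
    py <- rowSums(tab)
    Hc <- sum(sapply(seq_along(py), function(i) if (py[i] == 0) 0 else
      py[i] * hx(tab[i, ] / py[i])))
    (H - Hc) / H
  }
  pair_val <- function(j, a, b, ka, kb) {
    num <- function(k) k != "categorical"
    if (num(ka) && num(kb)) cor(j[[a]], j[[b]])
    else if (num(ka)) eta(j[[a]], j[[b]])
    else if (num(kb)) eta(j[[b]], j[[a]])
    else u(j[[a]], j[[b]])
  }
  feats <- c(age = "continuous", group = "categorical", score = "continuous",
             flag = "categorical", grade_num = "ordinal")
  oracle <- function(j1, j2) {
    nm <- names(feats)
    acc <- 0; p <- 0
    for (i in seq_along(nm)) for (k in seq_along(nm)) {
      if (i >= k) next
      acc <- acc + abs(pair_val(j1, nm[i], nm[k], feats[i], feats[k]) -
                       pair_val(j2, nm[i], nm[k], feats[i], feats[k]))
      p <- p + 1
    }
    acc / p
  }
  expect_equal(avg_corr_diff(ch, ch2), oracle(pool(ch), pool(ch2)), tolerance = 1e-10)

  # invariant under feature reordering of the schema
  perm <- ch$schema[c(3, 1, 5, 2, 4), ]
  ch_perm <- ch; ch_perm$schema <- cohort_schema(perm)
  ch2_perm <- ch2; ch2_perm$schema <- cohort_schema(perm)
  expect_equal(avg_corr_diff(ch_perm, ch2_perm), avg_corr_diff(ch, ch2))
})

test_that("Frechet distance matches its closed form and an eigenvalue oracle", {
  withr::with_seed(42, {
    e <- matrix(rnorm(400), 100, 4)
    expect_lt(fid_score(e, e), 1e-6)

    # 1-D gaussians: (mu1 - mu2)^2 + (sd1 - sd2)^2 = 1 for N(0,1) vs N(1,1)
    a <- matrix(rnorm(40000, 0, 1), ncol = 1)
    b <- matrix(rnorm(40000, 1, 1), ncol = 1)
    expect_equal(fid_score(a, b), 1, tolerance = 0.05)

    # 5-D case against an independent non-symmetric eigenvalue route:
    # Tr((S_r S_g)^(1/2)) = sum of sqrt eigenvalues of S_r S_g
    x <- matrix(rnorm(1500), 300, 5) %*% matrix(rnorm(25), 5)
    y <- matrix(rnorm(1500, 0.3), 300, 5)
    s_r <- cov(x) + diag(1e-6, 5); s_g <- cov(y) + diag(1e-6, 5)
    oracle <- sum((colMeans(x) - colMeans(y))^2) + sum(diag(s_r)) + sum(diag(s_g)) -
      2 * sum(sqrt(pmax(Re(eigen(s_r %*% s_g)$values), 0)))
    expect_equal(fid_score(x, y), oracle, tolerance = 1e-8)
    expect_equal(fid_score(x, y), fid_score(y, x), tolerance = 1e-8)
  })
})

test_that("alpha-precision measures support overlap", {
  withr::with_seed(7, {
    real <- matrix(rnorm(4000), 2000, 2)
    half <- real[1:1000, ]
    other <- matrix(rnorm(4000), 2000, 2)
    # an independent draw from the same distribution lands in the 0.95-support
    # about 95% of the time
    ap <- alpha_precision(half, other, alpha = 0.95)
    se <- sqrt(0.95 * 0.05 / 2000)
    expect_lt(abs(ap - 0.95), 3 * se + 0.01)
    # far-shifted generations never land in the support
    expect_equal(alpha_precision(real, other + 100, alpha = 0.95), 0)
    # the full support contains near-center points
    expect_equal(alpha_precision(real, real[abs(real[, 1]) < 0.1 &
                                            abs(real[, 2]) < 0.1, , drop = FALSE],
                                 alpha = 1), 1)
  })
})

test_that("JS distance is bounded, symmetric and zero on self", {
  withr::with_seed(8, {
    a <- rnorm(3000)
    b <- rnorm(3000)
    expect_lt(js_distance(a, b), 0.08)
    expect_equal(js_distance(a, a), 0, tolerance = 1e-6)
    disjoint <- js_distance(runif(500, 0, 1), runif(500, 100, 101))
    expect_equal(disjoint, 1, tolerance = 1e-3)
    expect_equal(js_distance(a, b), js_distance(b, a), tolerance = 1e-12)
    cat_d <- js_distance(c("a", "a", "b"), c("a", "a", "b"), kind = "categorical")
    expect_equal(cat_d, 0, tolerance = 1e-6)
  })
})

test_that("drop-off MAPE follows its hand values", {
  expect_equal(dropoff_mape(4, 4, 1)$mape, c(0, 0))
  expect_equal(dropoff_mape(5, 4, 1)$mape[1], 0.25)
  tab <- dropoff_mape(c(5, 8), c(4, 10), c(1, 1))
  expect_equal(tab$mape[tab$known_visits == "all"], mean(c(0.25, 0.2)))
  expect_error(dropoff_mape(1, 0, 1), ">= 1")
})

test_that("AUROC helper is exact and agrees with an independent implementation", {
  s <- c(0.9, 0.8, 0.3, 0.2)
  y <- c(1, 0, 1, 0)
  expect_equal(binary_auroc(s, y), 0.75)
  expect_equal(binary_auroc(s, 1 - y), 0.25)  # label inversion symmetry
  skip_if_not_installed("pROC")
  withr::with_seed(10, {
    sc <- runif(200)
    yy <- rbinom(200, 1, plogis(3 * sc - 1.5))
    want <- as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE)))
    expect_equal(binary_auroc(sc, yy), want, tolerance = 1e-10)
  })
})

test_that("post-hoc discriminator behaves at the null and at separation", {
  gen <- small_synth(120, seed = 14)
  halves <- split_cohort(gen$cohort, 0.5, seed = 1)
  null_score <- discriminator_score(halves$train, halves$test, seed = 2)
  expect_lt(abs(null_score$auroc - 0.5), 0.1)

  # constant sequences against varied real ones are trivially separable
  flat <- halves$test
  flat$temporal <- flat$temporal |>
    dplyr::mutate(marker_1 = 0, marker_2 = 0, marker_3 = 0,
                  adverse_event = "ae_no", impairment = "low")
  sep_score <- discriminator_score(halves$train, flat, seed = 2)
  expect_gt(sep_score$auroc, 0.95)
})

test_that("next-step utility separates equivalent data from noise", {
  gen <- small_synth(90, seed = 15)
  sp <- split_cohort(gen$cohort, 0.67, seed = 2)
  selfsub <- next_step_utility(sp$train, sp$train, sp$test, seed = 3)
  expect_lt(abs(selfsub$gen_mse - selfsub$real_mse) / selfsub$real_mse, 0.10)

  noise <- baseline_noise(sp$train, seed = 4)
  degraded <- next_step_utility(sp$train, noise, sp$test, seed = 3)
  expect_gt(degraded$gen_mse, degraded$real_mse)
})

test_that("a mean-predicting stub recovers the pooled variance identity", {
  gen <- small_synth(25, seed = 16)
  tr <- fit_transform(gen$cohort)
  b <- encode_batch(gen$cohort, tr)
  d <- dim(b$x)[3]
  # stub with zero recurrent weights and bias = pooled target mean
  params <- cohortwin:::posthoc_init(d, 4, d, seed = 1)
  for (nm in names(params$gru)) params$gru[[nm]][] <- 0
  params$Wo[] <- 0
  tgt <- NULL
  for (t in 2:dim(b$x)[2]) {
    rows <- which(b$mask[, t] == 1)
    if (length(rows)) tgt <- rbind(tgt, matrix(b$x[rows, t, ], ncol = d))
  }
  params$bo <- colMeans(tgt)
  # loop-computed pooled variance of the targets around their mean
  want <- mean(sweep(tgt, 2, colMeans(tgt))^2)
  xl <- cohortwin:::array_to_list(b$x)
  h <- matrix(0, nrow(b$s), 4)
  tot <- 0; cnt <- 0
  for (t in seq_len(dim(b$x)[2] - 1)) {
    h <- cohortwin:::f_gru_step(params$gru, xl[[t]], h)
    pred <- cohortwin:::op_addb(cohortwin:::op_mm(h, params$Wo), params$bo)
    m <- b$mask[, t + 1]
    tot <- tot + sum(((pred - xl[[t + 1]])^2) * m)
    cnt <- cnt + sum(m) * d
  }
  expect_equal(tot / cnt, want, tolerance = 1e-10)
})
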