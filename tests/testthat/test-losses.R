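# Brute-force loop oracles, independent of the vectorised implementations.

oracle_recon <- function(s, s_hat, x, x_hat, mask) {
  n <- nrow(s)
  tot <- 0
  for (i in seq_len(n)) {
    tot <- tot + sqrt(sum((s[i, ] - s_hat[i, ])^2))
    for (t in seq_len(ncol(mask))) {
      if (mask[i, t] == 1) tot <- tot + sqrt(sum((x[i, t, ] - x_hat[i, t, ])^2))
    }
  }
  tot / n
}

oracle_bce <- function(p, y, mask, w_pos) {
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(p))) for (t in seq_len(ncol(p))) {
    if (mask[i, t] == 1) {
      pc <- min(max(p[i, t], 1e-7), 1 - 1e-7)
      tot <- tot + if (y[i, t] == 1) -w_pos * log(pc) else -log(1 - pc)
      cnt <- cnt + 1
    }
  }
  tot / cnt
}

oracle_rsgan <- function(yr, yf, mask) {
  n <- nrow(yr); ld <- 0; lg <- 0
  for (i in seq_len(n)) for (t in seq_len(ncol(yr))) {
    if (mask[i, t] == 1) {
      ld <- ld - log(plogis(yr[i, t] - yf[i, t]))
      lg <- lg - log(plogis(yf[i, t] - yr[i, t]))
    }
  }
  list(l_d = ld / n, l_g = lg / n)
}

rand_case <- function(seed, n = 3, t_max = 4, d = 2) {
  withr::with_seed(seed, {
    lengths <- sample(seq_len(t_max), n, replace = TRUE)
    mask <- outer(lengths, seq_len(t_max), `>=`) * 1
    list(
      s = matrix(runif(n * d), n), s_hat = matrix(runif(n * d), n),
      x = array(runif(n * t_max * d), dim = c(n, t_max, d)),
      x_hat = array(runif(n * t_max * d), dim = c(n, t_max, d)),
      mask = mask, lengths = lengths
    )
  })
}

test_that("reconstruction loss matches hand values and the loop oracle", {
  c1 <- rand_case(1)
  expect_equal(loss_reconstruction(c1$s, c1$s, c1$x, c1$x, c1$mask), 0)

  # static-only hand value: ||(1,0) - (0,0)|| = 1
  s <- matrix(c(1, 0), 1); sh <- matrix(0, 1, 2)
  x0 <- array(0, dim = c(1, 1, 2))
  expect_equal(loss_reconstruction(s, sh, x0, x0, matrix(0, 1, 1)), 1)

  for (seed in 1:5) {
    cc <- rand_case(seed)
    expect_equal(
      loss_reconstruction(cc$s, cc$s_hat, cc$x, cc$x_hat, cc$mask),
      oracle_recon(cc$s, cc$s_hat, cc$x, cc$x_hat, cc$mask),
      tolerance = 1e-10
    )
  }
})

test_that("termination BCE reproduces closed forms and weighting", {
  m1 <- matrix(1, 1, 1)
  expect_equal(loss_termination_bce(matrix(0.5), matrix(0), m1, 1), log(2))
  expect_equal(loss_termination_bce(matrix(0.5), matrix(1), m1, 3), 3 * log(2))
  expect_error(loss_termination_bce(matrix(0.5), matrix(2), m1), "0/1")

  for (seed in 1:5) {
    cc <- rand_case(seed)
    p <- matrix(runif(12), 3)
    y <- (matrix(runif(12), 3) > 0.8) * cc$mask
    expect_equal(loss_termination_bce(p, y, cc$mask, 2.5),
                 oracle_bce(p, y, cc$mask, 2.5), tolerance = 1e-10)
  }
})

test_that("termination CE hits uniform/one-hot limits and reduces to BCE at C = 2", {
  m1 <- matrix(1, 1, 1)
  expect_equal(
    loss_termination_ce(array(0, dim = c(1, 1, 4)), matrix(1), m1),
    log(4)
  )
  big <- array(c(50, 0, 0, 0), dim = c(1, 1, 4))
  expect_lt(loss_termination_ce(big, matrix(1), m1), 1e-8)
  expect_error(loss_termination_ce(array(0, dim = c(1, 1, 2)), matrix(3), m1), "1..2")

  withr::with_seed(9, {
    p <- matrix(runif(12, 0.05, 0.95), 3)
    y <- (matrix(runif(12), 3) > 0.7) * 1
    mask <- rand_case(2)$mask
    logits <- array(0, dim = c(3, 4, 2))
    logits[, , 2] <- qlogis(p)  # class 2 = drop, logit difference = log-odds
    expect_equal(
      loss_termination_ce(logits, y + 1, mask, w_c = c(1, 3)),
      loss_termination_bce(p, y, mask, w_pos = 3),
      tolerance = 1e-8
    )
  })
})

test_that("relativistic losses are symmetric with the stated closed forms", {
  t_len <- 5
  y <- matrix(rnorm(t_len), 1)
  m <- matrix(1, 1, t_len)
  eq <- loss_rsgan(y, y, m)
  expect_equal(eq$l_d, t_len * log(2))
  expect_equal(eq$l_g, t_len * log(2))

  far <- loss_rsgan(y + 60, y, m)
  expect_lt(far$l_d, 1e-8)
  expect_gt(far$l_g, 10)

  withr::with_seed(3, {
    yr <- matrix(rnorm(12), 3); yf <- matrix(rnorm(12), 3)
    mask <- rand_case(4)$mask
    got <- loss_rsgan(yr, yf, mask)
    want <- oracle_rsgan(yr, yf, mask)
    expect_equal(got$l_d, want$l_d, tolerance = 1e-10)
    expect_equal(got$l_g, want$l_g, tolerance = 1e-10)
    swapped <- loss_rsgan(yf, yr, mask)
    expect_equal(swapped$l_d, got$l_g)
    expect_equal(swapped$l_g, got$l_d)
  })
})

test_that("auxiliary loss averages real- and fake-derived prediction norms", {
  h <- matrix(c(1, 0), 1)
  expect_equal(loss_auxc(h, h, h), 0)
  expect_equal(loss_auxc(h, matrix(0, 1, 2), h), 0.5)  # mean(1, 0)
  withr::with_seed(5, {
    h <- matrix(rnorm(8), 4); pr <- matrix(rnorm(8), 4); pf <- matrix(rnorm(8), 4)
    want <- mean((sqrt(rowSums((h - pr)^2)) + sqrt(rowSums((h - pf)^2))) / 2)
    expect_equal(loss_auxc(h, pr, pf), want, tolerance = 1e-10)
  })
})

test_that("supervised loss matches the 3-4-5 hand case and a loop oracle", {
  h <- array(c(3, 4), dim = c(1, 1, 2))
  pred <- array(0, dim = c(1, 1, 2))
  expect_equal(loss_supervised(h, pred, matrix(1, 1, 1)), 5)
  expect_equal(loss_supervised(h, h, matrix(1, 1, 1)), 0)

  cc <- rand_case(6)
  want <- 0
  for (i in 1:3) for (t in 1:4) {
    if (cc$mask[i, t] == 1) want <- want + sqrt(sum((cc$x[i, t, ] - cc$x_hat[i, t, ])^2))
  }
  expect_equal(loss_supervised(cc$x, cc$x_hat, cc$mask), want / 3, tolerance = 1e-10)
})

test_that("losses ignore padded positions entirely", {
  cc <- rand_case(7)
  perturb <- function(arr) {
    out <- arr
    for (i in 1:3) {
      pad <- which(cc$mask[i, ] == 0)
      if (length(pad)) out[i, pad, ] <- out[i, pad, ] + 100
    }
    out
  }
  expect_equal(
    loss_reconstruction(cc$s, cc$s_hat, cc$x, cc$x_hat, cc$mask),
    loss_reconstruction(cc$s, cc$s_hat, perturb(cc$x), perturb(cc$x_hat), cc$mask)
  )
  p <- matrix(runif(12, 0.1, 0.9), 3)
  y <- cc$mask * 0
  pp <- p; pp[cc$mask == 0] <- 0.99
  expect_equal(loss_termination_bce(p, y, cc$mask, 2),
               loss_termination_bce(pp, y, cc$mask, 2))
  yr <- matrix(rnorm(12), 3); yf <- matrix(rnorm(12), 3)
  yr2 <- yr; yr2[cc$mask == 0] <- 50
  expect_equal(loss_rsgan(yr, yf, cc$mask)$l_d, loss_rsgan(yr2, yf, cc$mask)$l_d)
  expect_equal(loss_supervised(cc$x, cc$x_hat, cc$mask),
               loss_supervised(perturb(cc$x), perturb(cc$x_hat), cc$mask))
})

test_that("each loss has a nonzero gradient in its predicted argument", {
  cc <- rand_case(8)
  grad_of <- function(build) {
    tp <- cohortwin:::ad_tape()
    arg <- cohortwin:::ad_param(tp, matrix(runif(6, 0.2, 0.8), 3))
    out <- build(arg)
    cohortwin:::ad_backward(out)
    arg$grad
  }
  m <- cc$mask[, 1, drop = FALSE]
  g1 <- grad_of(function(a) loss_reconstruction(cc$s, a, list(), list(),
                                                matrix(0, 3, 0)))
  expect_gt(max(abs(g1)), 0)
  g2 <- grad_of(function(a) loss_termination_bce(
    list(cohortwin:::op_cols(a, 1)), cc$mask[, 1, drop = FALSE] * 0, m, 2))
  expect_gt(max(abs(g2)), 0)
  g3 <- grad_of(function(a) loss_rsgan(cc$s, cohortwin:::op_cols(a, 1:2),
                                       matrix(1, 3, 2))$l_g)
  expect_gt(max(abs(g3)), 0)
  g4 <- grad_of(function(a) loss_auxc(cc$s, a))
  expect_gt(max(abs(g4)), 0)
  g5 <- grad_of(function(a) loss_supervised(list(cc$s), list(a),
                                            matrix(1, 3, 1)))
  expect_gt(max(abs(g5)), 0)
})
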