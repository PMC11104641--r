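test_that("llo_transform reproduces the worked values and fixed points", {
  p <- llo_params(0.88, 0.76)
  expect_equal(llo_transform(0.879, p), 0.868, tolerance = 0.001)
  expect_equal(llo_transform(0.534, p), 0.564, tolerance = 0.001)
  expect_equal(llo_transform(0.76, p), 0.76, tolerance = 1e-12)
  # identity at gamma = 1, any crossover
  expect_equal(llo_transform(0.3, llo_params(1, 0.6)), 0.3, tolerance = 1e-12)
  expect_error(llo_transform(0, p), "strictly")
  expect_error(llo_transform(1, p), "strictly")
  expect_error(llo_params(-0.5, 0.5), "gamma")
  expect_error(llo_params(0.9, 1), "p0")
})

test_that("llo_transform is monotone; gamma < 1 over/under-estimates around p0", {
  grid <- seq(0.001, 0.999, length.out = 400)
  set.seed(11)
  for (k in 1:10) {
    prm <- llo_params(runif(1, 0.2, 2.5), runif(1, 0.05, 0.95))
    v <- llo_transform(grid, prm)
    expect_true(all(diff(v) > 0))
  }
  prm <- llo_params(0.7, 0.5)
  below <- seq(0.01, 0.49, by = 0.02)
  above <- seq(0.51, 0.99, by = 0.02)
  expect_true(all(llo_transform(below, prm) > below))
  expect_true(all(llo_transform(above, prm) < above))
})

test_that("llo_inverse is the exact inverse", {
  p <- llo_params(0.88, 0.76)
  expect_equal(llo_inverse(0.868, p), 0.879, tolerance = 0.002)
  expect_equal(llo_inverse(0.76, p), 0.76, tolerance = 1e-12)
  set.seed(5)
  probs <- runif(50, 0.01, 0.99)
  prm <- llo_params(1.4, 0.3)
  expect_equal(llo_transform(llo_inverse(probs, prm), prm), probs,
               tolerance = 1e-10)
})

test_that("aicc/bic/evidence ratio arithmetic", {
  expect_equal(aicc(0, 2, 9), 6)
  expect_equal(aicc(-50, 1, 100), 102 + 4 / 98)
  expect_equal(bic(-50, 1, 100), 100 + log(100))
  expect_error(aicc(0, 4, 5), "N - K - 1")
  expect_equal(evidence_ratio(2), exp(1))
  expect_identical(evidence_ratio(0), 1)  # a model against itself
  # AICc converges to AIC for large N at fixed K
  expect_equal(aicc(-100, 3, 1e6), -2 * -100 + 6, tolerance = 1e-4)
})

test_that("fit_llo recovers parameters exactly from noiseless data", {
  truth <- interval_probability("symmetric", estimation_widths())
  gen <- llo_params(0.7, 0.4)
  est <- llo_transform(truth, gen)
  fit <- fit_llo(truth, est)
  expect_equal(fit$params$gamma, 0.7, tolerance = 1e-4)
  expect_equal(fit$params$p0, 0.4, tolerance = 1e-4)
  expect_identical(fit$preferred, "llo")
})

test_that("fit_llo prefers the null model on identity data", {
  truth <- interval_probability("symmetric", estimation_widths())
  fit <- fit_llo(truth, truth)
  expect_identical(fit$preferred, "null")
  expect_error(fit_llo(truth, rep(0.5, 9)), "degenerate")
  expect_error(fit_llo(c(0.2, 0.8), c(0.3, 0.7)), "length")
})

test_that("fit_llo recovers gamma and p0 under logit noise", {
  # experiment-matched design: 9 probabilities x 5 reps, logit noise 0.2
  truth <- rep(interval_probability("symmetric", estimation_widths()), 5)
  gen <- llo_params(0.88, 0.76)
  set.seed(99)
  gammas <- p0s <- numeric(60)
  for (r in 1:60) {
    est <- plogis(qlogis(llo_transform(truth, gen)) +
                    rnorm(length(truth), 0, 0.2))
    fit <- fit_llo(truth, est)
    gammas[r] <- fit$params$gamma
    p0s[r] <- fit$params$p0
  }
  expect_lt(abs(mean(gammas) - 0.88), 0.1)
  expect_lt(abs(mean(p0s) - 0.76), 0.15)
})

test_that("fit_llo is stable under a parametric-bootstrap refit", {
  truth <- rep(interval_probability("symmetric", estimation_widths()), 5)
  set.seed(3)
  est <- plogis(qlogis(llo_transform(truth, llo_params(0.8, 0.6))) +
                  rnorm(length(truth), 0, 0.15))
  f1 <- fit_llo(truth, est)
  # regenerate noiseless data from the fitted model, refit: idempotent
  est2 <- llo_transform(truth, f1$params)
  f2 <- fit_llo(truth, est2)
  expect_equal(f2$params$gamma, f1$params$gamma, tolerance = 1e-6)
  expect_equal(f2$params$p0, f1$params$p0, tolerance = 1e-4)
})

test_that("fit_additivity selects the generating hypothesis", {
  # exactly additive, noiseless
  s <- seq(0.1, 0.9, by = 0.1)
  f0 <- fit_additivity(s / 2, s / 2, s)
  expect_identical(f0$hypothesis, "H0")
  expect_identical(f0$b, 0)

  set.seed(21)
  recover_b <- function(b_true, sd, reps = 60) {
    sel <- character(reps); bs <- numeric(reps)
    for (r in seq_len(reps)) {
      su <- s / 2 + b_true / 2 + rnorm(9, 0, sd)
      sl <- s / 2 + b_true / 2 + rnorm(9, 0, sd)
      fit <- fit_additivity(pmin(pmax(su, 0.001), 0.999),
                            pmin(pmax(sl, 0.001), 0.999), s)
      sel[r] <- fit$hypothesis; bs[r] <- fit$b
    }
    list(sel = sel, b = mean(bs))
  }
  sup <- recover_b(0.065, 0.02)
  expect_gt(mean(sup$sel == "H1"), 0.9)
  expect_lt(abs(sup$b - 0.065), 0.01)
  sub <- recover_b(-0.05, 0.02)
  expect_gt(mean(sub$sel == "H2"), 0.9)
  expect_error(fit_additivity(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(fit_additivity(0.2, 0.2, 0.4), "at least 2")
})
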