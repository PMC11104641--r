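test_that("variance likelihood has the stated gamma form", {
  # mode at s2 (N-3)/(N-1) for N > 3, found numerically
  for (case in list(c(200, 30), c(150, 10), c(350, 5))) {
    s2 <- case[1]; N <- case[2]
    opt <- optimize(function(v) variance_likelihood(v, s2, N),
                    c(1, 1500), maximum = TRUE, tol = 1e-6)
    expect_equal(opt$maximum, s2 * (N - 3) / (N - 1), tolerance = 1e-3)
  }
  expect_gt(variance_likelihood(200, 200, 30),
            variance_likelihood(400, 200, 30))
  expect_error(variance_likelihood(-1, 200, 30), "> 0")
  expect_error(variance_likelihood(200, 200, 1), "N")
  # orthodox mode is a density in s2, not sigma2_hat
  expect_equal(variance_likelihood(250, 200, 5, mode = "orthodox"),
               dgamma(200, shape = 2, scale = 2 * 250 / 4))
})

test_that("variance posterior normalises, is scale-invariant and concentrates", {
  post <- variance_posterior(200, 5)
  expect_equal(sum(post$weights), 1, tolerance = 1e-10)
  expect_true(all(post$weights >= 0))
  expect_true(all(post$grid >= 100 & post$grid <= 400))
  # manual renormalised product oracle (likelihood x flat prior, trapezoid)
  grid <- post$grid
  lik <- variance_likelihood(grid, 200, 5)
  tw <- c(0.5, rep(1, length(grid) - 2), 0.5)
  expect_equal(post$weights, lik * tw / sum(lik * tw), tolerance = 1e-12)
  # s2 far above the support pushes the mass against the upper bound: the
  # density is increasing across the whole support (the flipped-likelihood
  # mode s2 (N-3)/(N-1) lies far above 400), leaving a ~sigma2/(shape-1)
  # exponential boundary layer below 400
  hi <- variance_posterior(5000, 30)
  dens <- hi$weights / c(0.5, rep(1, 599), 0.5)  # undo trapezoid end weights
  expect_identical(which.max(dens), 601L)
  expect_true(all(diff(dens) > 0))
  expect_gt(sum(hi$weights * hi$grid), 350)
  expect_gt(sum(hi$weights[hi$grid > 325]), 0.9)
  # N=5, s2=200: unimodal within the support
  mid <- variance_posterior(200, 5)
  peak <- which.max(mid$weights)
  expect_gt(peak, 1); expect_lt(peak, 601)
  expect_true(all(diff(mid$weights[1:peak]) >= -1e-15))
  expect_true(all(diff(mid$weights[peak:601]) <= 1e-15))
})

test_that("closed-form inner expected reward matches quadrature", {
  set.seed(17)
  for (penalty in c(0, -500)) {
    rw <- reward_function(penalty = penalty)
    for (k in 1:10) {
      S <- runif(1, -30, 260)
      sig <- sqrt(runif(1, 100, 400))
      expect_equal(sampleBDT:::gaussian_expected_reward(S, sig, rw),
                   quad_expected_reward(S, sig, rw), tolerance = 1e-6)
    }
  }
})

test_that("expected reward limits behave", {
  rw0 <- reward_function(penalty = 0)
  rw5 <- reward_function(penalty = -500)
  expect_equal(expected_reward(-200, 200, 5, rw0), 0, tolerance = 1e-6)
  expect_equal(expected_reward(2000, 200, 5, rw5), -500, tolerance = 1e-6)
  # reward_value itself: piecewise values
  expect_equal(reward_value(c(-5, 0, 90, 180, 180.1), rw5),
               c(0, 0, 50, 100, -500))
})

test_that("optimal set point agrees with an exhaustive 0.01 mm grid", {
  set.seed(23)
  for (k in 1:6) {
    s2 <- runif(1, 110, 390)
    N <- sample(c(5, 30), 1)
    rw <- reward_function(penalty = sample(c(0, -500), 1))
    S_opt <- as.numeric(optimal_set_point(s2, N, rw))
    fine <- seq(S_opt - 5, S_opt + 5, by = 0.01)
    eg <- expected_reward(fine, s2, N, rw)
    expect_lt(abs(fine[which.max(eg)] - S_opt), 0.05)
  }
})

test_that("optimal set point decreases in s2 and in penalty magnitude", {
  rw0 <- reward_function(penalty = 0)
  rw5 <- reward_function(penalty = -500)
  s2s <- c(120, 150, 200, 250, 300, 350)
  for (N in c(5, 30)) {
    S0 <- vapply(s2s, function(v) as.numeric(optimal_set_point(v, N, rw0)), 0)
    S5 <- vapply(s2s, function(v) as.numeric(optimal_set_point(v, N, rw5)), 0)
    expect_true(all(diff(S0) < 0))
    expect_true(all(diff(S5) < 0))
    expect_true(all(S5 < S0))          # larger penalty, safer setting
    expect_true(all(S5 < 180))         # below the boundary under penalty
  }
})

test_that("vanishing prior variance pushes S* to the boundary", {
  tiny <- variance_prior(0.5, 1.5)
  S <- as.numeric(optimal_set_point(1, 5, reward_function(penalty = -500),
                                    prior = tiny))
  expect_gt(S, 170); expect_lt(S, 180)
})

test_that("S* depends on the sample only through (s2, N)", {
  set.seed(31)
  y <- rnorm(5, 20, 15)
  s2 <- var(y)
  rw <- reward_function(penalty = -500)
  S1 <- as.numeric(optimal_set_point(s2, 5, rw))
  # permutation and uniform shift leave s2, hence S*, unchanged
  expect_identical(var(sample(y)), s2)
  expect_equal(var(y + 37.3), s2, tolerance = 1e-12)
  expect_equal(as.numeric(optimal_set_point(var(y + 37.3), 5, rw)), S1,
               tolerance = 1e-6)
  # batch path agrees with the scalar path
  b <- sampleBDT:::batch_optimal_set_point(c(s2, 200), 5, rw)
  expect_equal(b$S[1], S1, tolerance = 1e-6)
})
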