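test_that("interval probabilities follow the Gaussian CDF closed forms", {
  expect_equal(interval_probability(interval_spec("symmetric", 1.645)),
               0.90, tolerance = 0.001)
  expect_equal(interval_probability(interval_spec("upper_half", 1.645)),
               0.45, tolerance = 0.001)
  expect_identical(interval_probability("symmetric", 0), 0)
  expect_equal(interval_probability("symmetric", 50), 1)
  expect_error(interval_probability("symmetric", -0.1), "width_multiple")

  # the nine task widths induce 0.1..0.9 symmetric probabilities
  w <- estimation_widths()
  expect_equal(interval_probability("symmetric", w),
               seq(0.1, 0.9, by = 0.1), tolerance = 0.002)
  # symmetric = 2 x half, for arbitrary widths
  ws <- seq(0.05, 3, by = 0.17)
  expect_equal(interval_probability("symmetric", ws),
               2 * interval_probability("upper_half", ws))
  expect_equal(interval_probability("upper_half", ws),
               interval_probability("lower_half", ws))
})

test_that("sample_statistics returns vertical mean and unbiased variance", {
  s <- sample_statistics(cbind(x = c(5, -5), y = c(0, 2)))
  expect_equal(s$mean_y, 1)
  expect_equal(s$s2, 2)
  expect_equal(s$n, 2L)
  expect_equal(sample_statistics(rep(3, 10))$s2, 0)
  expect_error(sample_statistics(1), "at least 2")

  set.seed(41)
  y <- rnorm(2e5, 0, sqrt(200))
  expect_equal(sample_statistics(y)$s2, 200, tolerance = 0.02)
})

test_that("disc probability by quadrature matches the Rayleigh closed form", {
  for (sd in c(1.5, 3.05, 7)) {
    m <- endpoint_model(c(2, -1), sd = sd)
    for (r in c(0.5, 2, 5)) {
      p_quad <- region_probability(region_disc(c(2, -1), r), m)
      expect_equal(p_quad, 1 - exp(-r^2 / (2 * sd^2)), tolerance = 1e-6)
    }
  }
  # off-centre disc against the noncentral chi-square closed form
  m <- endpoint_model(c(0, 0), sd = 2)
  p <- region_probability(region_disc(c(3, 1), 2.5), m)
  expect_equal(p, pchisq((2.5 / 2)^2, df = 2, ncp = (sqrt(10) / 2)^2),
               tolerance = 1e-6)
})

test_that("disjoint-union additivity holds to 1e-8 for random rectangles", {
  set.seed(7)
  for (k in 1:20) {
    m <- endpoint_model(runif(2, -5, 5), sd = runif(1, 1, 6))
    x0 <- runif(1, -10, 0)
    r1 <- region_rect(c(x0, x0 + runif(1, 1, 5)), sort(runif(2, -8, 8)))
    # second rectangle strictly to the right of the first
    x1 <- r1$xlim[2] + runif(1, 0.1, 3)
    r2 <- region_rect(c(x1, x1 + runif(1, 1, 5)), sort(runif(2, -8, 8)))
    u <- region_union(r1, r2, disjoint = TRUE)
    expect_equal(region_probability(u, m),
                 region_probability(r1, m) + region_probability(r2, m),
                 tolerance = 1e-8)
  }
})

test_that("region edge cases and validation behave", {
  m <- endpoint_model(c(0, 0), sd = 2)
  expect_identical(region_probability(region_empty(), m), 0)
  # overlapping constituents declared disjoint are rejected
  a <- region_rect(c(-2, 2), c(-2, 2))
  b <- region_rect(c(0, 4), c(-1, 1))
  expect_error(region_probability(region_union(a, b, disjoint = TRUE), m),
               "overlap")
  # difference: disc minus concentric smaller disc = annulus
  ann <- region_difference(region_disc(c(0, 0), 3), region_disc(c(0, 0), 1))
  expect_equal(region_probability(ann, m),
               exp(-1 / 8) - exp(-9 / 8), tolerance = 1e-6)
  # half plane above matches pnorm directly
  expect_equal(region_probability(region_half_plane_above(1.5), m),
               pnorm(1.5 / 2, lower.tail = FALSE))
})

test_that("union of two bars matches the double-target closed form", {
  sc <- rect_scenario()
  half_gap <- sc$gap / 2
  bars <- region_union(
    region_rect(c(-half_gap - sc$bar_width, -half_gap), c(-100, 100)),
    region_rect(c(half_gap, half_gap + sc$bar_width), c(-100, 100)),
    disjoint = TRUE)
  m <- endpoint_model(c(0, 0), sd = sc$sd)
  expect_equal(region_probability(bars, m), double_target_probability(sc),
               tolerance = 1e-7)
})

test_that("gaussian_population enforces its invariants", {
  pop <- gaussian_population(vertical_variance = 200)
  expect_equal(pop$horizontal_variance, 100)
  expect_error(gaussian_population(vertical_variance = -1), "> 0")
  expect_error(gaussian_population(vertical_variance = 100,
                                   horizontal_variance = 0), "> 0")
})
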