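#' Uniform prior over the population variance
#'
#' The decision task draws the population vertical variance uniformly on
#' `[100, 400]` mm^2; the normative decision maker uses the same interval as
#' its prior.
#'
#' @param lower,upper support bounds in mm^2, `0 < lower < upper`.
#' @return an object of class `variance_prior`.
#' @export
variance_prior <- function(lower = 100, upper = 400) {
  if (!(is.numeric(lower) && is.numeric(upper) && lower > 0 && lower < upper))
    stop2("variance_prior requires 0 < lower < upper")
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "variance_prior")
}

#' Piecewise-linear reward function of the decision task
#'
#' An outcome `y` mm above the start earns `y * max_reward / boundary_height`
#' points for `0 < y <= boundary_height`, the penalty for
#' `y > boundary_height`, and 0 for `y <= 0`. Defaults: boundary 180 mm,
#' maximum reward 100 points, penalty 0 or -500 points.
#'
#' @param boundary_height penalty boundary height in mm.
#' @param max_reward reward at the boundary, points.
#' @param penalty points incurred above the boundary (0 or -500 in the task).
#' @return an object of class `reward_function`.
#' @export
reward_function <- function(boundary_height = 180, max_reward = 100,
                            penalty = 0) {
  stopifnot(boundary_height > 0, is.finite(max_reward), is.finite(penalty))
  structure(list(boundary_height = as.numeric(boundary_height),
                 max_reward = as.numeric(max_reward),
                 penalty = as.numeric(penalty)),
            class = "reward_function")
}

#' Evaluate the reward function at vertical outcomes
#' @param y vertical outcome(s) in mm relative to the start position.
#' @param reward a [reward_function()].
#' @return points earned (vectorised).
#' @export
reward_value <- function(y, reward) {
  stopifnot(inherits(reward, "reward_function"))
  out <- numeric(length(y))
  inside <- y > 0 & y <= reward$boundary_height
  out[inside] <- y[inside] * reward$max_reward / reward$boundary_height
  out[y > reward$boundary_height] <- reward$penalty
  out
}

#' Likelihood of the estimated population variance
#'
#' The sampling distribution of `s2` given `sigma2` is the scaled chi-square
#' with N-1 degrees of freedom; the decision maker's likelihood over the
#' estimated variance is obtained by exchanging the roles of `s2` and
#' `sigma2_hat` in that density ("flipped" form, the default), i.e. a
#' gamma-form density in `sigma2_hat` with shape `(N-1)/2` and scale
#' `2 s2 / (N-1)`. Its mode is `s2 (N-3)/(N-1)` for N > 3. `mode =
#' "orthodox"` instead evaluates the density of `s2` given
#' `sigma2 = sigma2_hat` (sensitivity analysis only).
#'
#' @param sigma2_hat candidate population variance(s), mm^2, > 0.
#' @param s2 observed sample variance, mm^2, > 0.
#' @param N sample size, >= 2.
#' @param mode "flipped" (default) or "orthodox".
#' @return non-negative density values (unnormalised use is fine; the
#'   posterior renormalises).
#' @export
variance_likelihood <- function(sigma2_hat, s2, N,
                                mode = c("flipped", "orthodox")) {
  mode <- match.arg(mode)
  if (any(sigma2_hat <= 0) || s2 <= 0) stop2("variances must be > 0")
  if (N < 2) stop2("N must be >= 2")
  shape <- (N - 1) / 2
  if (mode == "flipped")
    stats::dgamma(sigma2_hat, shape = shape, scale = 2 * s2 / (N - 1))
  else
    stats::dgamma(s2, shape = shape, scale = 2 * sigma2_hat / (N - 1))
}

#' Posterior over the population variance
#'
#' Weights proportional to likelihood times the uniform prior on an equally
#' spaced grid over the prior support, normalised with trapezoidal
#' quadrature weights so the masses sum to 1.
#'
#' @inheritParams variance_likelihood
#' @param prior a [variance_prior()].
#' @param grid_size number of grid points (default 601).
#' @return a `variance_posterior` list with `grid` (sigma2 values) and
#'   `weights` (masses summing to 1).
#' @export
variance_posterior <- function(s2, N, prior = variance_prior(),
                               grid_size = 601,
                               mode = c("flipped", "orthodox")) {
  mode <- match.arg(mode)
  stopifnot(inherits(prior, "variance_prior"), grid_size >= 3)
  grid <- seq(prior$lower, prior$upper, length.out = grid_size)
  lik <- variance_likelihood(grid, s2, N, mode = mode)
  w <- lik * trapezoid_weights(grid_size)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop2("variance_posterior: zero or non-finite total mass")
  structure(list(grid = grid, weights = w / tot, s2 = s2, N = N),
            class = "variance_posterior")
}

trapezoid_weights <- function(n) c(0.5, rep(1, n - 2), 0.5)

# Closed-form expected reward under a Gaussian outcome N(S, sigma2) for the
# piecewise-linear reward: slope * E[Y; 0 < Y <= H] + penalty * P(Y > H),
# with E[Y; a < Y <= b] = mu (Phi(beta) - Phi(alpha)) + sigma (phi(alpha) -
# phi(beta)). Vectorised over any combination of S and sigma of equal
# recycling length.
gaussian_expected_reward <- function(S, sigma, reward) {
  H <- reward$boundary_height
  slope <- reward$max_reward / H
  alpha <- (0 - S) / sigma
  beta <- (H - S) / sigma
  trunc_mean <- S * (stats::pnorm(beta) - stats::pnorm(alpha)) +
    sigma * (stats::dnorm(alpha) - stats::dnorm(beta))
  slope * trunc_mean + reward$penalty * stats::pnorm(beta, lower.tail = FALSE)
}

#' Posterior-weighted expected reward of a set point
#'
#' `EG(S)`: the expected reward of translating the sample (and hence the
#' estimated pdf) by `S`, averaging the closed-form Gaussian expected reward
#' over the posterior on the population variance.
#'
#' @param S set point(s) in mm (vectorised).
#' @inheritParams variance_posterior
#' @param reward a [reward_function()].
#' @return expected reward in points, same length as `S`.
#' @export
expected_reward <- function(S, s2, N, reward = reward_function(),
                            prior = variance_prior(), grid_size = 601) {
  post <- variance_posterior(s2, N, prior, grid_size)
  sig <- sqrt(post$grid)
  vapply(S, function(si)
    sum(post$weights * gaussian_expected_reward(si, sig, reward)), 0)
}

#' Optimal set point of the normative BDT decision maker
#'
#' Maximises the posterior-weighted expected reward over the set point by a
#' dense grid search followed by local refinement with [stats::optimize()]
#' (final precision well below 0.05 mm). The optimum depends on the sample
#' only through `(s2, N)`.
#'
#' @inheritParams expected_reward
#' @param s_grid candidate set points for the coarse search (mm); default a
#'   1-mm grid on `[-20, 280]`, refined locally afterwards.
#' @param details if TRUE return a list with the expected-gain landscape.
#' @return the optimal set point `S*` in mm (with attribute `expected_gain`),
#'   or a detail list when `details = TRUE`.
#' @export
optimal_set_point <- function(s2, N, reward = reward_function(),
                              prior = variance_prior(), grid_size = 601,
                              s_grid = NULL, details = FALSE) {
  res <- batch_optimal_set_point(s2, N, reward, prior, grid_size, s_grid)
  if (details)
    return(list(S = res$S[1], expected_gain = res$expected_gain[1],
                s_grid = res$s_grid, landscape = res$landscape[1, ]))
  out <- res$S
  attr(out, "expected_gain") <- res$expected_gain
  out
}

# Vectorised optimal set points for many sample variances at a shared N.
# The per-sigma expected-reward matrix M (grid x set points) is shared across
# all s2 values, so the posterior-weighted landscape is a single matrix
# product. Each row is then refined around its coarse argmax.
batch_optimal_set_point <- function(s2, N, reward = reward_function(),
                                    prior = variance_prior(),
                                    grid_size = 601, s_grid = NULL,
                                    refine_tol = 1e-4) {
  stopifnot(all(s2 > 0), N >= 2)
  if (is.null(s_grid)) s_grid <- seq(-20, 280, by = 1)
  grid <- seq(prior$lower, prior$upper, length.out = grid_size)
  sig <- sqrt(grid)
  M <- outer(sig, s_grid, function(sg, ss)
    gaussian_expected_reward(ss, sg, reward))

  tw <- trapezoid_weights(grid_size)
  L <- vapply(s2, function(v)
    variance_likelihood(grid, v, N) * tw, numeric(grid_size))
  W <- t(L) / colSums(L)                   # n_s2 x grid, rows sum to 1
  landscape <- W %*% M                     # n_s2 x n_sgrid
  idx <- max.col(landscape, ties.method = "first")

  step <- if (length(s_grid) > 1) diff(s_grid)[1] else 1
  n <- length(s2)
  S <- numeric(n); EG <- numeric(n)
  for (k in seq_len(n)) {
    w <- W[k, ]
    f <- function(ss) sum(w * gaussian_expected_reward(ss, sig, reward))
    lo <- s_grid[max(idx[k] - 1, 1)]
    hi <- s_grid[min(idx[k] + 1, length(s_grid))]
    if (hi > lo) {
      op <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = refine_tol)
      S[k] <- op$maximum; EG[k] <- op$objective
    } else {
      S[k] <- s_grid[idx[k]]; EG[k] <- landscape[k, idx[k]]
    }
  }
  list(S = S, expected_gain = EG, s_grid = s_grid, landscape = landscape)
}
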