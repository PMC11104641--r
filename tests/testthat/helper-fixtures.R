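# Shared fixture builders. All randomness is seeded by the caller.

# Independent quadrature oracle for the expected reward under N(S, sigma^2):
# integrates the reward function against the Gaussian density over a finite
# window wide enough to capture all mass.
quad_expected_reward <- function(S, sigma, reward) {
  H <- reward$boundary_height
  # integrate each smooth piece separately (the reward is discontinuous at H)
  ramp <- stats::integrate(function(y) y * reward$max_reward / H *
                             stats::dnorm(y, S, sigma),
                           0, H, abs.tol = 1e-11,
                           subdivisions = 800L)$value
  tail_mass <- stats::integrate(function(y) stats::dnorm(y, S, sigma),
                                H, max(H + 12 * sigma, S + 12 * sigma),
                                abs.tol = 1e-11, subdivisions = 800L)$value
  ramp + reward$penalty * tail_mass
}

# Independent ridge oracle: augmented least squares on centred data solved
# by QR (a different algebraic route from the normal-equations solve).
ridge_oracle <- function(P, S, lambda) {
  cm <- colMeans(P); ym <- mean(S)
  X <- sweep(P, 2, cm); y <- S - ym
  Xa <- rbind(X, diag(sqrt(lambda), ncol(X)))
  ya <- c(y, rep(0, ncol(X)))
  W <- qr.solve(Xa, ya)
  list(weights = as.numeric(W), intercept = ym - sum(cm * W))
}

# Max-Point observer decision trials without going through the session
# generator (direct, minimal): N points per trial, boundary B, noise sd.
make_max_point_trials <- function(n_trials, N, B, noise_sd, penalty = 0,
                                  seed = 1) {
  withr_seed <- function(code) code  # trials built under caller's seed
  set.seed(seed)
  sigma2 <- runif(n_trials, 100, 400)
  pts <- lapply(seq_len(n_trials), function(i) rnorm(N, 0, sqrt(sigma2[i])))
  p_max <- vapply(pts, max, 0)
  s2 <- vapply(pts, var, 0)
  S <- B - p_max + rnorm(n_trials, 0, noise_sd)
  list(trials = data.frame(trial_id = seq_len(n_trials), penalty = penalty,
                           n_points = N, s2 = s2, p_max = p_max,
                           set_point = S),
       points = pts)
}
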