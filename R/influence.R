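#' Influence design matrix from decision trials
#'
#' Builds the order-statistic predictor matrix: row j holds the sorted
#' vertical coordinates (ascending, mm relative to the start) of trial j's
#' sample; the response is the trial's set point. Construction is
#' permutation-invariant to the within-trial point order.
#'
#' @param points_by_trial list of numeric vectors (vertical coordinates per
#'   trial) or a matrix with one row per trial.
#' @param set_points numeric vector of set points (mm), one per trial.
#' @return an `influence_design` list with matrix `P` (trials x order index)
#'   and response `S`.
#' @export
influence_design <- function(points_by_trial, set_points) {
  if (is.matrix(points_by_trial))
    points_by_trial <- split(points_by_trial, row(points_by_trial))
  n <- length(points_by_trial)
  if (n < 2) stop2("influence_design needs at least 2 trials")
  if (length(set_points) != n)
    stop2("set_points must have one entry per trial")
  sizes <- lengths(points_by_trial)
  if (length(unique(sizes)) != 1)
    stop2("all trials must share the same sample size N; got N in {",
          paste(sort(unique(sizes)), collapse = ", "), "}")
  P <- t(vapply(points_by_trial, function(p) sort(as.numeric(p)),
                numeric(sizes[1])))
  structure(list(P = P, S = as.numeric(set_points)),
            class = "influence_design")
}

#' Ridge regression with unpenalised intercept
#'
#' Minimises `sum_j (S_j - sum_i W_i P_ij - W_0)^2 + lambda sum_i W_i^2`.
#' Predictors and response are centred before penalisation (no variance
#' scaling: all predictors share units of mm); the intercept is recovered
#' afterwards and never penalised.
#'
#' @param design an [influence_design()].
#' @param lambda ridge penalty, >= 0.
#' @return list with `weights` (length N) and `intercept`.
#' @export
ridge_fit <- function(design, lambda) {
  stopifnot(inherits(design, "influence_design"), lambda >= 0)
  P <- design$P; S <- design$S
  cm <- colMeans(P); ym <- mean(S)
  X <- sweep(P, 2, cm)
  y <- S - ym
  A <- crossprod(X) + diag(lambda, ncol(X))
  W <- drop(solve(A, crossprod(X, y)))
  list(weights = W, intercept = ym - sum(cm * W))
}

#' Choose the ridge penalty by 10-fold CV and the one-SE rule
#'
#' For each candidate lambda, the mean and standard error of the validation
#' mean-squared error are computed across folds; the selected lambda is the
#' largest one whose mean error does not exceed the minimum mean error plus
#' one standard error (at the minimiser). Fold assignment is a seeded random
#' permutation, reproducible under a fixed seed.
#'
#' @inheritParams ridge_fit
#' @param lambda_grid candidate penalties (default 60 log-spaced points on
#'   `[1e-2, 1e5]`).
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return list with `lambda` (chosen), `lambda_min`, `cv` (data frame of
#'   lambda, mean error, SE).
#' @export
select_lambda <- function(design, lambda_grid = default_lambda_grid(),
                          folds = 10, seed = 1) {
  stopifnot(inherits(design, "influence_design"))
  if (length(lambda_grid) < 2) stop2("lambda_grid must have length >= 2")
  n <- nrow(design$P)
  if (n < folds) stop2("need at least `folds` trials")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  lambda_grid <- sort(lambda_grid)

  err <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    d_tr <- structure(list(P = design$P[tr, , drop = FALSE],
                           S = design$S[tr]), class = "influence_design")
    P_va <- design$P[!tr, , drop = FALSE]
    S_va <- design$S[!tr]
    for (k in seq_along(lambda_grid)) {
      fit <- ridge_fit(d_tr, lambda_grid[k])
      pred <- drop(P_va %*% fit$weights) + fit$intercept
      err[f, k] <- mean((S_va - pred)^2)
    }
  }
  m <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(folds)
  i_min <- which.min(m)
  ok <- which(m <= m[i_min] + se[i_min])
  chosen <- lambda_grid[max(ok)]
  list(lambda = chosen, lambda_min = lambda_grid[i_min],
       cv = data.frame(lambda = lambda_grid, mean_error = m, se = se))
}

#' @rdname select_lambda
#' @export
default_lambda_grid <- function() 10^seq(-2, 5, length.out = 60)

#' Empirical influence of each sample point
#'
#' Ridge-regression weights of the per-trial order statistics on the set
#' point, at the penalty selected by 10-fold cross-validation with the
#' one-standard-error rule. One weight per order index: the empirical
#' influence of the i-th smallest sample point.
#'
#' @inheritParams influence_design
#' @inheritParams select_lambda
#' @param lambda optional fixed penalty; when NULL (default) it is selected
#'   by [select_lambda()].
#' @return an `influence_profile` list with `order_index`, `empirical`
#'   weights, `intercept`, `lambda`, and the CV table when CV was run.
#' @export
empirical_influence <- function(points_by_trial, set_points, lambda = NULL,
                                lambda_grid = default_lambda_grid(),
                                folds = 10, seed = 1) {
  design <- influence_design(points_by_trial, set_points)
  cv <- NULL
  if (is.null(lambda)) {
    sel <- select_lambda(design, lambda_grid, folds, seed)
    lambda <- sel$lambda
    cv <- sel$cv
  }
  fit <- ridge_fit(design, lambda)
  structure(list(order_index = seq_len(ncol(design$P)),
                 empirical = fit$weights, intercept = fit$intercept,
                 lambda = lambda, cv = cv),
            class = "influence_profile")
}

#' Normative influence by Monte-Carlo perturbation
#'
#' For each order index i, the influence of the i-th smallest sample point on
#' the normative optimal set point is estimated by numerical
#' differentiation: change that point by `delta` (1 mm in total by default),
#' recompute the optimal set point, and average the shift divided by `delta`
#' over `n_sims` freshly generated samples (population variance redrawn
#' uniformly from the prior support on each). The default is a central
#' difference (the point moved by `+delta/2` and `-delta/2`): because the
#' sample variance is quadratic in each coordinate, the one-sided `+delta`
#' scheme inflates the perturbed variances so that the influence profile
#' sums to `dS*/ds2 * delta` rather than zero; the central scheme cancels
#' that O(delta) bias while still changing the point by `delta` mm. Use
#' `difference = "forward"` for the literal one-sided scheme. The
#' perturbation is attributed to the original order index even when it would
#' swap adjacent order statistics.
#'
#' @param N sample size (5 or 30 in the task).
#' @param reward a [reward_function()].
#' @param prior a [variance_prior()]; also the generating distribution of the
#'   population variance.
#' @param n_sims number of Monte-Carlo samples (default 1000).
#' @param delta total perturbation size in mm.
#' @param seed RNG seed.
#' @param grid_size variance posterior grid size.
#' @param difference "central" (default) or "forward".
#' @return list with `order_index`, `normative` weights (mm per mm),
#'   `n_sims`, `delta`, `difference`.
#' @export
normative_influence <- function(N, reward = reward_function(),
                                prior = variance_prior(), n_sims = 1000,
                                delta = 1, seed = 1, grid_size = 601,
                                difference = c("central", "forward")) {
  difference <- match.arg(difference)
  stopifnot(delta > 0, N >= 2, n_sims >= 1)
  sims <- with_seed(seed, {
    lapply(seq_len(n_sims), function(r) {
      sigma2 <- stats::runif(1, prior$lower, prior$upper)
      sort(stats::rnorm(N, 0, sqrt(sigma2)))
    })
  })
  pert_var <- function(y, i, d) {
    yi <- y; yi[i] <- yi[i] + d; stats::var(yi)
  }
  if (difference == "forward") {
    # s2 for each base sample and each one-sided perturbation
    s2_all <- vapply(sims, function(y) {
      c(stats::var(y),
        vapply(seq_len(N), pert_var, 0, y = y, d = delta))
    }, numeric(N + 1))
    res <- batch_optimal_set_point(as.numeric(s2_all), N, reward, prior,
                                   grid_size)
    S <- matrix(res$S, nrow = N + 1)  # row 1 base, rows 2..N+1 perturbed
    shifts <- (S[-1, , drop = FALSE] -
               matrix(S[1, ], nrow = N, ncol = n_sims, byrow = TRUE)) / delta
  } else {
    # paired +delta/2 / -delta/2 perturbations of each order statistic
    s2_all <- vapply(sims, function(y) {
      c(vapply(seq_len(N), pert_var, 0, y = y, d = delta / 2),
        vapply(seq_len(N), pert_var, 0, y = y, d = -delta / 2))
    }, numeric(2 * N))
    res <- batch_optimal_set_point(as.numeric(s2_all), N, reward, prior,
                                   grid_size)
    S <- matrix(res$S, nrow = 2 * N)
    shifts <- (S[seq_len(N), , drop = FALSE] -
               S[N + seq_len(N), , drop = FALSE]) / delta
  }
  list(order_index = seq_len(N), normative = rowMeans(shifts),
       n_sims = n_sims, delta = delta, difference = difference)
}

#' Influence ratios with masking of unreliable entries
#'
#' `phi_i = empirical_i / normative_i`; entries whose normative influence is
#' below `mask_threshold` in magnitude cannot be estimated reliably and are
#' reported as NA. The default threshold is 5% of the largest normative
#' magnitude.
#'
#' @param empirical,normative equal-length weight vectors.
#' @param mask_threshold absolute masking threshold; default
#'   `0.05 * max(abs(normative))`.
#' @return list with `ratio` (NA where masked), `masked` (logical), and the
#'   threshold used. Warns when every entry is masked.
#' @export
influence_ratio <- function(empirical, normative,
                            mask_threshold = 0.05 * max(abs(normative))) {
  if (length(empirical) != length(normative))
    stop2("profiles must have equal length")
  masked <- abs(normative) < mask_threshold
  ratio <- empirical / normative
  ratio[masked] <- NA_real_
  if (all(masked)) warning("all influence ratios masked", call. = FALSE)
  list(ratio = ratio, masked = masked, mask_threshold = mask_threshold)
}
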