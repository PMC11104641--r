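#' Max-Point heuristic prediction
#'
#' The heuristic places the sample's highest point at a mental reference
#' boundary `B`: the set point is `S = B - P_MAX` where `P_MAX` is the
#' maximum vertical coordinate of the sample at the start position.
#'
#' @param points sample points (matrix/data frame with a y column, or a
#'   numeric vector of vertical coordinates).
#' @param B mental reference boundary in mm.
#' @return predicted set point in mm.
#' @export
max_point_predict <- function(points, B) {
  y <- vertical_coords(points)
  if (length(y) == 0) stop2("max_point_predict: empty sample")
  stopifnot(is.finite(B))
  B - max(y)
}

#' Fit the Max-Point model to decision trials
#'
#' One boundary per penalty condition, shared across sample sizes. The
#' least-squares (and Gaussian-MLE) boundary is closed form:
#' `B-hat = mean(S_j + P_MAX,j)` within each penalty group. Residual noise is
#' Gaussian with an MLE standard deviation per penalty group.
#'
#' @param trials a decision-trial data frame with columns `penalty`,
#'   `set_point` and `p_max` (maximum vertical sample coordinate), e.g. from
#'   [simulate_decision_session()] (which provides `p_max`) or built from a
#'   points table.
#' @return a `max_point_fit` list: `B` (named by penalty level), `sigma`
#'   (named), `fit` (a pooled [aicc()]-bearing result with
#'   K = #boundaries + #noise parameters), and per-trial `predicted`.
#' @export
fit_max_point <- function(trials) {
  needed <- c("penalty", "set_point", "p_max")
  if (!all(needed %in% names(trials)))
    stop2("fit_max_point: trials must have columns ",
          paste(needed, collapse = ", "))
  groups <- split(seq_len(nrow(trials)), trials$penalty)
  if (any(lengths(groups) < 2))
    stop2("fit_max_point: a penalty group has fewer than 2 trials")
  B <- numeric(0); sigma <- numeric(0); logL <- 0
  predicted <- numeric(nrow(trials))
  for (g in names(groups)) {
    idx <- groups[[g]]
    Bg <- mean(trials$set_point[idx] + trials$p_max[idx])
    pred <- Bg - trials$p_max[idx]
    sg <- max(sqrt(mean((trials$set_point[idx] - pred)^2)), 1e-8)
    logL <- logL + sum(stats::dnorm(trials$set_point[idx], pred, sg,
                                    log = TRUE))
    B[g] <- Bg; sigma[g] <- sg
    predicted[idx] <- pred
  }
  K <- length(B) + length(sigma)
  structure(list(B = B, sigma = sigma, predicted = predicted,
                 fit = fit_result(list(B = B, sigma = sigma), logL,
                                  K = K, N = nrow(trials))),
            class = "max_point_fit")
}

#' @export
print.max_point_fit <- function(x, ...) {
  cat("Max-Point fit:\n")
  for (g in names(x$B))
    cat(sprintf("  penalty %s: B = %.2f mm (residual sd %.2f mm)\n",
                g, x$B[g], x$sigma[g]))
  print(x$fit)
  invisible(x)
}

#' Compare the normative BDT and Max-Point models on decision trials
#'
#' Both models produce a per-trial predicted set point; residuals around the
#' prediction are Gaussian with one MLE noise parameter per condition
#' (penalty x sample size). BDT has no structural free parameters
#' (K = #conditions); Max-Point fits one boundary per penalty level
#' (K = #penalty levels + #conditions). AICc, BIC and evidence ratios
#' `exp(dAICc / 2)` against the best model are reported.
#'
#' @param trials decision-trial data frame with columns `penalty`,
#'   `n_points`, `set_point`, `s2` and `p_max`.
#' @param reward_max,boundary_height reward-function constants shared by the
#'   conditions (the penalty column supplies the penalty).
#' @param prior a [variance_prior()].
#' @param grid_size variance posterior grid size.
#' @return a `comparison_table` data frame with one row per model.
#' @export
compare_models <- function(trials, reward_max = 100, boundary_height = 180,
                           prior = variance_prior(), grid_size = 601) {
  needed <- c("penalty", "n_points", "set_point", "s2", "p_max")
  if (!all(needed %in% names(trials)))
    stop2("compare_models: trials must have columns ",
          paste(needed, collapse = ", "))
  n <- nrow(trials)

  # per-trial BDT predictions, batched within (penalty, N) groups
  bdt_pred <- numeric(n)
  cond <- interaction(trials$penalty, trials$n_points, drop = TRUE)
  for (g in levels(cond)) {
    idx <- which(cond == g)
    rw <- reward_function(boundary_height, reward_max,
                          penalty = trials$penalty[idx[1]])
    bdt_pred[idx] <- batch_optimal_set_point(
      trials$s2[idx], trials$n_points[idx[1]], rw, prior, grid_size)$S
  }
  mp <- fit_max_point(trials)

  logL_cond <- function(pred) {
    tot <- 0
    for (g in levels(cond)) {
      idx <- which(cond == g)
      sg <- max(sqrt(mean((trials$set_point[idx] - pred[idx])^2)), 1e-8)
      tot <- tot + sum(stats::dnorm(trials$set_point[idx], pred[idx], sg,
                                    log = TRUE))
    }
    tot
  }
  n_cond <- nlevels(cond)
  n_pen <- length(unique(trials$penalty))
  models <- data.frame(
    model = c("normative_bdt", "max_point"),
    log_likelihood = c(logL_cond(bdt_pred), logL_cond(mp$predicted)),
    K = c(n_cond, n_pen + n_cond))
  models$aicc <- mapply(aicc, models$log_likelihood, models$K,
                        MoreArgs = list(N = n))
  models$bic <- mapply(bic, models$log_likelihood, models$K,
                       MoreArgs = list(N = n))
  best <- min(models$aicc)
  models$evidence_ratio_vs_best <- evidence_ratio(models$aicc - best)^-1
  attr(models, "predictions") <- data.frame(normative_bdt = bdt_pred,
                                            max_point = mp$predicted)
  attr(models, "max_point_fit") <- mp
  class(models) <- c("comparison_table", class(models))
  models
}

#' Efficiency of a decision maker
#'
#' The ratio of the realized total score to the total expected score the
#' normative BDT decision maker would have obtained at its optimal set
#' points, given the same samples.
#'
#' @param trials decision-trial data frame with columns `penalty`,
#'   `n_points`, `s2` and `score` (realized points).
#' @inheritParams compare_models
#' @return the efficiency ratio (1 = normative performance in expectation).
#' @export
efficiency <- function(trials, reward_max = 100, boundary_height = 180,
                       prior = variance_prior(), grid_size = 601) {
  needed <- c("penalty", "n_points", "s2", "score")
  if (!all(needed %in% names(trials)))
    stop2("efficiency: trials must have columns ",
          paste(needed, collapse = ", "))
  cond <- interaction(trials$penalty, trials$n_points, drop = TRUE)
  opt <- numeric(nrow(trials))
  for (g in levels(cond)) {
    idx <- which(cond == g)
    rw <- reward_function(boundary_height, reward_max,
                          penalty = trials$penalty[idx[1]])
    opt[idx] <- batch_optimal_set_point(
      trials$s2[idx], trials$n_points[idx[1]], rw, prior,
      grid_size)$expected_gain
  }
  denom <- sum(opt)
  if (abs(denom) < 1e-12) stop2("efficiency: zero optimal expected score")
  sum(trials$score) / denom
}
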