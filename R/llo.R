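#' Linear-in-log-odds (LLO) distortion parameters
#'
#' The LLO model distorts a probability p by a linear map on the log-odds
#' scale: `Lo(phat) = gamma * Lo(p) + (1 - gamma) * Lo(p0)` where
#' `Lo(q) = log(q / (1 - q))`. `gamma` is the slope; `p0` is the crossover
#' probability where the distortion curve crosses the identity line.
#'
#' @param gamma slope on the log-odds scale, > 0.
#' @param p0 crossover probability in (0, 1).
#' @return an object of class `llo_params`.
#' @export
llo_params <- function(gamma, p0) {
  if (!is.numeric(gamma) || gamma <= 0) stop2("gamma must be > 0")
  assert_prob(p0, "p0")
  structure(list(gamma = as.numeric(gamma), p0 = as.numeric(p0)),
            class = "llo_params")
}

#' @export
print.llo_params <- function(x, ...) {
  cat(sprintf("LLO distortion: gamma = %.4g, p0 = %.4g\n", x$gamma, x$p0))
  invisible(x)
}

#' Apply the LLO probability distortion
#'
#' @param p probability in (0, 1); vectorised.
#' @param params an [llo_params()] object.
#' @return the distorted probability.
#' @export
#' @examples
#' llo_transform(0.879, llo_params(0.88, 0.76))  # ~0.868
llo_transform <- function(p, params) {
  stopifnot(inherits(params, "llo_params"))
  assert_prob(p, "p")
  stats::plogis(params$gamma * stats::qlogis(p) +
                (1 - params$gamma) * stats::qlogis(params$p0))
}

#' Invert the LLO probability distortion
#'
#' @param phat distorted probability in (0, 1); vectorised.
#' @inheritParams llo_transform
#' @return the undistorted probability, so that
#'   `llo_transform(llo_inverse(x, params), params) == x`.
#' @export
llo_inverse <- function(phat, params) {
  stopifnot(inherits(params, "llo_params"))
  assert_prob(phat, "phat")
  stats::plogis((stats::qlogis(phat) -
                 (1 - params$gamma) * stats::qlogis(params$p0)) / params$gamma)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2K + (2K^2 + 2K) / (N - K - 1)`.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param K number of free parameters, >= 1.
#' @param N number of observations; requires `N - K - 1 > 0`.
#' @return the AICc value.
#' @export
aicc <- function(log_likelihood, K, N) {
  if (N - K - 1 <= 0) stop2("aicc requires N - K - 1 > 0")
  -2 * log_likelihood + 2 * K + (2 * K^2 + 2 * K) / (N - K - 1)
}

#' Bayesian information criterion
#' @inheritParams aicc
#' @return the BIC value `-2 logL + K log(N)`.
#' @export
bic <- function(log_likelihood, K, N) -2 * log_likelihood + K * log(N)

#' Evidence ratio from an AICc difference
#'
#' `exp(delta_aicc / 2)`: how many times more likely the data are under the
#' alternative than under the null, where
#' `delta_aicc = AICc(null) - AICc(alternative)`.
#' @param delta_aicc AICc difference.
#' @export
evidence_ratio <- function(delta_aicc) exp(delta_aicc / 2)

# Bundle a fit into the standard result shape used across the package.
fit_result <- function(params, log_likelihood, K, N) {
  structure(list(params = params, log_likelihood = log_likelihood,
                 K = K, N = N,
                 aicc = aicc(log_likelihood, K, N),
                 bic = bic(log_likelihood, K, N)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: logL = %.3f, K = %d, N = %d, AICc = %.3f, BIC = %.3f\n",
              x$log_likelihood, x$K, x$N, x$aicc, x$bic))
  invisible(x)
}

#' Maximum-likelihood fit of the LLO distortion model
#'
#' The noise model is Gaussian error on the logit of the estimate with
#' constant variance (one extra parameter), so the MLE of (gamma, p0) is the
#' least-squares line on the logit scale: `logit(estimate)` regressed on
#' `logit(truth)`, with `gamma` the slope and `p0` recovered from the
#' intercept `(1 - gamma) logit(p0)`. The null model of no distortion
#' (gamma = 1, estimate = truth + logit noise) is fitted alongside and the
#' AICc difference and evidence ratio `exp(delta AICc / 2)` are reported.
#' Estimates at 0 or 1 are clipped to `[clip, 1 - clip]` before the logit.
#'
#' @param truth true probabilities (at least 3 distinct values).
#' @param estimate the decision maker's probability estimates.
#' @param clip clipping bound applied to the estimates (default 0.005).
#' @return a `llo_fit` list: `params` ([llo_params()]), `sigma` (logit-scale
#'   residual SD), `fit` and `null_fit` ([aicc()]-bearing results),
#'   `delta_aicc`, `evidence_ratio`, and `preferred` ("llo" or "null").
#' @export
fit_llo <- function(truth, estimate, clip = 0.005) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 3)
  assert_prob(truth, "truth")
  if (length(unique(truth)) < 3)
    stop2("fit_llo needs at least 3 distinct true probabilities")
  estimate <- pmin(pmax(estimate, clip), 1 - clip)
  if (stats::sd(estimate) == 0)
    stop2("degenerate data: all estimates identical")
  x <- stats::qlogis(truth)
  y <- stats::qlogis(estimate)
  n <- length(y)

  cf <- stats::coef(stats::lm(y ~ x))
  gamma <- unname(cf[2]); intercept <- unname(cf[1])
  if (gamma <= 0) {
    # outside the admissible region; pin the slope just above zero
    gamma <- 1e-6
    intercept <- mean(y) - gamma * mean(x)
  }
  p0 <- if (abs(1 - gamma) < 1e-8) 0.5
        else stats::plogis(intercept / (1 - gamma))
  # keep p0 in the open unit interval for downstream use
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)

  mu <- gamma * x + intercept
  sigma <- sqrt(mean((y - mu)^2))
  sigma <- max(sigma, 1e-8)
  logL <- sum(stats::dnorm(y, mu, sigma, log = TRUE))
  fit <- fit_result(llo_params(gamma, p0), logL, K = 3L, N = n)

  sigma0 <- max(sqrt(mean((y - x)^2)), 1e-8)
  logL0 <- sum(stats::dnorm(y, x, sigma0, log = TRUE))
  null_fit <- fit_result(NULL, logL0, K = 1L, N = n)

  delta <- null_fit$aicc - fit$aicc
  structure(list(params = fit$params, sigma = sigma, fit = fit,
                 null_fit = null_fit, delta_aicc = delta,
                 evidence_ratio = evidence_ratio(delta),
                 preferred = if (delta > 0) "llo" else "null"),
            class = "llo_fit")
}

#' @export
print.llo_fit <- function(x, ...) {
  cat(sprintf(
    "LLO fit: gamma = %.3f, p0 = %.3f, sigma = %.3f (logits)\n",
    x$params$gamma, x$params$p0, x$sigma))
  cat(sprintf("  vs null (gamma = 1): dAICc = %.2f, evidence ratio = %.3g\n",
              x$delta_aicc, x$evidence_ratio))
  invisible(x)
}

#' Fit the additivity offset over disjoint interval estimates
#'
#' For triples of estimates (upper half `su`, lower half `sl`, symmetric
#' union `s`), the model is `su + sl = s + b` with Gaussian residuals. Three
#' hypotheses are compared by AICc: H0 additive (b = 0, K = 1), H1
#' super-additive (b > 0, K = 2), and H2 sub-additive (b < 0, K = 2). The
#' sign-constrained MLEs of b are the clamped residual mean; a tie at
#' b-hat ~ 0 is broken toward H0 (parsimony).
#'
#' @param su,sl,s estimates in (0, 1), equal lengths, at least 2 triples.
#' @return an `additivity_fit` list with `b` (the selected model's offset),
#'   `hypothesis` ("H0", "H1" or "H2"), a per-hypothesis `table`
#'   (data frame with b, logL, K, AICc, BIC, evidence ratio vs H0), and the
#'   unconstrained `b_hat`.
#' @export
fit_additivity <- function(su, sl, s) {
  n <- length(s)
  if (n == 0) stop2("fit_additivity: empty input")
  stopifnot(length(su) == n, length(sl) == n)
  if (n < 2) stop2("fit_additivity needs at least 2 triples")
  assert_prob(c(su, sl, s), "estimates")
  r <- su + sl - s
  b_hat <- mean(r)

  loglik_b <- function(b) {
    sigma <- max(sqrt(mean((r - b)^2)), 1e-10)
    sum(stats::dnorm(r, b, sigma, log = TRUE))
  }
  bs <- c(H0 = 0, H1 = max(b_hat, 0), H2 = min(b_hat, 0))
  Ks <- c(H0 = 1L, H1 = 2L, H2 = 2L)
  logLs <- vapply(bs, loglik_b, 0)
  aiccs <- mapply(aicc, logLs, Ks, MoreArgs = list(N = n))
  bics <- mapply(bic, logLs, Ks, MoreArgs = list(N = n))

  # prefer H0 on ties (including the degenerate b_hat == 0 case)
  ord <- order(aiccs, c(0, 1, 1))
  best <- names(bs)[ord[1]]
  tab <- data.frame(hypothesis = names(bs), b = unname(bs),
                    log_likelihood = unname(logLs), K = unname(Ks),
                    aicc = unname(aiccs), bic = unname(bics),
                    evidence_ratio_vs_H0 =
                      evidence_ratio(aiccs["H0"] - unname(aiccs)),
                    row.names = NULL)
  structure(list(b = unname(bs[best]), hypothesis = best, b_hat = b_hat,
                 table = tab),
            class = "additivity_fit")
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat(sprintf("Additivity fit: %s selected, b = %.4f (unconstrained %.4f)\n",
              x$hypothesis, x$b, x$b_hat))
  print(x$table, digits = 4)
  invisible(x)
}
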