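#' Session configuration for the synthetic experiments
#'
#' Defaults reproduce the human experiment's structure: the estimation
#' session crosses 2 sample sizes x 3 interval configurations x 9 widths x 5
#' repetitions = 270 trials; the decision session crosses 2 sample sizes x 2
#' penalty levels x 50 repetitions = 200 trials.
#'
#' @param task "estimation" or "decision".
#' @param sample_sizes sample sizes N (default c(5, 30)).
#' @param widths interval width multiples (estimation; default
#'   [estimation_widths()]).
#' @param penalties penalty levels (decision; default c(0, -500)).
#' @param repetitions repetitions per condition (default 5 for estimation,
#'   50 for decision).
#' @param seed RNG seed for the session.
#' @return an object of class `session_config`.
#' @export
session_config <- function(task = c("estimation", "decision"),
                           sample_sizes = c(5, 30),
                           widths = estimation_widths(),
                           penalties = c(0, -500),
                           repetitions = NULL, seed = 1) {
  task <- match.arg(task)
  repetitions <- repetitions %||% if (task == "estimation") 5L else 50L
  structure(list(task = task, sample_sizes = as.integer(sample_sizes),
                 widths = widths, penalties = penalties,
                 repetitions = as.integer(repetitions),
                 seed = seed),
            class = "session_config")
}

#' Artificial observer specification
#'
#' Agents for the estimation task: `llo_estimator` (reports the LLO
#' distortion of the true probability, optionally super-additive via `b`
#' split equally over the half intervals, with Gaussian noise on the logit),
#' `counting_estimator` (fraction of sample points inside the interval) and
#' `constant`. Agents for the decision task: `normative_bdt` (optimal set
#' point), `max_point` (`S = B - P_MAX`), `mean_tracker` (`S = B - mean`),
#' and `constant`; all with additive Gaussian response noise on the set
#' point.
#'
#' @param kind agent kind (see above).
#' @param llo an [llo_params()] for `llo_estimator`.
#' @param b additivity offset for `llo_estimator` (adds b/2 to each half
#'   -interval estimate); default 0.
#' @param B named or single mental boundary (mm) for `max_point` /
#'   `mean_tracker`; a named vector maps penalty levels to boundaries.
#' @param constant constant response (probability or set point).
#' @param noise_sd response noise SD: logits for estimation agents
#'   (default 0), mm for decision agents (default 0).
#' @return an object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("llo_estimator", "counting_estimator",
                                "constant", "normative_bdt", "max_point",
                                "mean_tracker"),
                       llo = NULL, b = 0, B = NULL, constant = NULL,
                       noise_sd = 0) {
  kind <- match.arg(kind)
  if (kind == "llo_estimator" && is.null(llo))
    stop2("llo_estimator needs llo = llo_params(...)")
  if (kind %in% c("max_point", "mean_tracker") && is.null(B))
    stop2(kind, " needs a boundary B")
  if (kind == "constant" && is.null(constant))
    stop2("constant agent needs `constant`")
  stopifnot(noise_sd >= 0)
  structure(list(kind = kind, llo = llo, b = b, B = B, constant = constant,
                 noise_sd = noise_sd),
            class = "agent_spec")
}

#' Draw a population for one trial
#'
#' The population vertical variance is uniform on `[100, 400]` mm^2 (the
#' prior support), the horizontal variance is half the vertical, and the
#' mean sits at the screen origin.
#'
#' @param seed optional RNG seed.
#' @param prior a [variance_prior()] giving the variance range.
#' @return a [gaussian_population()].
#' @export
draw_population <- function(seed = NULL, prior = variance_prior()) {
  sigma2 <- with_seed(seed, stats::runif(1, prior$lower, prior$upper))
  gaussian_population(vertical_variance = sigma2)
}

#' Draw a sample of points from a population
#'
#' @param pop a [gaussian_population()].
#' @param N sample size, >= 2.
#' @param seed optional RNG seed.
#' @return an `N x 2` matrix with columns `x`, `y` (mm).
#' @export
draw_sample <- function(pop, N, seed = NULL) {
  stopifnot(inherits(pop, "gaussian_population"), N >= 2)
  with_seed(seed, {
    cbind(x = stats::rnorm(N, pop$mean[1], sqrt(pop$horizontal_variance)),
          y = stats::rnorm(N, pop$mean[2], sqrt(pop$vertical_variance)))
  })
}

# interval bounds in mm for a configuration, width multiple and sigma
interval_bounds <- function(configuration, w, sigma) {
  switch(configuration,
         symmetric = c(-w, w) * sigma,
         upper_half = c(0, w) * sigma,
         lower_half = c(-w, 0) * sigma)
}

#' Simulate an estimation session
#'
#' Generates the 270-trial interval-estimation session (at defaults): per
#' trial a fresh population and sample, the true interval probability, and
#' the agent's estimate.
#'
#' @param config a [session_config()] with `task = "estimation"`.
#' @param agent an [agent_spec()] of kind `llo_estimator`,
#'   `counting_estimator` or `constant`.
#' @return a data frame with columns `trial_id`, `n_points`, `configuration`
#'   (S/SU/SL), `width_multiple`, `true_probability`, `estimate`.
#' @export
simulate_estimation_session <- function(config = session_config("estimation"),
                                        agent) {
  stopifnot(inherits(config, "session_config"), config$task == "estimation",
            inherits(agent, "agent_spec"))
  if (!agent$kind %in% c("llo_estimator", "counting_estimator", "constant"))
    stop2("estimation agents: llo_estimator, counting_estimator, constant")
  confs <- c(S = "symmetric", SU = "upper_half", SL = "lower_half")
  grid <- expand.grid(rep = seq_len(config$repetitions),
                      width = config$widths,
                      conf = names(confs),
                      n = config$sample_sizes,
                      stringsAsFactors = FALSE)
  with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      pop <- gaussian_population(
        vertical_variance = stats::runif(1, 100, 400))
      pts <- draw_sample(pop, g$n)
      p_true <- interval_probability(confs[[g$conf]], g$width)
      est <- switch(agent$kind,
        llo_estimator = {
          q <- agent$llo$gamma * stats::qlogis(max(p_true, 1e-12)) +
            (1 - agent$llo$gamma) * stats::qlogis(agent$llo$p0)
          if (agent$noise_sd > 0) q <- q + stats::rnorm(1, 0, agent$noise_sd)
          e <- stats::plogis(q)
          # a super-additive observer inflates each half estimate by b/2
          if (g$conf != "S") e <- min(max(e + agent$b / 2, 1e-6), 1 - 1e-6)
          e
        },
        counting_estimator = {
          bounds <- interval_bounds(confs[[g$conf]], g$width,
                                    sqrt(pop$vertical_variance))
          mean(pts[, "y"] >= bounds[1] & pts[, "y"] <= bounds[2])
        },
        constant = agent$constant)
      data.frame(trial_id = i, n_points = g$n, configuration = g$conf,
                 width_multiple = g$width, true_probability = p_true,
                 estimate = est)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a decision session
#'
#' Generates the 200-trial decision session (at defaults): per trial the
#' population variance is redrawn, a sample is drawn, the agent's set point
#' is computed (plus Gaussian response noise), one outcome point is drawn
#' from the shifted population, and the realized score follows the reward
#' function.
#'
#' @param config a [session_config()] with `task = "decision"`.
#' @param agent an [agent_spec()] of kind `normative_bdt`, `max_point`,
#'   `mean_tracker` or `constant`.
#' @param prior the [variance_prior()] shared by the generator and the
#'   normative agent.
#' @param boundary_height,reward_max reward-function constants.
#' @param grid_size variance posterior grid size for the normative agent.
#' @return list with `trials` (data frame: `trial_id`, `penalty`, `n_points`,
#'   `sigma2`, `s2`, `p_max`, `mean_y`, `set_point`, `outcome_y`, `score`)
#'   and `points` (long data frame: `trial_id`, `point_index`, `x_mm`,
#'   `y_mm`).
#' @export
simulate_decision_session <- function(config = session_config("decision"),
                                      agent, prior = variance_prior(),
                                      boundary_height = 180,
                                      reward_max = 100, grid_size = 601) {
  stopifnot(inherits(config, "session_config"), config$task == "decision",
            inherits(agent, "agent_spec"))
  if (!agent$kind %in% c("normative_bdt", "max_point", "mean_tracker",
                         "constant"))
    stop2("decision agents: normative_bdt, max_point, mean_tracker, constant")
  grid <- expand.grid(rep = seq_len(config$repetitions),
                      penalty = config$penalties,
                      n = config$sample_sizes)
  boundary_for <- function(penalty) {
    if (is.null(agent$B)) return(NULL)
    if (!is.null(names(agent$B)) && as.character(penalty) %in% names(agent$B))
      unname(agent$B[[as.character(penalty)]])
    else unname(agent$B[[1]])
  }
  with_seed(config$seed, {
    nt <- nrow(grid)
    sigma2 <- stats::runif(nt, prior$lower, prior$upper)
    samples <- lapply(seq_len(nt), function(i)
      draw_sample(gaussian_population(vertical_variance = sigma2[i]),
                  grid$n[i]))
    s2 <- vapply(samples, function(p) stats::var(p[, "y"]), 0)
    p_max <- vapply(samples, function(p) max(p[, "y"]), 0)
    mean_y <- vapply(samples, function(p) mean(p[, "y"]), 0)

    S <- numeric(nt)
    if (agent$kind == "normative_bdt") {
      cond <- interaction(grid$penalty, grid$n, drop = TRUE)
      for (g in levels(cond)) {
        idx <- which(cond == g)
        rw <- reward_function(boundary_height, reward_max,
                              penalty = grid$penalty[idx[1]])
        S[idx] <- batch_optimal_set_point(s2[idx], grid$n[idx[1]], rw,
                                          prior, grid_size)$S
      }
    } else {
      for (i in seq_len(nt)) {
        S[i] <- switch(agent$kind,
          max_point = boundary_for(grid$penalty[i]) - p_max[i],
          mean_tracker = boundary_for(grid$penalty[i]) - mean_y[i],
          constant = agent$constant)
      }
    }
    if (agent$noise_sd > 0) S <- S + stats::rnorm(nt, 0, agent$noise_sd)

    outcome <- stats::rnorm(nt, S, sqrt(sigma2))
    score <- vapply(seq_len(nt), function(i)
      reward_value(outcome[i],
                   reward_function(boundary_height, reward_max,
                                   penalty = grid$penalty[i])), 0)
    trials <- data.frame(trial_id = seq_len(nt), penalty = grid$penalty,
                         n_points = grid$n, sigma2 = sigma2, s2 = s2,
                         p_max = p_max, mean_y = mean_y, set_point = S,
                         outcome_y = outcome, score = score)
    points <- do.call(rbind, lapply(seq_len(nt), function(i)
      data.frame(trial_id = i, point_index = seq_len(nrow(samples[[i]])),
                 x_mm = samples[[i]][, "x"], y_mm = samples[[i]][, "y"])))
    rownames(points) <- NULL
    list(trials = trials, points = points)
  })
}
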