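# CSV schemas, validation, pipeline, and the command-line entry point.

estimation_schema <- c(trial_id = "numeric", n_points = "numeric",
                       configuration = "character",
                       width_multiple = "numeric",
                       true_probability = "numeric", estimate = "numeric")
decision_schema <- c(trial_id = "numeric", penalty = "numeric",
                     n_points = "numeric", set_point = "numeric")
points_schema <- c(trial_id = "numeric", point_index = "numeric",
                   x_mm = "numeric", y_mm = "numeric")

check_schema <- function(df, schema, path) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop2("file '", path, "': missing column(s) ",
          paste(missing, collapse = ", "))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- df[[col]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
        stop2("file '", path, "', column '", col, "': non-numeric value",
              if (length(bad)) paste0(" at row ", bad[1]) else "")
      }
      if (anyNA(v))
        stop2("file '", path, "', column '", col, "': NA at row ",
              which(is.na(v))[1])
    }
  }
  invisible(df)
}

#' Read and validate trial tables
#'
#' `read_estimation_trials()` reads the estimation-trial CSV (columns
#' `trial_id`, `n_points`, `configuration` in S/SU/SL, `width_multiple`,
#' `true_probability`, `estimate`). `read_decision_trials()` reads the
#' decision-trial CSV (`trial_id`, `penalty`, `n_points`, `set_point`, plus
#' any derived columns) and its long companion points table (`trial_id`,
#' `point_index`, `x_mm`, `y_mm`), checks they are consistent, that the
#' sample size is constant within each condition, and derives `s2`, `p_max`
#' and `mean_y` from the points when absent. Errors name the file, row and
#' column at fault.
#'
#' @param path,trials_path,points_path CSV file paths.
#' @return validated data frame(s); `read_decision_trials()` returns a list
#'   with `trials` and `points`.
#' @export
read_estimation_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, estimation_schema, path)
  bad <- which(!df$configuration %in% c("S", "SU", "SL"))
  if (length(bad))
    stop2("file '", path, "', column 'configuration': invalid value at row ",
          bad[1], " (expected S, SU or SL)")
  assert_prob(df$true_probability, "true_probability")
  df
}

#' @rdname read_estimation_trials
#' @export
read_decision_trials <- function(trials_path, points_path) {
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  check_schema(trials, decision_schema, trials_path)
  points <- utils::read.csv(points_path, stringsAsFactors = FALSE)
  check_schema(points, points_schema, points_path)

  counts <- table(points$trial_id)
  got_n <- as.integer(counts[as.character(trials$trial_id)])
  if (anyNA(got_n))
    stop2("file '", points_path, "': no points for trial_id ",
          trials$trial_id[which(is.na(got_n))[1]])
  bad <- which(got_n != trials$n_points)
  if (length(bad))
    stop2("file '", points_path, "': trial_id ", trials$trial_id[bad[1]],
          " has ", got_n[bad[1]], " points but n_points = ",
          trials$n_points[bad[1]])
  cond <- interaction(trials$penalty, trials$n_points, drop = TRUE)
  for (g in levels(cond)) {
    ns <- unique(trials$n_points[cond == g])
    if (length(ns) != 1)
      stop2("file '", trials_path, "': mixed sample sizes within condition ",
            g)
  }
  by_trial <- split(points$y_mm, points$trial_id)
  key <- as.character(trials$trial_id)
  if (is.null(trials$s2))
    trials$s2 <- vapply(by_trial[key], stats::var, 0)
  if (is.null(trials$p_max))
    trials$p_max <- vapply(by_trial[key], max, 0)
  if (is.null(trials$mean_y))
    trials$mean_y <- vapply(by_trial[key], mean, 0)
  list(trials = trials, points = points)
}

#' Write trial tables
#' @param x a data frame (estimation trials) or the list returned by
#'   [simulate_decision_session()].
#' @param path CSV path (estimation) .
#' @param trials_path,points_path CSV paths (decision).
#' @return the path(s), invisibly.
#' @export
write_estimation_trials <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimation_trials
#' @export
write_decision_trials <- function(x, trials_path, points_path) {
  utils::write.csv(x$trials, trials_path, row.names = FALSE)
  utils::write.csv(x$points, points_path, row.names = FALSE)
  invisible(c(trials_path, points_path))
}

## ---- pipeline ------------------------------------------------------------

#' Run the full synthetic-analysis pipeline
#'
#' Simulates an estimation and a decision session for the configured agents,
#' then runs the analyses: LLO fit, additivity fit, empirical and normative
#' influence, model comparison, efficiency, and the two cost scenarios. All
#' randomness derives from `seed` via per-stage child seeds; rerunning with
#' the same configuration is bit-identical. A provenance manifest (seed,
#' config hash, package version, per-stage seeds) is embedded in the report
#' and written alongside the outputs.
#'
#' @param seed master seed.
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @param stages character subset of
#'   `c("estimation", "decision", "influence", "scenario")`.
#' @param estimation_agent,decision_agent [agent_spec()]s for the two
#'   sessions (defaults: the fitted LLO observer and the Max-Point observer).
#' @param n_sims Monte-Carlo replicates for the normative influence stage.
#' @param verbose print one line per stage.
#' @return the report as a nested list (also written as JSON).
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL,
                         stages = c("estimation", "decision", "influence",
                                    "scenario"),
                         estimation_agent = agent_spec(
                           "llo_estimator", llo = llo_params(0.88, 0.76),
                           b = 0.063, noise_sd = 0.2),
                         decision_agent = agent_spec(
                           "max_point", B = c(`0` = 179, `-500` = 168.7),
                           noise_sd = 5),
                         n_sims = 200, verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  config <- strip_classes(list(seed = seed, stages = stages,
                               estimation_agent = estimation_agent,
                               decision_agent = decision_agent,
                               n_sims = n_sims))
  manifest <- list(
    package = "sampleBDT",
    version = as.character(utils::packageVersion("sampleBDT")),
    seed = seed,
    config_hash = {
      h <- fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
      sprintf("fnv1a32:%04x%04x", as.integer(h %/% 65536),
              as.integer(h %% 65536))
    },
    stage_seeds = list())
  report <- list(manifest = manifest)

  decision <- NULL
  if ("estimation" %in% stages) {
    s <- derive_seed(seed, "estimation")
    report$manifest$stage_seeds$estimation <- s
    say("estimation session (seed ", s, ")")
    est <- simulate_estimation_session(
      session_config("estimation", seed = s), estimation_agent)
    sym <- est[est$configuration == "S", ]
    agg <- stats::aggregate(estimate ~ true_probability, sym, mean)
    fit <- fit_llo(agg$true_probability, agg$estimate)
    halves <- est[est$configuration != "S", ]
    mean_by <- function(d) stats::aggregate(
      estimate ~ n_points + width_multiple, d, mean)
    su <- mean_by(est[est$configuration == "SU", ])
    sl <- mean_by(est[est$configuration == "SL", ])
    ss <- mean_by(sym)
    add <- fit_additivity(su$estimate, sl$estimate, ss$estimate)
    report$estimation <- list(
      n_trials = nrow(est),
      llo = list(gamma = fit$params$gamma, p0 = fit$params$p0,
                 sigma = fit$sigma, delta_aicc = fit$delta_aicc,
                 evidence_ratio = fit$evidence_ratio,
                 preferred = fit$preferred),
      additivity = list(b = add$b, hypothesis = add$hypothesis,
                        b_hat = add$b_hat))
    if (!is.null(out_dir))
      write_estimation_trials(est, file.path(out_dir, "estimation_trials.csv"))
  }
  if ("decision" %in% stages) {
    s <- derive_seed(seed, "decision")
    report$manifest$stage_seeds$decision <- s
    say("decision session (seed ", s, ")")
    decision <- simulate_decision_session(
      session_config("decision", seed = s), decision_agent)
    cmp <- compare_models(decision$trials)
    eff <- efficiency(decision$trials)
    mp <- attr(cmp, "max_point_fit")
    report$decision <- list(
      n_trials = nrow(decision$trials),
      comparison = as.data.frame(cmp[, c("model", "log_likelihood", "K",
                                         "aicc", "bic",
                                         "evidence_ratio_vs_best")]),
      max_point_boundaries = as.list(mp$B),
      efficiency = eff)
    if (!is.null(out_dir))
      write_decision_trials(decision,
                            file.path(out_dir, "decision_trials.csv"),
                            file.path(out_dir, "decision_points.csv"))
  }
  if ("influence" %in% stages) {
    s <- derive_seed(seed, "influence")
    report$manifest$stage_seeds$influence <- s
    say("influence (seed ", s, ", n_sims ", n_sims, ")")
    if (is.null(decision))
      decision <- simulate_decision_session(
        session_config("decision", seed = derive_seed(seed, "decision")),
        decision_agent)
    tr <- decision$trials
    pts <- decision$points
    sel <- tr$penalty == min(tr$penalty) & tr$n_points == min(tr$n_points)
    ids <- tr$trial_id[sel]
    pbt <- split(pts$y_mm[pts$trial_id %in% ids], pts$trial_id[pts$trial_id
                                                               %in% ids])
    pbt <- pbt[as.character(ids)]
    emp <- empirical_influence(pbt, tr$set_point[sel], seed = s)
    norm <- normative_influence(min(tr$n_points),
                                reward_function(penalty = min(tr$penalty)),
                                n_sims = n_sims, seed = s)
    rat <- influence_ratio(emp$empirical, norm$normative)
    report$influence <- list(
      n_points = min(tr$n_points), penalty = min(tr$penalty),
      lambda = emp$lambda, empirical = emp$empirical,
      normative = norm$normative, ratio = rat$ratio,
      masked = rat$masked)
  }
  if ("scenario" %in% stages) {
    say("cost scenarios")
    report$scenario <- scenario_report()
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
  }
  report
}

## ---- CLI -----------------------------------------------------------------

# parse "--key value" pairs after the subcommand
parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop2("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop2("missing value for --", key)
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop2("missing required option --", key)
    return(default)
  }
  as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit-llo`, `fit-additivity`, `setpoint`,
#' `influence`, `compare`, `efficiency`, `scenario`, `run-all`. Results are
#' written as JSON to `--out-json` (or stdout). Returns (and, under
#' `Rscript`, exits with) 0 on success, 2 on validation errors, 1 on other
#' failures.
#'
#' @param args character vector of command-line arguments (default: the
#'   actual command line).
#' @return exit status, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop2("usage: <subcommand> [--key value ...]")
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    emit <- function(x) {
      json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE,
                               dataframe = "rows")
      if (!is.null(opts$`out-json`)) writeLines(json, opts$`out-json`)
      else cat(json, "\n")
    }
    switch(cmd,
      "simulate" = {
        task <- opts$task %||% "decision"
        seed <- cli_num(opts, "seed", 1)
        out <- opts$out %||% "."
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        if (task == "decision") {
          agent <- agent_spec("max_point",
                              B = c(`0` = 179, `-500` = 168.7),
                              noise_sd = cli_num(opts, "noise-sd", 5))
          sess <- simulate_decision_session(
            session_config("decision", seed = seed), agent)
          write_decision_trials(sess, file.path(out, "decision_trials.csv"),
                                file.path(out, "decision_points.csv"))
        } else {
          agent <- agent_spec("llo_estimator", llo = llo_params(0.88, 0.76),
                              noise_sd = cli_num(opts, "noise-sd", 0.2))
          write_estimation_trials(
            simulate_estimation_session(
              session_config("estimation", seed = seed), agent),
            file.path(out, "estimation_trials.csv"))
        }
        emit(list(task = task, seed = seed, out = out))
      },
      "fit-llo" = {
        df <- read_estimation_trials(opts$input)
        sym <- df[df$configuration == "S", ]
        agg <- stats::aggregate(estimate ~ true_probability, sym, mean)
        fit <- fit_llo(agg$true_probability, agg$estimate)
        emit(list(gamma = fit$params$gamma, p0 = fit$params$p0,
                  sigma = fit$sigma, delta_aicc = fit$delta_aicc,
                  evidence_ratio = fit$evidence_ratio,
                  preferred = fit$preferred))
      },
      "fit-additivity" = {
        df <- read_estimation_trials(opts$input)
        mean_by <- function(cfg) {
          d <- df[df$configuration == cfg, ]
          stats::aggregate(estimate ~ n_points + width_multiple, d,
                           mean)$estimate
        }
        fit <- fit_additivity(mean_by("SU"), mean_by("SL"), mean_by("S"))
        emit(list(b = fit$b, hypothesis = fit$hypothesis,
                  b_hat = fit$b_hat))
      },
      "setpoint" = {
        s2 <- cli_num(opts, "s2"); n <- cli_num(opts, "n")
        pen <- cli_num(opts, "penalty", 0)
        S <- optimal_set_point(s2, n, reward_function(penalty = pen))
        emit(list(S_star = as.numeric(S),
                  expected_gain = attr(S, "expected_gain")))
      },
      "influence" = {
        dat <- read_decision_trials(opts$trials, opts$points)
        pen <- cli_num(opts, "penalty"); n <- cli_num(opts, "n")
        seed <- cli_num(opts, "seed", 1)
        sel <- dat$trials$penalty == pen & dat$trials$n_points == n
        ids <- dat$trials$trial_id[sel]
        pbt <- split(dat$points$y_mm[dat$points$trial_id %in% ids],
                     dat$points$trial_id[dat$points$trial_id %in% ids])
        pbt <- pbt[as.character(ids)]
        emp <- empirical_influence(pbt, dat$trials$set_point[sel],
                                   seed = seed)
        norm <- normative_influence(n, reward_function(penalty = pen),
                                    n_sims = cli_num(opts, "n-sims", 1000),
                                    seed = seed)
        rat <- influence_ratio(emp$empirical, norm$normative)
        emit(list(lambda = emp$lambda, empirical = emp$empirical,
                  normative = norm$normative, ratio = rat$ratio))
      },
      "compare" = {
        dat <- read_decision_trials(opts$trials, opts$points)
        emit(as.data.frame(compare_models(dat$trials)))
      },
      "efficiency" = {
        dat <- read_decision_trials(opts$trials, opts$points)
        if (is.null(dat$trials$score))
          stop2("efficiency needs a 'score' column in the trials CSV")
        emit(list(efficiency = efficiency(dat$trials)))
      },
      "scenario" = {
        rep <- if (!is.null(opts$config)) {
          sc <- read_scenario(opts$config)
          if (inherits(sc, "disc_scenario")) list(disc = optimal_aim(sc))
          else list(rect = list(
            double_probability = double_target_probability(sc)))
        } else scenario_report()
        emit(rep)
      },
      "run-all" = {
        rep <- run_pipeline(seed = cli_num(opts, "seed", 1),
                            out_dir = opts$out %||% ".")
        emit(rep$manifest)
      },
      stop2("unknown subcommand: ", cmd))
    0L
  },
  validation_error = function(e) 2L,
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("file '|missing column|usage:|unknown subcommand|missing",
              conditionMessage(e))) 2L else 1L
  })
  if (!interactive() && identical(Sys.getenv("SAMPLEBDT_CLI_EXIT"), "1"))
    quit(status = status, save = "no")
  invisible(status)
}
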