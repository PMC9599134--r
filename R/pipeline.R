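## Pipeline orchestration ----------------------------------------------------
##
## simulate -> process -> analyze as a configured, logged, reproducible run.
## The config round-trips through YAML; every stage writes its outputs and a
## manifest (seed, counts, file hashes) under the run's output directory.

#' Default run configuration
#'
#' @param experiment Experiment id (1, 2 or 3).
#' @param seed Master seed of the run.
#' @param out_dir Output directory.
#' @param n_per_group Named group sizes; defaults to the reference cohort
#'   sizes of the chosen design ([study_cohort_sizes()]).
#' @param params_override Named list of [sim_params()] overrides.
#' @param W Learning window in cycles.
#' @param recompute_window Recompute W from the data via
#'   [find_learning_window()] instead of using the fixed default.
#' @param exclude_flagged Drop too-slow/too-fast trials from cycle means.
#' @param epsilon Denominator guard (deg) of the gradual learning rate.
#' @param trajectories Simulate/process sample-level trajectories (TRUE) or
#'   run state-level only (FALSE).
#' @param n_boot Bootstrap resamples for the decay fit.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = 1, seed = 1L, out_dir = tempfile("run"),
                       n_per_group = NULL, params_override = list(),
                       W = 9, recompute_window = FALSE,
                       exclude_flagged = FALSE, epsilon = 0.5,
                       trajectories = TRUE, n_boot = 1000) {
  experiment <- check_experiment(experiment)
  if (is.null(n_per_group)) {
    n_per_group <- study_cohort_sizes()[[paste0("exp", experiment)]]
  }
  cfg <- list(experiment = experiment, seed = as.integer(seed),
              out_dir = out_dir, n_per_group = as.list(n_per_group),
              params_override = params_override, W = W,
              recompute_window = recompute_window,
              exclude_flagged = exclude_flagged, epsilon = epsilon,
              trajectories = trajectories, n_boot = n_boot)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("experiment", "seed")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("config lacks required field(s): ",
                         paste(miss, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_params <- function(cfg) do.call(sim_params, cfg$params_override)

manifest_write <- function(cfg, stage, paths) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  mf <- list(stage = stage, seed = cfg$seed, experiment = cfg$experiment,
             time = format(Sys.time(), tz = "UTC"),
             files = lapply(paths, function(p)
               list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(mf, file.path(cfg$out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline stage: simulate a cohort
#'
#' Builds the design, simulates the configured cohort and writes
#' `trials.csv` (and `samples.csv` when trajectories are on) plus a
#' manifest with file hashes.
#'
#' @param cfg A [run_config()].
#' @return List of written paths, invisibly reused by later stages.
#' @export
cmd_simulate <- function(cfg) {
  design <- build_design(cfg$experiment, seed = cfg$seed)
  sim <- simulate_cohort(design, cfg_params(cfg),
                         n_per_group = unlist(cfg$n_per_group),
                         seed = cfg$seed, trajectories = cfg$trajectories,
                         out_dir = cfg$out_dir)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  manifest_write(cfg, "simulate", sim$paths)
  message(sprintf("simulated %d participants, %d trials%s",
                  length(unique(sim$trials$participant)), nrow(sim$trials),
                  if (cfg$trajectories) sprintf(", %d samples", nrow(sim$samples)) else ""))
  invisible(sim$paths)
}

read_required_csv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop(path, " lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Pipeline stage: process raw trajectories
#'
#' Reads the trial-metadata and trajectory CSVs, extracts per-trial
#' kinematics and writes `kinematics.csv`, `cycles.csv` and an
#' invalid-trial log.
#'
#' @param cfg A [run_config()].
#' @param trials_csv,samples_csv Input paths (default: the simulate-stage
#'   outputs in `cfg$out_dir`).
#' @return List of written paths.
#' @export
cmd_process <- function(cfg,
                        trials_csv = file.path(cfg$out_dir, "trials.csv"),
                        samples_csv = file.path(cfg$out_dir, "samples.csv")) {
  trials <- read_required_csv(trials_csv,
    c("participant", "group", "day", "phase", "cycle", "trial_in_cycle",
      "trial_global", "target_deg", "condition", "perturbation_deg"))
  samples <- read_required_csv(samples_csv,
    c("participant", "trial_global", "t_ms", "x_cm", "y_cm"))
  kin <- process_trajectories(samples, trials)
  cycles <- cycle_average(kin, exclude_flagged = cfg$exclude_flagged)
  paths <- list(kinematics = file.path(cfg$out_dir, "kinematics.csv"),
                cycles = file.path(cfg$out_dir, "cycles.csv"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(kin, paths$kinematics)
  readr::write_csv(cycles, paths$cycles)
  bad <- kin[!kin$valid, c("participant", "trial_global", "invalid_reason")]
  if (nrow(bad)) {
    paths$invalid <- file.path(cfg$out_dir, "invalid_trials.csv")
    readr::write_csv(bad, paths$invalid)
  }
  manifest_write(cfg, "process", paths)
  message(sprintf("processed %d trials (%d invalid)", nrow(kin), nrow(bad)))
  invisible(paths)
}

#' Pipeline stage: metrics, decay fits, group report
#'
#' Aggregates kinematics into adaptation summaries, bootstraps the decay
#' rate per group and day, runs the group comparisons and writes
#' `summary.csv`, `decay.json`, `report.csv`, `report.txt` and a cycle-series
#' figure.
#'
#' @param cfg A [run_config()].
#' @param kinematics_csv Input path (default: the process-stage output).
#' @return List with `summaries`, `report`, `decay_fits` and written paths.
#' @export
cmd_analyze <- function(cfg,
                        kinematics_csv = file.path(cfg$out_dir, "kinematics.csv")) {
  kin <- read_required_csv(kinematics_csv,
    c("participant", "group", "day", "phase", "cycle", "cycle_in_phase",
      "ad_deg", "rt_ms", "valid", "too_slow", "too_fast", "perturbation_deg"))
  groups <- unique(kin$group)
  if (!length(groups) || any(!nzchar(groups))) stop("no group labels in input")

  W <- cfg$W
  res <- summarize_adaptation(kin, W = W, epsilon = cfg$epsilon,
                              exclude_flagged = cfg$exclude_flagged)
  if (cfg$recompute_window && !res$gradual) {
    lw <- find_learning_window(res$cycles)
    W <- lw$W
    message("recomputed learning window: W = ", W,
            " (stops: ", paste(lw$stops, collapse = ", "), ")")
    res <- summarize_adaptation(kin, W = W, epsilon = cfg$epsilon,
                                exclude_flagged = cfg$exclude_flagged)
  }

  days <- sort(unique(res$cycles$day))
  decay_fits <- list()
  for (d in days) {
    lab <- if (d == 1) "Decay rate (95% CI)" else sprintf("Decay rate day %d (95%% CI)", d)
    fits <- lapply(stats::setNames(groups, groups), function(g)
      bootstrap_decay(decay_matrix(res$cycles, day = d, group = g),
                      n_boot = cfg$n_boot, seed = cfg$seed + d))
    decay_fits[[lab]] <- fits
  }

  report <- build_report(res$summary, decay_fits = decay_fits,
                         gradual = res$gradual)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(summary = file.path(cfg$out_dir, "summary.csv"),
                report_csv = file.path(cfg$out_dir, "report.csv"),
                report_txt = file.path(cfg$out_dir, "report.txt"),
                decay_json = file.path(cfg$out_dir, "decay.json"))
  readr::write_csv(res$summary, paths$summary)
  readr::write_csv(report, paths$report_csv)
  writeLines(format_report(report, print = FALSE), paths$report_txt)
  jsonlite::write_json(
    lapply(decay_fits, function(fits) lapply(fits, function(f)
      list(a_hat = f$a_hat, ci = f$ci, n_boot = f$n_boot, seed = f$seed))),
    paths$decay_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fig <- plot_cycle_series(res$cycles)
  paths$figure <- file.path(cfg$out_dir, "cycles.png")
  ggplot2::ggsave(paths$figure, fig, width = 9, height = 4 * length(days),
                  dpi = 120)
  manifest_write(cfg, "analyze", paths)
  invisible(list(summaries = res, report = report, decay_fits = decay_fits,
                 paths = paths))
}

#' Run the full pipeline
#'
#' simulate, process (when trajectories are enabled) and analyze in one
#' call.
#'
#' @param cfg A [run_config()].
#' @return The [cmd_analyze()] result, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cmd_simulate(cfg)
  if (cfg$trajectories) {
    cmd_process(cfg)
    out <- cmd_analyze(cfg)
  } else {
    ## state-level run: the simulated trial table doubles as kinematics
    trials <- readr::read_csv(file.path(cfg$out_dir, "trials.csv"),
                              show_col_types = FALSE, progress = FALSE)
    readr::write_csv(trials, file.path(cfg$out_dir, "kinematics.csv"))
    out <- cmd_analyze(cfg)
  }
  invisible(out)
}

#' Group-mean cycle series figure
#'
#' Group mean +- standard error of the corrected angular deviation per
#' cycle, faceted by day, with phase boundaries marked. Advisory output;
#' numbers are never read back from figures.
#'
#' @param cycles_corr Baseline-corrected cycle series.
#' @return A ggplot object.
#' @export
plot_cycle_series <- function(cycles_corr) {
  agg <- dplyr::summarise(
    dplyr::group_by(cycles_corr, .data$group, .data$day, .data$cycle),
    m = mean(.data$ad_corr, na.rm = TRUE),
    se = sd(.data$ad_corr, na.rm = TRUE) / sqrt(sum(is.finite(.data$ad_corr))),
    .groups = "drop")
  bounds <- dplyr::summarise(
    dplyr::group_by(cycles_corr, .data$day, .data$phase),
    start = min(.data$cycle), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$cycle, y = .data$m,
                                    colour = .data$group, fill = .data$group)) +
    ggplot2::geom_vline(data = bounds, ggplot2::aes(xintercept = .data$start - 0.5),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$day, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial cycle", y = "angular deviation (deg, corrected)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}
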