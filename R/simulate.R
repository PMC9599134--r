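## Synthetic cohorts ---------------------------------------------------------
##
## The generator is a stand-in for real participants: a single-rate
## state-space learner with a soft saturation of clamp-driven drift, plus
## per-participant baseline direction bias, per-trial motor noise, a simple
## reaction/movement-time model and minimum-jerk pen trajectories sampled at
## 125 Hz. Its parameters are free simulation knobs, not estimates of any
## real cohort.

#' Simulation parameters
#'
#' Constructs and validates the parameter set of the synthetic cohort
#' generator.
#'
#' The hidden implicit state `u` (degrees, clockwise-positive compensation)
#' evolves per trial:
#' * error-clamp trials: `u <- A * u + B * theta * max(0, 1 - u / U)` where
#'   `theta` is the clamp angle and `U = clamp_asymptote_deg`, so the drift
#'   saturates near `U`;
#' * rotation trials: `u <- A * u + B * (r - u - s)` where `r` is that
#'   trial's rotation and `s` the explicit strategy (abrupt re-adaptation
#'   only); veridical trials are the `r = 0` case;
#' * no-feedback trials: `u <- A * u`.
#'
#' The produced hand direction is `target - u - s - bias - noise` (so the
#' measured angular deviation, positive clockwise, equals
#' `u + s + bias + noise`).
#'
#' @param A_retain Per-trial retention factor, in (0, 1].
#' @param B_learn Per-trial error sensitivity, in [0, 1).
#' @param clamp_asymptote_deg Saturation level of clamp-driven drift (deg).
#' @param motor_noise_sd_deg SD of per-trial direction noise (deg).
#' @param baseline_bias_sd_deg Between-participant SD of the constant
#'   direction bias (deg).
#' @param rt_base_ms,rt_noise_ms Mean and SD of trial reaction time (ms).
#' @param rt_jump_ms Reaction-time increase at the onset of an abrupt
#'   rotation, decaying over cycles with time constant `rt_jump_tau_cycles`.
#' @param rt_jump_tau_cycles Decay constant (cycles) of the RT jump.
#' @param explicit_gain Fraction of an abrupt rotation countered by explicit
#'   strategy (day-2 re-adaptation), in [0, 1].
#' @param explicit_ramp_cycles Cycles over which the strategy ramps in.
#' @param mt_mean_ms,mt_noise_ms Mean and SD of movement duration (ms).
#' @param sample_rate_hz Trajectory sampling rate; fixed at 125.
#' @param sample_jitter_cm Per-sample positional jitter SD (cm), so that
#'   low-pass filtering is non-trivial.
#' @param reach_dist_cm Total reach amplitude (cm); must exceed the 5 cm
#'   target ring.
#' @param overnight_retention Multiplicative retention of the state across
#'   days, in [0, 1] (1 = no overnight forgetting).
#' @param group_effect_deg Additive increase of the perturbation drive for
#'   one designated group; used for power/recovery studies, 0 for null
#'   cohorts.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(A_retain = 0.995,
                       B_learn = 0.02,
                       clamp_asymptote_deg = 20,
                       motor_noise_sd_deg = 3.5,
                       baseline_bias_sd_deg = 2,
                       rt_base_ms = 350,
                       rt_noise_ms = 40,
                       rt_jump_ms = 150,
                       rt_jump_tau_cycles = 5,
                       explicit_gain = 0.5,
                       explicit_ramp_cycles = 3,
                       mt_mean_ms = 450,
                       mt_noise_ms = 30,
                       sample_rate_hz = 125,
                       sample_jitter_cm = 0.02,
                       reach_dist_cm = 8,
                       overnight_retention = 1,
                       group_effect_deg = 0) {
  p <- as.list(environment())
  if (!(p$A_retain > 0 && p$A_retain <= 1)) stop("A_retain must be in (0, 1]")
  if (!(p$B_learn >= 0 && p$B_learn < 1)) stop("B_learn must be in [0, 1)")
  if (p$sample_rate_hz != 125) stop("sample_rate_hz is fixed at 125")
  sds <- c(p$motor_noise_sd_deg, p$baseline_bias_sd_deg, p$rt_noise_ms,
           p$mt_noise_ms, p$sample_jitter_cm)
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  if (!(p$explicit_gain >= 0 && p$explicit_gain <= 1)) {
    stop("explicit_gain must be in [0, 1]")
  }
  if (p$clamp_asymptote_deg <= 0) stop("clamp_asymptote_deg must be > 0")
  if (p$reach_dist_cm <= 5) stop("reach_dist_cm must exceed the 5 cm ring")
  if (!(p$overnight_retention >= 0 && p$overnight_retention <= 1)) {
    stop("overnight_retention must be in [0, 1]")
  }
  structure(p, class = "sim_params")
}

#' Simulate one participant through a design
#'
#' Runs the state-space learner over every trial of `design` and (optionally)
#' synthesizes 125 Hz pen trajectories for each trial. Fully reproducible
#' from `seed`.
#'
#' @param design An `experiment_design` from [build_design()].
#' @param params A [sim_params()] object.
#' @param participant Participant identifier (character).
#' @param group Group label (e.g. "anodal", "sham"); metadata only unless
#'   `apply_effect` is TRUE.
#' @param seed Integer seed for this participant.
#' @param trajectories If TRUE, also return sample-level trajectories.
#' @param apply_effect If TRUE, add `params$group_effect_deg` to the
#'   perturbation drive of this participant (power/recovery studies).
#' @return A list with `trials` (trial table plus simulated columns:
#'   `state_deg`, `strategy_deg`, `bias_deg`, `ad_true_deg`, `ad_deg`,
#'   `hand_dir_deg`, `rt_ms`, `mt_ms`) and `samples` (tibble
#'   `participant, trial_global, t_ms, x_cm, y_cm`, or NULL).
#' @export
simulate_participant <- function(design, params = sim_params(),
                                 participant = "P01", group = "sham",
                                 seed = 1L, trajectories = TRUE,
                                 apply_effect = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  if (!inherits(params, "sim_params")) stop("`params` must come from sim_params()")
  tt <- trial_table(design)
  n <- nrow(tt)
  set.seed(as.integer(seed))

  bias <- rnorm(1, 0, params$baseline_bias_sd_deg)
  noise <- rnorm(n, 0, params$motor_noise_sd_deg)
  rt_noise <- rnorm(n, 0, params$rt_noise_ms)
  mt_noise <- rnorm(n, 0, params$mt_noise_ms)

  eff <- if (apply_effect) params$group_effect_deg else 0
  day_v <- tt$day
  cond_v <- tt$condition
  pert_v <- tt$perturbation_deg
  cip_v <- tt$cycle_in_phase
  readapt <- cond_v == "rotation" & tt$phase == "re-adaptation"
  A <- params$A_retain
  B <- params$B_learn
  U <- params$clamp_asymptote_deg

  ## strategy and timing are trial-local; only the state needs the loop
  strategy <- ifelse(readapt,
                     params$explicit_gain * pert_v *
                       pmin(1, cip_v / params$explicit_ramp_cycles), 0)
  rt <- pmax(150, params$rt_base_ms + rt_noise) +
    ifelse(readapt,
           params$rt_jump_ms * exp(-(cip_v - 1) / params$rt_jump_tau_cycles), 0)
  mt <- pmax(200, params$mt_mean_ms + mt_noise)

  u <- 0
  state <- numeric(n)
  day_prev <- day_v[1]
  for (i in seq_len(n)) {
    if (day_v[i] != day_prev) {
      u <- params$overnight_retention * u
      day_prev <- day_v[i]
    }
    state[i] <- u
    cond <- cond_v[i]
    u <- if (cond == "clamp") {
      A * u + B * (pert_v[i] + eff) * max(0, 1 - u / U)
    } else if (cond == "rotation") {
      A * u + B * ((pert_v[i] + eff) - u - strategy[i])
    } else if (cond == "veridical") {
      A * u - B * u
    } else {
      A * u
    }
  }

  ad_true <- state + strategy + bias
  ad <- ad_true + noise
  trials <- tt
  trials$participant <- participant
  trials$group <- group
  trials$state_deg <- state
  trials$strategy_deg <- strategy
  trials$bias_deg <- bias
  trials$ad_true_deg <- ad_true
  trials$ad_deg <- ad
  trials$hand_dir_deg <- wrap180(tt$target_deg - ad)
  trials$rt_ms <- rt
  trials$mt_ms <- mt
  ## make the state-level output directly usable as a kinematics table
  trials$valid <- TRUE
  trials$too_slow <- FALSE
  trials$too_fast <- FALSE
  trials <- trials[, c("participant", "group", setdiff(names(trials),
                                                       c("participant", "group")))]

  samples <- NULL
  if (trajectories) {
    samples <- synth_trajectories(trials, params)
  }
  list(trials = trials, samples = samples)
}

## Minimum-jerk radial position profile on normalized time in [0, 1].
minjerk_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Synthesize 125 Hz trajectories for simulated trials
#'
#' Each trial is a hold at the start position for the trial's reaction time,
#' a straight minimum-jerk reach of `reach_dist_cm` along the trial's hand
#' direction lasting its movement time, then a hold at the endpoint until
#' 0.5 s past the reach end; all sampled every 8 ms with optional per-sample
#' positional jitter.
#'
#' @param trials Trial table from [simulate_participant()] (needs
#'   `participant`, `trial_global`, `hand_dir_deg`, `rt_ms`, `mt_ms`).
#' @param params A [sim_params()] object.
#' @return Tibble `participant, trial_global, t_ms, x_cm, y_cm`; `t_ms` is 0
#'   at target appearance.
#' @export
synth_trajectories <- function(trials, params = sim_params()) {
  dt <- 1000 / params$sample_rate_hz
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    rt <- trials$rt_ms[i]
    mt <- trials$mt_ms[i]
    t_ms <- seq(0, rt + mt + 500, by = dt)
    r <- params$reach_dist_cm * minjerk_pos((t_ms - rt) / mt)
    dir <- trials$hand_dir_deg[i] * pi / 180
    x <- r * cos(dir)
    y <- r * sin(dir)
    if (params$sample_jitter_cm > 0) {
      x <- x + rnorm(length(x), 0, params$sample_jitter_cm)
      y <- y + rnorm(length(y), 0, params$sample_jitter_cm)
    }
    out[[i]] <- tibble::tibble(
      participant = trials$participant[i],
      trial_global = trials$trial_global[i],
      t_ms = t_ms, x_cm = x, y_cm = y
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate a cohort of participants
#'
#' Derives independent per-participant seeds from the master seed, simulates
#' each participant through the design and optionally writes the combined
#' trial-metadata and trajectory CSVs.
#'
#' @param design An `experiment_design`.
#' @param params A [sim_params()] object.
#' @param n_per_group Named integer vector of group sizes, e.g.
#'   `c(anodal = 41, sham = 41)`.
#' @param seed Master integer seed.
#' @param trajectories If TRUE, generate sample-level trajectories.
#' @param effect_group Optional name of the group whose perturbation drive is
#'   increased by `params$group_effect_deg`.
#' @param out_dir Optional directory; if given, writes `trials.csv` and (with
#'   trajectories) `samples.csv` there.
#' @return A list with `trials`, `samples` (or NULL) and `paths`.
#' @export
simulate_cohort <- function(design, params = sim_params(), n_per_group,
                            seed = 1L, trajectories = FALSE,
                            effect_group = NULL, out_dir = NULL) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("`n_per_group` must be a named vector of group sizes")
  }
  if (any(n_per_group < 1)) stop("each group needs at least 1 participant")
  if (!is.null(effect_group) && !effect_group %in% names(n_per_group)) {
    stop("`effect_group` must be one of: ", paste(names(n_per_group), collapse = ", "))
  }
  total <- sum(n_per_group)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, total)

  trials <- vector("list", total)
  samples <- vector("list", total)
  k <- 0L
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      k <- k + 1L
      pp <- sprintf("%s_%02d", g, i)
      sim <- simulate_participant(design, params, participant = pp, group = g,
                                  seed = seeds[k], trajectories = trajectories,
                                  apply_effect = identical(g, effect_group))
      trials[[k]] <- sim$trials
      samples[[k]] <- sim$samples
    }
  }
  trials <- dplyr::bind_rows(trials)
  samples <- if (trajectories) dplyr::bind_rows(samples) else NULL

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$trials <- file.path(out_dir, "trials.csv")
    readr::write_csv(trials, paths$trials)
    if (trajectories) {
      paths$samples <- file.path(out_dir, "samples.csv")
      readr::write_csv(samples, paths$samples)
    }
  }
  list(trials = trials, samples = samples, paths = paths)
}
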