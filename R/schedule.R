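## Experiment schedules ------------------------------------------------------
##
## The three study designs share a common shape: each day has a baseline,
## an (re-)adaptation and a decay phase; trials are organized in cycles,
## one movement to each target per cycle, target order randomized within
## the cycle. Perturbations are counterclockwise (CCW positive, degrees).

GRADUAL_RAMP_TRIALS <- 320L
GRADUAL_RAMP_END_DEG <- 30

#' Target layout for an experiment
#'
#' Experiments 1 and 3 use eight targets every 45 degrees starting at 0
#' (laterally right); Experiment 2 uses the four diagonal targets. Targets
#' sit on an invisible ring of 5 cm radius around the start position.
#'
#' @param experiment Integer, 1, 2 or 3.
#' @return A list with `angles_deg` (ordered target directions, degrees CCW
#'   from laterally right) and `radius_cm`.
#' @export
target_layout <- function(experiment) {
  experiment <- check_experiment(experiment)
  angles <- if (experiment == 2L) c(45, 135, 225, 315) else seq(0, 315, by = 45)
  list(angles_deg = angles, radius_cm = 5)
}

check_experiment <- function(experiment) {
  if (length(experiment) != 1L || !experiment %in% 1:3) {
    stop("`experiment` must be 1, 2 or 3, got: ", paste(experiment, collapse = ", "),
         call. = FALSE)
  }
  as.integer(experiment)
}

#' Rotation magnitude on a trial of the gradual ramp
#'
#' In the gradual design the 30 degree rotation is imposed in equal per-trial
#' increments over 40 cycles (320 trials), i.e. 0.09375 degrees per trial
#' (printed as 0.0938). The rotation applied on trial `trial` (1-based within
#' the ramp) is `trial * 30/320`, reaching exactly 30 on the final trial.
#'
#' @param trial Integer vector, 1-based trial index within the gradual
#'   adaptation phase (1..320).
#' @return Rotation in degrees (CCW positive) applied on those trials.
#' @examples
#' gradual_rotation_at(1)    # 0.09375
#' gradual_rotation_at(160)  # 15
#' gradual_rotation_at(320)  # 30
#' @export
gradual_rotation_at <- function(trial) {
  if (any(trial < 1 | trial > GRADUAL_RAMP_TRIALS) || any(trial != round(trial))) {
    stop("`trial` must be an integer in 1..", GRADUAL_RAMP_TRIALS, call. = FALSE)
  }
  trial * (GRADUAL_RAMP_END_DEG / GRADUAL_RAMP_TRIALS)
}

phase_spec <- function(name, n_cycles, condition, perturbation_by_cycle = NULL,
                       gradual = FALSE, clamp_angle = NA_real_) {
  stopifnot(n_cycles > 0)
  list(name = name, n_cycles = as.integer(n_cycles), condition = condition,
       perturbation_by_cycle = perturbation_by_cycle, gradual = gradual,
       clamp_angle = clamp_angle)
}

day_phases <- function(experiment, day) {
  if (experiment == 1L && day == 1L) {
    list(
      phase_spec("baseline", 15L, c(rep("veridical", 5), rep("none", 10))),
      phase_spec("adaptation", 40L, "clamp", clamp_angle = 30),
      phase_spec("decay", 40L, "none")
    )
  } else if (experiment == 2L) {
    list(
      phase_spec("baseline", 40L, c(rep("veridical", 30), rep("none", 10))),
      phase_spec("adaptation", 80L, "clamp", clamp_angle = 4),
      phase_spec("decay", 80L, "none")
    )
  } else if (experiment == 3L && day == 1L) {
    list(
      phase_spec("baseline", 20L, "veridical"),
      phase_spec("adaptation", 40L, "rotation", gradual = TRUE),
      phase_spec("decay", 40L, "none")
    )
  } else {
    ## day 2 of experiments 1 and 3: abrupt task-relevant 30 degree rotation
    list(
      phase_spec("baseline", 15L, c(rep("veridical", 5), rep("none", 10))),
      phase_spec("re-adaptation", 40L, "rotation", clamp_angle = 30),
      phase_spec("decay", 40L, "none")
    )
  }
}

#' Build the full trial-by-trial design of an experiment
#'
#' Enumerates every trial of the chosen design: phases and their cycle
#' counts, per-cycle feedback condition, per-trial perturbation magnitude,
#' and a seeded random target order within each cycle.
#'
#' Designs:
#' * Experiment 1 (two days): baseline 15 cycles (5 veridical + 10
#'   no-feedback), error-clamp adaptation at 30 degrees CCW for 40 cycles,
#'   no-feedback decay 40 cycles; 95 cycles / 760 trials per day. Day 2
#'   replaces the clamp with an abrupt task-relevant 30 degree rotation
#'   (re-adaptation).
#' * Experiment 2 (one day, 4 targets): baseline 40 (30 veridical + 10
#'   no-feedback), 4 degree error clamp for 80 cycles, decay 80; 200 cycles.
#' * Experiment 3 (two days): baseline 20 veridical, gradual rotation ramp
#'   0 to 30 degrees over 40 cycles (320 trials, 0.09375 degrees/trial),
#'   decay 40; day 2 identical to Experiment 1 day 2.
#'
#' Cerebellar stimulation timing is carried as metadata only (`stim`):
#' 20 min starting at cycle 11 (Experiments 1 and 3) or cycle 31
#' (Experiment 2), i.e. at the no-feedback tail of the baseline.
#'
#' @param experiment Integer, 1, 2 or 3.
#' @param seed Integer seed for the within-cycle target permutations.
#' @return An object of class `experiment_design`: a list with `experiment`,
#'   `layout`, `trials_per_cycle`, `days` (phase specs per day), `stim`,
#'   `seed` and `trials`, the fully enumerated trial table (see
#'   [trial_table()]).
#' @examples
#' d <- build_design(1, seed = 42)
#' design_totals(d)
#' @export
build_design <- function(experiment, seed = 1L) {
  experiment <- check_experiment(experiment)
  layout <- target_layout(experiment)
  n_days <- if (experiment == 2L) 1L else 2L
  days <- lapply(seq_len(n_days), function(d) day_phases(experiment, d))
  tpc <- length(layout$angles_deg)

  set.seed(as.integer(seed))
  rows <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    phases <- days[[d]]
    cyc0 <- 0L
    prows <- vector("list", length(phases))
    for (pi in seq_along(phases)) {
      ph <- phases[[pi]]
      cond <- rep(ph$condition, length.out = ph$n_cycles)
      tg <- unlist(lapply(seq_len(ph$n_cycles),
                          function(i) sample(layout$angles_deg)))
      cyc_in_phase <- rep(seq_len(ph$n_cycles), each = tpc)
      tr_in_phase <- seq_len(ph$n_cycles * tpc)
      pert <- if (ph$gradual) {
        gradual_rotation_at(tr_in_phase)
      } else if (ph$condition[1] %in% c("clamp", "rotation")) {
        rep(ph$clamp_angle, length(tr_in_phase))
      } else {
        rep(0, length(tr_in_phase))
      }
      prows[[pi]] <- tibble::tibble(
        day = d,
        phase = ph$name,
        cycle = cyc0 + cyc_in_phase,
        cycle_in_phase = cyc_in_phase,
        trial_in_cycle = rep(seq_len(tpc), times = ph$n_cycles),
        target_deg = tg,
        condition = rep(cond, each = tpc),
        perturbation_deg = pert
      )
      cyc0 <- cyc0 + ph$n_cycles
    }
    rows[[d]] <- dplyr::bind_rows(prows)
  }
  trials <- dplyr::bind_rows(rows)
  trials$trial_global <- seq_len(nrow(trials))
  trials <- trials[, c("day", "phase", "cycle", "cycle_in_phase",
                       "trial_in_cycle", "trial_global", "target_deg",
                       "condition", "perturbation_deg")]

  structure(
    list(experiment = experiment, layout = layout, trials_per_cycle = tpc,
         days = days, seed = as.integer(seed),
         stim = list(start_cycle = if (experiment == 2L) 31L else 11L,
                     duration_min = 20),
         trials = trials),
    class = "experiment_design"
  )
}

#' Flatten a design to its trial metadata table
#'
#' One row per trial with day, phase, 1-based cycle index (within day and
#' within phase), trial-in-cycle, global trial index, target angle, feedback
#' condition and perturbation magnitude. The table round-trips losslessly
#' through [readr::write_csv()] / [readr::read_csv()].
#'
#' @param design An `experiment_design` from [build_design()].
#' @return A tibble with one row per trial.
#' @export
trial_table <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  design$trials
}

#' Cycle and trial totals of a design
#'
#' @param design An `experiment_design`.
#' @return A tibble with per-day cycle and trial counts.
#' @export
design_totals <- function(design) {
  tt <- trial_table(design)
  dplyr::summarise(dplyr::group_by(tt, .data$day),
                   cycles = max(.data$cycle),
                   trials = dplyr::n(), .groups = "drop")
}

#' @export
print.experiment_design <- function(x, ...) {
  tot <- design_totals(x)
  cat(sprintf("Experiment %d design: %d target(s) at %s deg, %d trials/cycle\n",
              x$experiment, length(x$layout$angles_deg),
              paste(x$layout$angles_deg, collapse = ", "), x$trials_per_cycle))
  for (d in seq_len(nrow(tot))) {
    cat(sprintf("  day %d: %d cycles, %d trials (%s)\n", tot$day[d],
                tot$cycles[d], tot$trials[d],
                paste(vapply(x$days[[d]], function(p)
                  sprintf("%s %d", p$name, p$n_cycles), ""), collapse = " / ")))
  }
  invisible(x)
}

#' Published per-session cycle bookkeeping of the three designs
#'
#' The protocol descriptions summarize each session as a cycle count and the
#' matching trial total (cycles x trials-per-cycle): 95 cycles / 760 trials
#' per day (Experiment 1), 200 cycles / 800 trials (Experiment 2) and 110
#' cycles / 880 trials (Experiment 3). The trial totals are recomputed here
#' from the cycle counts and target layouts. Note that for the gradual
#' design the published 110-cycle session count is not equal to the sum of
#' its enumerated day-1 phases (20 + 40 + 40 = 100); the enumerated design
#' keeps the per-phase counts and this table carries the published summary
#' arithmetic (see the methods vignette).
#'
#' @return Tibble with `experiment`, `published_cycles`, `trials_per_cycle`,
#'   `published_trials`.
#' @export
published_bookkeeping <- function() {
  cycles <- c(95L, 200L, 110L)
  tpc <- vapply(1:3, function(e) length(target_layout(e)$angles_deg), 1L)
  tibble::tibble(experiment = 1:3, published_cycles = cycles,
                 trials_per_cycle = tpc,
                 published_trials = cycles * tpc)
}

#' Reference cohort sizes of the three study designs
#'
#' Group sizes of the cohorts the designs were run with: 41 anodal + 41 sham
#' (Experiment 1), 14 anodal + 14 cathodal + 10 sham (Experiment 2) and
#' 27 anodal + 27 sham (Experiment 3), 174 participants in total. Useful as
#' defaults for cohort simulation and for bookkeeping checks.
#'
#' @return A named list of named integer vectors, one per experiment.
#' @export
study_cohort_sizes <- function() {
  list(
    exp1 = c(anodal = 41L, sham = 41L),
    exp2 = c(anodal = 14L, cathodal = 14L, sham = 10L),
    exp3 = c(anodal = 27L, sham = 27L)
  )
}
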