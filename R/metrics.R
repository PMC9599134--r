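## Adaptation metrics --------------------------------------------------------
##
## Per-trial angular deviations are averaged within trial cycles, corrected
## for each participant's baseline direction bias (mean of the last five
## baseline cycles of the day), and summarized into the standard adaptation
## measures: initial rate (mean over the first W cycles, default W = 9),
## extent (mean over the last 10 cycles of the learning phase), aftereffect
## (first decay cycle), decay residue (last 10 decay cycles), cross-day
## retention (first day-2 cycle, corrected with the day-1 bias), trial-wise
## learning rate for gradual ramps, and reaction-time change.

#' Cycle-averaged angular deviation and reaction time
#'
#' Averages the per-trial measures of a processed kinematics table within
#' trial cycles. Cycles without a single valid trial get a missing mean
#' (never an imputed 0).
#'
#' @param kin Kinematics table carrying trial metadata (`participant`,
#'   `group`, `day`, `phase`, `cycle`, `cycle_in_phase`) and measures
#'   (`ad_deg`, `rt_ms`, `valid`, `too_slow`, `too_fast`). Both
#'   [process_trajectories()] output and the state-level
#'   [simulate_participant()] trial table qualify.
#' @param exclude_flagged If TRUE, drop too-slow/too-fast trials from the
#'   cycle means (by default they are retained).
#' @return Tibble with one row per (participant, day, cycle): `mean_ad`,
#'   `mean_rt`, `n_valid`.
#' @export
cycle_average <- function(kin, exclude_flagged = FALSE) {
  need <- c("participant", "group", "day", "phase", "cycle", "cycle_in_phase",
            "ad_deg", "rt_ms", "valid")
  miss <- setdiff(need, names(kin))
  if (length(miss)) stop("`kin` lacks columns: ", paste(miss, collapse = ", "))
  use <- kin$valid & !is.na(kin$ad_deg)
  if (exclude_flagged) use <- use & !kin$too_slow & !kin$too_fast
  kin$.use <- use
  dplyr::summarise(
    dplyr::group_by(kin, .data$participant, .data$group, .data$day,
                    .data$phase, .data$cycle, .data$cycle_in_phase),
    mean_ad = if (any(.data$.use)) mean(.data$ad_deg[.data$.use]) else NA_real_,
    mean_rt = if (any(.data$.use)) mean(.data$rt_ms[.data$.use]) else NA_real_,
    n_valid = sum(.data$.use),
    .groups = "drop"
  ) |>
    dplyr::arrange(.data$participant, .data$day, .data$cycle)
}

#' Baseline bias correction of a cycle series
#'
#' For each participant and day, the directional bias is the mean angular
#' deviation over the last five baseline cycles; it is subtracted from every
#' cycle of that day (`ad_corr`). Correcting an already corrected series
#' subtracts ~0 (idempotence).
#'
#' @param cycles Output of [cycle_average()].
#' @return The input with `bias_deg` and `ad_corr` columns added.
#' @export
baseline_correct <- function(cycles) {
  f <- function(df, key) {
    base <- df[df$phase == "baseline", ]
    if (nrow(base) < 5) {
      stop("participant ", key$participant, " day ", key$day,
           " has fewer than 5 baseline cycles", call. = FALSE)
    }
    last5 <- utils::tail(base[order(base$cycle), ], 5)
    bias <- mean(last5$mean_ad, na.rm = TRUE)
    df$bias_deg <- bias
    df$ad_corr <- df$mean_ad - bias
    df
  }
  dplyr::group_by(cycles, .data$participant, .data$day) |>
    dplyr::group_modify(f) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant, .data$day, .data$cycle)
}

## one-sided paired test that cycle c is still above cycle c-1
paired_increase_p <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired test needs at least 2 participants", call. = FALSE)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) return(if (m > 0) 0 else 1)
  pt(m / (s / sqrt(n)), df = n - 1, lower.tail = FALSE)
}

#' Learning-window determination by paired t-tests
#'
#' For each group, locates the adaptation cycle at which the angular
#' deviation stops increasing from the immediately preceding cycle: from
#' cycle 2 onward, a one-sided paired t-test across participants compares
#' cycle c with cycle c-1, and the stopping cycle is the first c whose
#' increase is non-significant (p >= alpha). The window size W is the
#' rounded mean of the per-group stopping cycles (e.g. stops at 7 and 11
#' give W = 9).
#'
#' @param cycles_corr Baseline-corrected cycle series ([baseline_correct()]).
#' @param phase Learning phase to examine (default "adaptation").
#' @param day Day of that phase.
#' @param alpha Significance level of the one-sided test (default 0.05).
#' @return A list with `stops` (named per-group stopping cycles) and `W`.
#' @export
find_learning_window <- function(cycles_corr, phase = "adaptation", day = 1,
                                 alpha = 0.05) {
  df <- cycles_corr[cycles_corr$phase == phase & cycles_corr$day == day, ]
  if (!nrow(df)) stop("no cycles in phase '", phase, "' on day ", day)
  stops <- vapply(split(df, df$group), function(g) {
    wide <- tidyr::pivot_wider(g[, c("participant", "cycle_in_phase", "ad_corr")],
                               names_from = "cycle_in_phase",
                               values_from = "ad_corr")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(mat) < 2) stop("learning window needs >= 2 participants per group",
                            call. = FALSE)
    nc <- ncol(mat)
    for (cc in 2:nc) {
      if (paired_increase_p(mat[, cc] - mat[, cc - 1]) >= alpha) return(cc)
    }
    warning("no non-significant step found; stopping at last cycle")
    nc
  }, numeric(1))
  list(stops = stops, W = as.integer(round(mean(stops))))
}

phase_slice <- function(cycles_corr, phase, day) {
  df <- cycles_corr[cycles_corr$phase == phase & cycles_corr$day == day, ]
  if (!nrow(df)) stop("no cycles in phase '", phase, "' on day ", day,
                      call. = FALSE)
  df
}

#' Initial adaptation rate over a fixed window
#'
#' Mean baseline-corrected angular deviation over the first `W` cycles of
#' the learning phase, per participant.
#'
#' @param cycles_corr Baseline-corrected cycle series.
#' @param W Window size in cycles (default 9).
#' @param phase Phase name ("adaptation" or "re-adaptation").
#' @param day Day of the phase.
#' @return Tibble `participant, group, value` (degrees).
#' @export
initial_rate <- function(cycles_corr, W = 9, phase = "adaptation", day = 1) {
  df <- phase_slice(cycles_corr, phase, day)
  if (max(df$cycle_in_phase) < W) {
    stop("phase '", phase, "' has fewer than W = ", W, " cycles")
  }
  df <- df[df$cycle_in_phase <= W, ]
  dplyr::summarise(dplyr::group_by(df, .data$participant, .data$group),
                   value = mean(.data$ad_corr), .groups = "drop")
}

#' Adaptation extent
#'
#' Mean corrected angular deviation over the last `last` cycles (default 10)
#' of the learning phase, per participant.
#'
#' @inheritParams initial_rate
#' @param last Number of terminal cycles to average.
#' @return Tibble `participant, group, value` (degrees).
#' @export
adaptation_extent <- function(cycles_corr, phase = "adaptation", day = 1,
                              last = 10) {
  df <- phase_slice(cycles_corr, phase, day)
  top <- max(df$cycle_in_phase)
  df <- df[df$cycle_in_phase > top - last, ]
  dplyr::summarise(dplyr::group_by(df, .data$participant, .data$group),
                   value = mean(.data$ad_corr), .groups = "drop")
}

#' Trial-wise learning rate for a gradual ramp
#'
#' For a gradually imposed rotation the deviation rises monotonically and a
#' fixed window is not meaningful; instead each trial contributes
#' `rate_n = (AD_{n+1} - AD_n) / e_n` with `e_n = r_n - AD_n`, the cursor
#' error experienced on trial n. Trials with |e_n| below `epsilon` are
#' excluded to guard against near-zero denominators, and the remaining
#' rates are averaged.
#'
#' Note the estimator divides two noisy quantities that share the trial's
#' motor noise; it is only unbiased for B when trial-to-trial noise is small
#' relative to the tracking lag (see the methods vignette).
#'
#' @param ad Trial-ordered baseline-corrected angular deviations (degrees).
#' @param rotation Rotation magnitude applied on each trial (degrees).
#' @param epsilon Exclusion threshold for |e_n| (default 0.5 deg).
#' @return Mean trial-wise learning rate (unitless).
#' @export
gradual_learning_rate <- function(ad, rotation, epsilon = 0.5) {
  if (length(ad) != length(rotation)) stop("ad and rotation lengths differ")
  n <- length(ad)
  if (n < 2) stop("need at least 2 trials")
  e <- rotation[-n] - ad[-n]
  rate <- diff(ad) / e
  keep <- abs(e) >= epsilon & is.finite(rate)
  if (!any(keep)) stop("all trials excluded by the |e| >= ", epsilon, " guard")
  mean(rate[keep])
}

#' Aftereffect, decay residue and cross-day retention
#'
#' Per participant: the aftereffect is the corrected deviation of the first
#' decay cycle of each day; the decay residue is the mean of the last 10
#' decay cycles; cross-day retention is the raw deviation of the first
#' day-2 cycle corrected with the *day-1* bias (the day-2 baseline would
#' absorb exactly the retention being measured). Missing phases yield
#' missing values, not errors.
#'
#' @param cycles_corr Baseline-corrected cycle series.
#' @return Tibble `participant, group, day, aftereffect, residue, crossday`
#'   (crossday is repeated on both day rows of a participant).
#' @export
retention_measures <- function(cycles_corr) {
  f <- function(df) {
    out <- lapply(split(df, df$day), function(dd) {
      dec <- dd[dd$phase == "decay", ]
      aft <- res <- NA_real_
      if (nrow(dec)) {
        aft <- dec$ad_corr[dec$cycle_in_phase == 1]
        if (!length(aft)) aft <- NA_real_
        top <- max(dec$cycle_in_phase)
        if (top >= 10) res <- mean(dec$ad_corr[dec$cycle_in_phase > top - 10])
      }
      tibble::tibble(group = dd$group[1], day = dd$day[1],
                     aftereffect = aft, residue = res)
    })
    out <- dplyr::bind_rows(out)
    cross <- NA_real_
    if (any(df$day == 2)) {
      d2 <- df[df$day == 2, ]
      first2 <- d2[which.min(d2$cycle), ]
      bias1 <- df$bias_deg[df$day == 1][1]
      cross <- first2$mean_ad - bias1
    }
    out$crossday <- cross
    out
  }
  dplyr::group_by(cycles_corr, .data$participant) |>
    dplyr::group_modify(~ f(.x)) |>
    dplyr::ungroup()
}

#' Reaction-time change in the initial learning window
#'
#' Mean reaction time over the first `W` cycles of the learning phase minus
#' the mean over the last 5 baseline cycles of the same day, per
#' participant.
#'
#' @inheritParams initial_rate
#' @return Tibble `participant, group, rt_window, delta_rt` (ms).
#' @export
delta_rt <- function(cycles_corr, W = 9, phase = "re-adaptation", day = 2) {
  df <- phase_slice(cycles_corr, phase, day)
  df <- df[df$cycle_in_phase <= W, ]
  base <- cycles_corr[cycles_corr$phase == "baseline" & cycles_corr$day == day, ]
  if (!nrow(base)) stop("no baseline cycles on day ", day)
  topb <- max(base$cycle_in_phase)
  base <- base[base$cycle_in_phase > topb - 5, ]
  win <- dplyr::summarise(dplyr::group_by(df, .data$participant, .data$group),
                          rt_window = mean(.data$mean_rt), .groups = "drop")
  bl <- dplyr::summarise(dplyr::group_by(base, .data$participant),
                         rt_base = mean(.data$mean_rt), .groups = "drop")
  out <- dplyr::left_join(win, bl, by = "participant")
  out$delta_rt <- out$rt_window - out$rt_base
  out[, c("participant", "group", "rt_window", "delta_rt")]
}

#' Per-participant adaptation summary
#'
#' Runs the metric chain (cycle averaging, baseline correction, rates,
#' extents, retention, reaction-time change) over a processed kinematics
#' table and returns one summary row per participant, wide over days.
#'
#' The day-1 learning-phase rate is the fixed-window mean unless the phase
#' is a gradual ramp (non-constant rotation), in which case the trial-wise
#' learning rate ([gradual_learning_rate()]) on trial-level corrected
#' deviations is used. Day-2 re-adaptation metrics use the day-2 baseline;
#' cross-day retention uses the day-1 baseline.
#'
#' @param kin Kinematics table (see [cycle_average()]).
#' @param W Learning window size in cycles (default 9).
#' @param epsilon Denominator guard of the gradual rate (deg).
#' @param exclude_flagged Drop too-slow/too-fast trials from cycle means.
#' @return A list with `cycles` (corrected cycle series), `summary`
#'   (per-participant wide tibble) and `gradual` (was day 1 a gradual ramp).
#' @export
summarize_adaptation <- function(kin, W = 9, epsilon = 0.5,
                                 exclude_flagged = FALSE) {
  cycles <- cycle_average(kin, exclude_flagged = exclude_flagged)
  corr <- baseline_correct(cycles)
  days <- sort(unique(corr$day))
  ret <- retention_measures(corr)

  d1_phase <- "adaptation"
  d1 <- kin[kin$day == 1 & kin$phase == d1_phase, ]
  gradual <- nrow(d1) > 0 &&
    length(unique(round(d1$perturbation_deg, 6))) > 1

  if (gradual) {
    biases <- dplyr::distinct(corr[corr$day == 1, ],
                              .data$participant, .data$bias_deg)
    ## the estimated baseline bias, not any same-named simulator column
    d1 <- dplyr::left_join(d1[, setdiff(names(d1), "bias_deg")], biases,
                           by = "participant")
    rate1 <- dplyr::summarise(
      dplyr::group_by(d1[order(d1$trial_global), ], .data$participant, .data$group),
      value = gradual_learning_rate(.data$ad_deg[.data$valid] - .data$bias_deg[.data$valid],
                                    .data$perturbation_deg[.data$valid],
                                    epsilon = epsilon),
      .groups = "drop")
  } else {
    rate1 <- initial_rate(corr, W = W, phase = d1_phase, day = 1)
  }
  extent1 <- adaptation_extent(corr, phase = d1_phase, day = 1)

  summary <- dplyr::rename(rate1, rate_d1 = "value")
  summary$extent_d1 <- extent1$value[match(summary$participant, extent1$participant)]
  r1 <- ret[ret$day == 1, ]
  summary$aftereffect_d1 <- r1$aftereffect[match(summary$participant, r1$participant)]
  summary$residue_d1 <- r1$residue[match(summary$participant, r1$participant)]

  if (2 %in% days) {
    summary$crossday <- r1$crossday[match(summary$participant, r1$participant)]
    rate2 <- initial_rate(corr, W = W, phase = "re-adaptation", day = 2)
    extent2 <- adaptation_extent(corr, phase = "re-adaptation", day = 2)
    r2 <- ret[ret$day == 2, ]
    drt <- delta_rt(corr, W = W, phase = "re-adaptation", day = 2)
    summary$rate_d2 <- rate2$value[match(summary$participant, rate2$participant)]
    summary$extent_d2 <- extent2$value[match(summary$participant, extent2$participant)]
    summary$aftereffect_d2 <- r2$aftereffect[match(summary$participant, r2$participant)]
    summary$residue_d2 <- r2$residue[match(summary$participant, r2$participant)]
    summary$rt_d2 <- drt$rt_window[match(summary$participant, drt$participant)]
    summary$delta_rt_d2 <- drt$delta_rt[match(summary$participant, drt$participant)]
  }
  list(cycles = corr, summary = summary, gradual = gradual, W = W)
}

#' Per-participant decay series as a matrix
#'
#' Extracts the corrected angular deviations of the decay phase as a
#' participants-by-cycles matrix, the input expected by
#' [bootstrap_decay()].
#'
#' @param cycles_corr Baseline-corrected cycle series.
#' @param day Day of the decay phase.
#' @param group Optional group label to filter on.
#' @return Numeric matrix, rownames = participants.
#' @export
decay_matrix <- function(cycles_corr, day = 1, group = NULL) {
  df <- phase_slice(cycles_corr, "decay", day)
  if (!is.null(group)) df <- df[df$group == group, ]
  if (!nrow(df)) stop("no decay cycles for group '", group, "' on day ", day)
  wide <- tidyr::pivot_wider(df[, c("participant", "cycle_in_phase", "ad_corr")],
                             names_from = "cycle_in_phase",
                             values_from = "ad_corr")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$participant
  mat[, order(as.integer(colnames(mat))), drop = FALSE]
}
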