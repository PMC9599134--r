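## Trajectory kinematics -----------------------------------------------------
##
## Raw 125 Hz pen positions are low-pass filtered (zero-phase 4th-order
## Butterworth, 10 Hz cutoff), differentiated to radial velocity, and
## summarized per trial: movement onset at 5% of peak radial speed, reaction
## and movement times, and the angular deviation of the hand direction at
## peak outward velocity from the target direction (positive = clockwise).

#' Zero-phase Butterworth filtering of a trajectory
#'
#' Applies a 4th-order low-pass Butterworth filter forward and backward
#' (zero phase, so onset timing is not lag-biased; the effective attenuation
#' order is 8) to x and y independently. Before filtering, each series is
#' extended on both ends with 150 samples of its boundary value; reach
#' trajectories hold steady at both ends (pre-trial hold, post-ring hold),
#' so constant extension is the correct boundary model and start-up
#' transients of the filter die out inside the padding. A constant series
#' therefore passes through unchanged (unit DC gain).
#'
#' @param x,y Numeric vectors of positions (cm) at uniform sampling.
#' @param fs Sampling rate in Hz (125 for the tablet data).
#' @param cutoff_hz Cutoff frequency (default 10 Hz).
#' @param order Filter order (default 4).
#' @return A list with filtered `x` and `y`, same lengths as the input.
#' @export
filter_trajectory <- function(x, y, fs = 125, cutoff_hz = 10, order = 4) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 15) stop("too few samples to filter (need >= 15)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- 150L
  run <- function(s) {
    sp <- c(rep(s[1], pad), s, rep(s[n], pad))
    as.numeric(signal::filtfilt(bf, sp))[pad + seq_len(n)]
  }
  list(x = run(x), y = run(y))
}

#' Radial speed of a trajectory
#'
#' Central-difference derivative of the radial distance from the start
#' position (first sample); one-sided differences at the endpoints.
#'
#' @param x,y Filtered positions (cm).
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of radial speed (cm/s), same length as input.
#' @export
radial_velocity <- function(x, y, fs = 125) {
  r <- sqrt((x - x[1])^2 + (y - y[1])^2)
  n <- length(r)
  if (n < 3) stop("need at least 3 samples")
  dt <- 1 / fs
  v <- numeric(n)
  v[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (2 * dt)
  v[1] <- (r[2] - r[1]) / dt
  v[n] <- (r[n] - r[n - 1]) / dt
  v
}

#' Movement onset from a radial speed series
#'
#' Onset is the first sample of the contiguous rise into the peak at which
#' radial speed exceeds `threshold_frac` of the peak outward speed. The
#' search walks backward from the peak, so sub-threshold pre-movement jitter
#' cannot trigger a spurious onset.
#'
#' @param v Radial speed series (cm/s).
#' @param threshold_frac Fraction of peak speed (default 0.05).
#' @return Integer sample index of onset, or NA if the series has no
#'   positive peak.
#' @export
detect_onset <- function(v, threshold_frac = 0.05) {
  p <- which.max(v)
  if (!length(p) || !is.finite(v[p]) || v[p] <= 0) return(NA_integer_)
  thr <- threshold_frac * v[p]
  i <- p
  while (i > 1 && v[i - 1] > thr) i <- i - 1L
  i
}

#' Angular deviation at peak outward velocity
#'
#' The hand direction is the direction of the vector from the start position
#' to the hand at peak radial speed; the angular deviation is the target
#' direction minus the hand direction, wrapped to (-180, 180], so that a
#' positive value is a clockwise error.
#'
#' @param x,y Filtered positions (cm).
#' @param peak_idx Sample index of peak radial speed.
#' @param target_deg Target direction (degrees CCW from laterally right).
#' @return A list with `hand_dir_deg` and `ad_deg`.
#' @export
angular_deviation <- function(x, y, peak_idx, target_deg) {
  dx <- x[peak_idx] - x[1]
  dy <- y[peak_idx] - y[1]
  if (dx == 0 && dy == 0) stop("hand at peak coincides with start position")
  hand <- atan2(dy, dx) * 180 / pi
  list(hand_dir_deg = hand, ad_deg = wrap180(target_deg - hand))
}

#' Per-trial kinematic measures from raw samples
#'
#' Full per-trial chain: filter, differentiate, onset, timing and angular
#' deviation. Time 0 of `t_ms` is target appearance. Trials are flagged
#' `too_slow` when target attainment (first 5 cm crossing) exceeds 0.8 s and
#' `too_fast` below 0.2 s; trials that cannot be processed (too few samples,
#' no movement, no ring crossing, peak before onset) come back with
#' `valid = FALSE` and a reason.
#'
#' @param t_ms,x,y Raw samples of one trial.
#' @param target_deg Target direction of the trial.
#' @param fs,cutoff_hz,order Filter settings, see [filter_trajectory()].
#' @param ring_cm Radius of the target ring (5 cm).
#' @return One-row tibble: `onset_ms, rt_ms, mt_ms, peak_speed_cm_s,
#'   hand_dir_deg, ad_deg, too_slow, too_fast, valid, invalid_reason`.
#' @export
process_trial <- function(t_ms, x, y, target_deg, fs = 125, cutoff_hz = 10,
                          order = 4, ring_cm = 5) {
  bad <- function(reason) tibble::tibble(
    onset_ms = NA_real_, rt_ms = NA_real_, mt_ms = NA_real_,
    peak_speed_cm_s = NA_real_, hand_dir_deg = NA_real_, ad_deg = NA_real_,
    too_slow = NA, too_fast = NA, valid = FALSE, invalid_reason = reason
  )
  if (length(x) < 15) return(bad("too few samples"))
  f <- filter_trajectory(x, y, fs = fs, cutoff_hz = cutoff_hz, order = order)
  v <- radial_velocity(f$x, f$y, fs = fs)
  onset <- detect_onset(v)
  if (is.na(onset)) return(bad("no positive radial speed peak"))
  p <- which.max(v)
  if (p < onset) return(bad("peak before onset"))

  r <- sqrt((f$x - f$x[1])^2 + (f$y - f$y[1])^2)
  cross <- which(r >= ring_cm)
  if (!length(cross)) return(bad("never crosses target ring"))
  ci <- cross[1]
  attain_ms <- if (ci == 1) t_ms[1] else {
    ## linear interpolation between the straddling samples
    t_ms[ci - 1] + (t_ms[ci] - t_ms[ci - 1]) *
      (ring_cm - r[ci - 1]) / (r[ci] - r[ci - 1])
  }
  ang <- angular_deviation(f$x, f$y, p, target_deg)
  onset_ms <- t_ms[onset]
  tibble::tibble(
    onset_ms = onset_ms,
    rt_ms = onset_ms,
    mt_ms = attain_ms - onset_ms,
    peak_speed_cm_s = v[p],
    hand_dir_deg = ang$hand_dir_deg,
    ad_deg = ang$ad_deg,
    too_slow = attain_ms > 800,
    too_fast = attain_ms < 200,
    valid = TRUE,
    invalid_reason = NA_character_
  )
}

#' Kinematics for a table of trajectories
#'
#' Applies [process_trial()] to every `(participant, trial_global)` group of
#' a sample-level table and joins the trial metadata.
#'
#' @param samples Tibble `participant, trial_global, t_ms, x_cm, y_cm`.
#' @param trials Trial metadata table (must contain `participant`,
#'   `trial_global`, `target_deg`); every trajectory must have a matching
#'   metadata row.
#' @param ... Passed to [process_trial()].
#' @return The trial metadata with the kinematic columns appended, one row
#'   per trajectory.
#' @export
process_trajectories <- function(samples, trials, ...) {
  need <- c("participant", "trial_global", "t_ms", "x_cm", "y_cm")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("`samples` lacks columns: ", paste(miss, collapse = ", "))
  need_t <- c("participant", "trial_global", "target_deg")
  miss <- setdiff(need_t, names(trials))
  if (length(miss)) stop("`trials` lacks columns: ", paste(miss, collapse = ", "))

  key_s <- paste(samples$participant, samples$trial_global, sep = "\r")
  key_t <- paste(trials$participant, trials$trial_global, sep = "\r")
  orphans <- setdiff(unique(key_s), key_t)
  if (length(orphans)) {
    stop("trajectories without metadata for keys: ",
         paste(gsub("\r", "/", utils::head(orphans, 5)), collapse = ", "))
  }
  idx <- split(seq_len(nrow(samples)), key_s)
  meta_row <- match(names(idx), key_t)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    ii <- idx[[j]]
    out[[j]] <- process_trial(samples$t_ms[ii], samples$x_cm[ii],
                              samples$y_cm[ii],
                              trials$target_deg[meta_row[j]], ...)
  }
  kin <- dplyr::bind_rows(out)
  ## measured quantities replace any same-named simulator columns
  meta <- trials[meta_row, setdiff(names(trials), names(kin)), drop = FALSE]
  dplyr::bind_cols(meta, kin) |>
    dplyr::arrange(.data$participant, .data$trial_global)
}
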