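# Shared fixtures: noiseless generator settings and hand-built inputs.

quiet_params <- function(...) {
  sim_params(motor_noise_sd_deg = 0, baseline_bias_sd_deg = 0,
             sample_jitter_cm = 0, rt_noise_ms = 0, mt_noise_ms = 0, ...)
}

# analytic minimum-jerk helpers (independent of the package internals)
mj_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}
mj_speed <- function(tau, D, T) 30 * D / T * (tau^2 - 2 * tau^3 + tau^4)
# first time (fraction of T) at which speed crosses `frac` of its peak:
# solve tau^2 (1 - tau)^2 = frac * 1.875 / 30
mj_onset_tau <- function(frac = 0.05) {
  c <- sqrt(frac * 1.875 / 30)
  (1 - sqrt(1 - 4 * c)) / 2
}

# hand-built cycle series table (one participant unless given)
make_cycles <- function(mean_ad, phase, day = 1, participant = "P1",
                        group = "g", mean_rt = 350) {
  n <- length(mean_ad)
  stopifnot(length(phase) == n)
  cip <- stats::ave(seq_len(n), factor(phase, levels = unique(phase)),
                    FUN = seq_along)
  tibble::tibble(participant = participant, group = group, day = day,
                 phase = phase, cycle = seq_len(n), cycle_in_phase = cip,
                 mean_ad = mean_ad,
                 mean_rt = rep_len(mean_rt, n), n_valid = 8L)
}

# trial-level kinematics-like table for cycle_average tests
make_kin <- function(ad, cycle, valid = TRUE, too_slow = FALSE,
                     too_fast = FALSE, phase = "adaptation", day = 1,
                     participant = "P1", group = "g", rt = 350) {
  n <- length(ad)
  tibble::tibble(participant = participant, group = group, day = day,
                 phase = phase, cycle = cycle,
                 cycle_in_phase = cycle,
                 trial_global = seq_len(n), target_deg = 0,
                 condition = "clamp", perturbation_deg = 30,
                 ad_deg = ad, rt_ms = rep_len(rt, n),
                 valid = rep_len(valid, n),
                 too_slow = rep_len(too_slow, n),
                 too_fast = rep_len(too_fast, n))
}
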