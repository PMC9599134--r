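test_that("zero-phase filtering preserves DC and the passband, kills 40 Hz", {
  n <- 376  # 3 s at 125 Hz
  t <- (0:(n - 1)) / 125
  # constant position: DC gain is exactly 1
  f <- filter_trajectory(rep(2.5, n), rep(-1, n))
  expect_equal(f$x, rep(2.5, n), tolerance = 1e-8)
  expect_equal(f$y, rep(-1, n), tolerance = 1e-8)
  # 1 Hz component: squared 4th-order Butterworth response at f/fc = 0.1
  # is 1/(1 + 0.1^8), i.e. amplitude preserved to well within 1%
  amp <- function(sig, out) {
    mid <- seq(n %/% 4, 3 * n %/% 4)  # avoid edge transients
    sqrt(mean(out[mid]^2) / mean(sig[mid]^2))
  }
  s1 <- sin(2 * pi * 1 * t)
  f1 <- filter_trajectory(s1, s1)
  expect_lt(abs(amp(s1, f1$x) - 1), 0.01)
  # 40 Hz: |H|^2 = 1/(1 + 4^8), amplitude below 1% of the input
  s40 <- sin(2 * pi * 40 * t)
  f40 <- filter_trajectory(s40, s40)
  expect_lt(amp(s40, f40$x), 0.01)
  expect_error(filter_trajectory(1:5, 1:5), "too few samples")
})

test_that("radial velocity is exact for linear motion and zero at rest", {
  t <- (0:49) / 125
  v <- radial_velocity(10 * t * cos(pi / 6), 10 * t * sin(pi / 6))
  expect_equal(v[2:49], rep(10, 48), tolerance = 1e-10)
  expect_equal(radial_velocity(rep(1, 30), rep(2, 30)), rep(0, 30))
})

test_that("radial velocity peak matches the minimum-jerk closed form", {
  D <- 8; T <- 0.45
  t <- seq(0, T, by = 1 / 125)
  r <- D * mj_pos(t / T)
  v <- radial_velocity(r, rep(0, length(r)) + 0)  # motion along x
  expect_lt(abs(max(v) - 1.875 * D / T) / (1.875 * D / T), 0.02)
})

test_that("onset detection follows the 5%-of-peak rule on the rise", {
  v <- c(0, 0, 0, 10, 10, 10, 10, 5, 0)
  expect_identical(detect_onset(v), 4L)
  # sub-threshold pre-movement jitter does not trigger onset
  v2 <- c(0.2, 0.3, 0.2, 10, 10, 10, 10, 5, 0)
  expect_identical(detect_onset(v2), 4L)
  # all-zero series has no onset
  expect_true(is.na(detect_onset(rep(0, 20))))
})

test_that("detected onset matches the analytic minimum-jerk 5% crossing", {
  p <- quiet_params()
  d <- build_design(1, seed = 6)
  d$trials <- d$trials[1:6, ]
  sim <- simulate_participant(d, p, seed = 2, trajectories = TRUE)
  kin <- process_trajectories(sim$samples, sim$trials)
  analytic <- sim$trials$rt_ms + mj_onset_tau(0.05) * sim$trials$mt_ms
  expect_true(all(abs(kin$onset_ms - analytic) <= 8),
              label = "onset within one sample of the analytic crossing")
})

test_that("angular deviation uses the clockwise-positive convention", {
  # straight reaches at known directions; peak anywhere on the path
  ray <- function(dir_deg) {
    r <- seq(0, 8, length.out = 30)
    list(x = r * cospi(dir_deg / 180), y = r * sinpi(dir_deg / 180))
  }
  r60 <- ray(60)
  expect_equal(angular_deviation(r60$x, r60$y, 25, target_deg = 90)$ad_deg, 30)
  r0 <- ray(0)
  expect_equal(angular_deviation(r0$x, r0$y, 25, target_deg = 0)$ad_deg, 0)
  r10 <- ray(10)
  expect_equal(angular_deviation(r10$x, r10$y, 25, target_deg = 0)$ad_deg, -10)
  # wrap-around stays in (-180, 180]
  r170 <- ray(-170)
  expect_equal(angular_deviation(r170$x, r170$y, 25, target_deg = 175)$ad_deg, -15)
})

test_that("angular deviation is equivariant under joint rotation", {
  p <- quiet_params(B_learn = 0.05)
  d <- build_design(1, seed = 6)
  d$trials <- d$trials[d$trials$phase == "adaptation", ][1:4, ]
  sim <- simulate_participant(d, p, seed = 3, trajectories = TRUE)
  kin0 <- process_trajectories(sim$samples, sim$trials)
  phi <- 37 * pi / 180
  rot <- sim$samples
  rot$x_cm <- cos(phi) * sim$samples$x_cm - sin(phi) * sim$samples$y_cm
  rot$y_cm <- sin(phi) * sim$samples$x_cm + cos(phi) * sim$samples$y_cm
  trials_rot <- sim$trials
  trials_rot$target_deg <- trials_rot$target_deg + 37
  kin1 <- process_trajectories(rot, trials_rot)
  expect_equal(kin1$ad_deg, kin0$ad_deg, tolerance = 1e-8)
})

test_that("timing measures and speed flags follow the task thresholds", {
  mk <- function(rt, mt) {
    t <- seq(0, rt + mt + 500, by = 8)
    r <- 8 * mj_pos((t - rt) / mt)
    list(t = t, x = r, y = rep(0, length(t)))
  }
  # attainment past 0.8 s: too slow
  slow <- mk(500, 700)  # 5 cm at ~ 500 + 0.55*700 = 885 ms
  ks <- process_trial(slow$t, slow$x, slow$y, target_deg = 0)
  expect_true(ks$too_slow); expect_false(ks$too_fast)
  # interior of the window: both flags off
  mid <- mk(250, 400)
  km <- process_trial(mid$t, mid$x, mid$y, target_deg = 0)
  expect_false(km$too_slow); expect_false(km$too_fast)
  # attainment under 0.2 s: too fast
  fast <- mk(30, 200)  # 5 cm at ~ 30 + 110 = 140 ms
  kf <- process_trial(fast$t, fast$x, fast$y, target_deg = 0)
  expect_true(kf$too_fast)
  # rt + mt arithmetic: rt ~ onset, attainment - onset = mt
  expect_equal(km$rt_ms, km$onset_ms)
  # 5 cm on an 8 cm minimum-jerk reach is crossed at ~ 0.568 of the duration
  expect_lt(abs((km$rt_ms + km$mt_ms) - (250 + 0.568 * 400)), 10)
})

test_that("unprocessable trials are marked invalid with a reason", {
  # too few samples
  k1 <- process_trial(seq(0, 80, by = 8), rep(0, 11), rep(0, 11), 0)
  expect_false(k1$valid); expect_match(k1$invalid_reason, "few samples")
  # never leaves the start: no positive peak
  t <- seq(0, 800, by = 8)
  k2 <- process_trial(t, rep(0, length(t)), rep(0, length(t)), 0)
  expect_false(k2$valid)
  # moves but never crosses the ring
  r <- 3 * mj_pos((t - 200) / 300)
  k3 <- process_trial(t, r, rep(0, length(t)), 0)
  expect_false(k3$valid); expect_match(k3$invalid_reason, "ring")
})

test_that("trajectory tables without matching metadata are rejected", {
  d <- build_design(2, seed = 1)
  d$trials <- d$trials[1:4, ]
  sim <- simulate_participant(d, quiet_params(), seed = 1, trajectories = TRUE)
  orphan <- sim$samples
  orphan$trial_global <- orphan$trial_global + 1000
  expect_error(process_trajectories(orphan, sim$trials), "without metadata")
  expect_error(process_trajectories(sim$samples[, -1], sim$trials),
               "lacks columns")
})
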