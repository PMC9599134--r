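test_that("no learning, no noise, no bias gives identically zero deviation", {
  d <- build_design(1, seed = 2)
  # no implicit learning and no explicit strategy: every reach is on target
  p <- quiet_params(B_learn = 0, explicit_gain = 0)
  sim <- simulate_participant(d, p, seed = 5, trajectories = FALSE)
  expect_equal(sim$trials$ad_deg, rep(0, nrow(sim$trials)))
  expect_equal(sim$trials$hand_dir_deg, wrap180(sim$trials$target_deg))
})

test_that("clamp-driven state is monotone non-decreasing and bounded", {
  d <- build_design(1, seed = 2)
  p <- quiet_params()
  sim <- simulate_participant(d, p, seed = 5, trajectories = FALSE)
  u <- sim$trials$state_deg[sim$trials$day == 1 & sim$trials$phase == "adaptation"]
  expect_true(all(diff(u) >= -1e-12))
  expect_true(all(u <= p$clamp_asymptote_deg))
})

test_that("feedback-free decay follows the closed-form geometric law", {
  d <- build_design(1, seed = 2)
  p <- quiet_params(A_retain = 0.95)
  sim <- simulate_participant(d, p, seed = 5, trajectories = FALSE)
  dec <- sim$trials[sim$trials$day == 1 & sim$trials$phase == "decay", ]
  u0 <- dec$state_deg[1]
  k <- seq_len(nrow(dec)) - 1
  expect_equal(dec$state_deg, u0 * 0.95^k, tolerance = 1e-12)
})

test_that("cross-day carry-over honours the overnight retention factor", {
  d <- build_design(1, seed = 2)
  for (ret in c(1, 0.5, 0)) {
    sim <- simulate_participant(d, quiet_params(overnight_retention = ret),
                                seed = 5, trajectories = FALSE)
    last1 <- max(which(sim$trials$day == 1))
    first2 <- min(which(sim$trials$day == 2))
    # the final day-1 trial is feedback-free, so its post-update state is A * u
    u_end <- sim$trials$state_deg[last1] * 0.995
    expect_equal(sim$trials$state_deg[first2], ret * u_end, tolerance = 1e-12)
  }
})

test_that("a 30 degree clamp drives faster and higher adaptation than 4 degrees", {
  p <- quiet_params()
  s30 <- simulate_participant(build_design(1, seed = 2), p, seed = 5,
                              trajectories = FALSE)$trials
  s04 <- simulate_participant(build_design(2, seed = 2), p, seed = 5,
                              trajectories = FALSE)$trials
  u30 <- s30$state_deg[s30$day == 1 & s30$phase == "adaptation"]
  u04 <- s04$state_deg[s04$phase == "adaptation"]
  # same elapsed trial count (320): the large clamp is ahead throughout
  expect_true(all(u30[-1] > u04[seq_along(u30)][-1]))
  expect_gt(max(u30), max(u04))
})

test_that("simulated trajectories satisfy the sampling contract", {
  d <- build_design(2, seed = 4)
  d$trials <- d$trials[1:12, ]
  sim <- simulate_participant(d, quiet_params(), seed = 9, trajectories = TRUE)
  for (tg in unique(sim$samples$trial_global)) {
    s <- sim$samples[sim$samples$trial_global == tg, ]
    expect_equal(unique(diff(s$t_ms)), 8)
    r <- sqrt(s$x_cm^2 + s$y_cm^2)
    expect_lt(r[1], 2)                       # starts near the origin
    expect_equal(sum(diff(r >= 5) == 1), 1)  # crosses the ring exactly once
    expect_gte(max(s$t_ms) - s$t_ms[which(r >= 5)[1]], 500)  # 0.5 s past ring
  }
})

test_that("cohort simulation is deterministic and correctly sized", {
  d <- build_design(2, seed = 4)
  d$trials <- d$trials[d$trials$cycle <= 45, ]  # trimmed for speed
  a <- simulate_cohort(d, sim_params(), c(anodal = 2, sham = 3), seed = 7)
  b <- simulate_cohort(d, sim_params(), c(anodal = 2, sham = 3), seed = 7)
  expect_identical(a$trials, b$trials)
  expect_equal(length(unique(a$trials$participant)), 5)
  expect_equal(nrow(a$trials), 5 * nrow(d$trials))
  expect_equal(as.vector(table(a$trials$group)[c("anodal", "sham")]),
               c(2, 3) * nrow(d$trials))
  c <- simulate_cohort(d, sim_params(), c(anodal = 2, sham = 3), seed = 8)
  expect_false(identical(a$trials$ad_deg, c$trials$ad_deg))
})

test_that("invalid parameters and group specs are rejected", {
  expect_error(sim_params(A_retain = 0), "A_retain")
  expect_error(sim_params(A_retain = 1.1), "A_retain")
  expect_error(sim_params(B_learn = 1), "B_learn")
  expect_error(sim_params(motor_noise_sd_deg = -1), "SD")
  expect_error(sim_params(sample_rate_hz = 100), "125")
  expect_error(sim_params(reach_dist_cm = 4), "5 cm")
  d <- build_design(2, seed = 1)
  expect_error(simulate_cohort(d, sim_params(), c(3, 3)), "named")
  expect_error(simulate_cohort(d, sim_params(), c(a = 0, b = 3)), "at least 1")
  expect_error(simulate_cohort(d, sim_params(), c(a = 2, b = 2),
                               effect_group = "z"), "one of")
})
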