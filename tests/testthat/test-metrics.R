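test_that("cycle averaging is the mean over valid trials, never imputed", {
  kin <- make_kin(ad = 1:8, cycle = rep(1L, 8))
  cy <- cycle_average(kin)
  expect_equal(cy$mean_ad, 4.5)
  expect_equal(cy$n_valid, 8L)

  kin2 <- make_kin(ad = 1:8, cycle = rep(1L, 8),
                   valid = c(FALSE, rep(TRUE, 7)))
  cy2 <- cycle_average(kin2)
  expect_equal(cy2$mean_ad, mean(2:8))
  expect_equal(cy2$n_valid, 7L)

  kin3 <- make_kin(ad = 1:8, cycle = rep(1:2, each = 4),
                   valid = c(rep(FALSE, 4), rep(TRUE, 4)))
  cy3 <- cycle_average(kin3)
  expect_true(is.na(cy3$mean_ad[1]))   # all-invalid cycle stays missing
  expect_equal(cy3$n_valid[1], 0L)
  expect_equal(cy3$mean_ad[2], mean(5:8))

  # flagged trials are retained by default, dropped on request
  kin4 <- make_kin(ad = c(100, 2, 2, 2), cycle = rep(1L, 4),
                   too_slow = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cycle_average(kin4)$mean_ad, 26.5)
  expect_equal(cycle_average(kin4, exclude_flagged = TRUE)$mean_ad, 2)
})

test_that("baseline correction subtracts the last-5-baseline mean and is idempotent", {
  cyc <- make_cycles(mean_ad = c(rep(2, 15), rep(10, 5)),
                     phase = c(rep("baseline", 15), rep("adaptation", 5)))
  corr <- baseline_correct(cyc)
  expect_equal(unique(corr$bias_deg), 2)
  expect_equal(corr$ad_corr[corr$phase == "adaptation"], rep(8, 5))
  # bias is the last five baseline cycles only
  cyc2 <- make_cycles(mean_ad = c(rep(0, 10), rep(3, 5), rep(10, 5)),
                      phase = c(rep("baseline", 15), rep("adaptation", 5)))
  corr2 <- baseline_correct(cyc2)
  expect_equal(unique(corr2$bias_deg), 3)
  expect_equal(corr2$ad_corr[corr2$phase == "adaptation"], rep(7, 5))
  # idempotence: correcting a corrected series subtracts ~0
  again <- cyc2
  again$mean_ad <- corr2$ad_corr
  corr3 <- baseline_correct(again)
  expect_equal(corr3$ad_corr, corr2$ad_corr, tolerance = 1e-12)
  # too-short baselines are rejected
  short <- make_cycles(mean_ad = rep(1, 8),
                       phase = c(rep("baseline", 3), rep("adaptation", 5)))
  expect_error(baseline_correct(short), "fewer than 5 baseline")
})

test_that("learning window: plateau detection and group combination", {
  # deterministic staircase: equal +2 steps up to cycle 7, exactly flat after
  plateau_series <- function(stop_cycle, n_cycles = 14, jitter) {
    vals <- pmin(seq_len(n_cycles), stop_cycle - 1) * 2 + jitter
    vals
  }
  mk_group <- function(stop_cycle, group, n_pp = 6) {
    dplyr::bind_rows(lapply(seq_len(n_pp), function(i) {
      cy <- make_cycles(plateau_series(stop_cycle, jitter = i / 10),
                        phase = rep("adaptation", 14),
                        participant = sprintf("%s%02d", group, i), group = group)
      cy$ad_corr <- cy$mean_ad
      cy$bias_deg <- 0
      cy
    }))
  }
  one <- mk_group(8, "g1")
  lw <- find_learning_window(one)
  expect_equal(unname(lw$stops), 8)
  # the worked combination: stops at 7 and 11 give a window of 9
  two <- dplyr::bind_rows(mk_group(7, "a"), mk_group(11, "s"))
  lw2 <- find_learning_window(two)
  expect_equal(sort(unname(lw2$stops)), c(7, 11))
  expect_identical(lw2$W, 9L)
  # a single participant cannot support a paired test
  single <- mk_group(8, "solo", n_pp = 1)
  expect_error(find_learning_window(single), ">= 2 participants")
})

test_that("fixed-window rate and extent are exact slices", {
  cyc <- make_cycles(mean_ad = c(rep(0, 15), 1:40),
                     phase = c(rep("baseline", 15), rep("adaptation", 40)))
  corr <- baseline_correct(cyc)
  expect_equal(initial_rate(corr, W = 9)$value, 5)         # mean of 1..9
  expect_equal(adaptation_extent(corr)$value, mean(31:40)) # last 10 cycles
  flat <- make_cycles(mean_ad = c(rep(0, 15), rep(5, 9)),
                      phase = c(rep("baseline", 15), rep("adaptation", 9)))
  expect_equal(initial_rate(baseline_correct(flat), W = 9)$value, 5)
  expect_error(initial_rate(corr, W = 99), "fewer than W")
})

test_that("gradual learning rate: arithmetic, guard, and parameter recovery", {
  # one step of 1 degree against an error of 5 degrees is a rate of 0.2
  expect_equal(gradual_learning_rate(c(0, 1), c(5, 5)), 0.2)
  # perfect tracking leaves no usable denominators
  r <- gradual_rotation_at(1:320)
  expect_error(gradual_learning_rate(r, r), "excluded")
  # noiseless single-rate learner with full per-trial retention: the
  # trial-wise rate equals B exactly (state-space algebra)
  B <- 0.1
  u <- numeric(321)
  for (n in 1:320) u[n + 1] <- u[n] + B * (r[n] - u[n])
  expect_equal(gradual_learning_rate(u[1:320], r), B, tolerance = 1e-10)
})

test_that("retention: aftereffect, residue, and day-1-based cross-day retention", {
  cyc <- make_cycles(mean_ad = c(rep(1, 15), rep(12, 10), 10:1),
                     phase = c(rep("baseline", 15), rep("adaptation", 10),
                               rep("decay", 10)))
  corr <- baseline_correct(cyc)
  ret <- retention_measures(corr)
  expect_equal(ret$aftereffect, 9)        # 10 - bias 1
  expect_equal(ret$residue, 5.5 - 1)      # mean(10..1) - bias
  expect_true(is.na(ret$crossday))        # single-day design

  # two days: day-2 first cycle is corrected with the day-1 bias
  d1 <- make_cycles(mean_ad = c(rep(2, 15), rep(10, 10), rep(5, 10)),
                    phase = c(rep("baseline", 15), rep("adaptation", 10),
                              rep("decay", 10)), day = 1)
  d2 <- make_cycles(mean_ad = c(6, rep(0, 14), rep(8, 10), rep(3, 10)),
                    phase = c(rep("baseline", 15), rep("re-adaptation", 10),
                              rep("decay", 10)), day = 2)
  corr2 <- baseline_correct(dplyr::bind_rows(d1, d2))
  ret2 <- retention_measures(corr2)
  expect_equal(unique(ret2$crossday), 6 - 2)
})

test_that("reaction-time change is window mean minus last-5-baseline mean", {
  phases <- c(rep("baseline", 15), rep("re-adaptation", 12), rep("decay", 10))
  rts <- c(rep(350, 15), rep(420, 12), rep(350, 10))
  cyc <- make_cycles(mean_ad = rep(0, length(phases)), phase = phases,
                     day = 2, mean_rt = rts)
  corr <- baseline_correct(cyc)
  dr <- delta_rt(corr, W = 9)
  expect_equal(dr$delta_rt, 70)
  flat <- make_cycles(mean_ad = rep(0, length(phases)), phase = phases,
                      day = 2, mean_rt = 333)
  expect_equal(delta_rt(baseline_correct(flat), W = 9)$delta_rt, 0)
})

test_that("the noiseless pipeline summary equals the generator closed form", {
  d <- build_design(1, seed = 11)
  p <- quiet_params()
  sim <- simulate_cohort(d, p, c(g = 2), seed = 3)
  res <- summarize_adaptation(sim$trials)
  tr <- sim$trials[sim$trials$participant == "g_01", ]
  agg <- function(rows) mean(tr$ad_true_deg[rows])
  d1a <- tr$day == 1 & tr$phase == "adaptation"
  s <- res$summary[res$summary$participant == "g_01", ]
  expect_equal(s$rate_d1, agg(d1a & tr$cycle_in_phase <= 9), tolerance = 1e-10)
  expect_equal(s$extent_d1, agg(d1a & tr$cycle_in_phase > 30), tolerance = 1e-10)
  dec <- tr$day == 1 & tr$phase == "decay"
  expect_equal(s$aftereffect_d1, agg(dec & tr$cycle_in_phase == 1), tolerance = 1e-10)
  # cross-day retention: first day-2 cycle state survives overnight
  first2 <- tr$day == 2 & tr$cycle == 1
  expect_equal(s$crossday, agg(first2), tolerance = 1e-10)
})

test_that("initial rate and extent increase with the learning rate B", {
  d <- build_design(1, seed = 11)
  d$trials <- d$trials[d$trials$day == 1, ]
  vals <- sapply(c(0.01, 0.02, 0.05), function(B) {
    sim <- simulate_cohort(d, quiet_params(B_learn = B), c(g = 2), seed = 3)
    res <- summarize_adaptation(sim$trials)
    c(mean(res$summary$rate_d1), mean(res$summary$extent_d1))
  })
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})
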