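test_that("sliding covariance equals the brute-force slice oracle", {
  set.seed(21)
  b1 <- stats::rnorm(20); b2 <- stats::rnorm(20)
  tr <- make_trace(b1, b2, fs = 1000)
  cfg <- detection_config(window = 5 / 1000)
  cv <- sliding_covariance(tr, cfg)
  oracle <- vapply(1:16, function(i) stats::cov(b1[i:(i + 4)], b2[i:(i + 4)]),
                   numeric(1))
  expect_equal(cv$value, oracle * tr$config$trap_stiffness^2, tolerance = 1e-12)
  expect_length(cv$time, 16)
})

test_that("identical bead signals give covariance equal to windowed variance", {
  set.seed(22)
  b <- stats::rnorm(50)
  tr <- make_trace(b, b, fs = 1000, trap_stiffness = 1)
  cfg <- detection_config(window = 0.007, signal_choice = "position")
  cv <- sliding_covariance(tr, cfg)
  oracle <- vapply(seq_along(cv$value),
                   function(i) stats::var(b[i:(i + 6)]), numeric(1))
  expect_equal(cv$value, oracle, tolerance = 1e-12)
})

test_that("uncorrelated noise fluctuates about zero covariance", {
  set.seed(23)
  tr <- make_trace(stats::rnorm(5000), stats::rnorm(5000), fs = 1000,
                   trap_stiffness = 1)
  cv <- sliding_covariance(tr, detection_config(window = 0.021,
                                                signal_choice = "position"))
  expect_lt(abs(mean(cv$value)), 0.02)
})

test_that("window shorter than 3 samples is rejected", {
  tr <- make_trace(stats::rnorm(100), stats::rnorm(100), fs = 1000)
  expect_error(sliding_covariance(tr, detection_config(window = 0.0005)),
               "3 samples")
})

test_that("threshold sits at the midpoint for symmetric components", {
  set.seed(24)
  v <- c(stats::rnorm(20000, -1, 0.1), stats::rnorm(20000, 1, 0.1))
  th <- covariance_threshold(make_cov(v))
  expect_lt(abs(th$threshold), 0.03)
  expect_equal(sort(th$mix_fit$means), th$mix_fit$means)  # low first
})

test_that("threshold equals the grid-search overlap minimizer for unequal mixes", {
  set.seed(25)
  v <- c(stats::rnorm(5000, 0, 0.5), stats::rnorm(45000, 4, 1.2))
  th <- covariance_threshold(make_cov(v))
  mf <- th$mix_fit
  grid <- seq(mf$means[1], mf$means[2], length.out = 20001)
  miscls <- mf$weights[1] * stats::pnorm(grid, mf$means[1], mf$sds[1],
                                         lower.tail = FALSE) +
    mf$weights[2] * stats::pnorm(grid, mf$means[2], mf$sds[2])
  expect_lt(abs(th$threshold - grid[which.min(miscls)]),
            2 * diff(grid[1:2]))
  expect_gt(th$threshold, mf$means[1])
  expect_lt(th$threshold, mf$means[2])
})

test_that("unimodal covariance is reported as undetectable", {
  set.seed(26)
  v <- stats::rnorm(20000, 1, 0.3)
  expect_error(covariance_threshold(make_cov(v)), class = "myotrap_no_events")
})

test_that("square-wave covariance yields events at the programmed phases", {
  v <- rep(rep(c(0, 1), each = 100), 5)   # 100 ms low / 100 ms high at 1 kHz
  cv <- make_cov(v, fs = 1000, window_used = 0.01)
  cfg <- detection_config(window = 0.01)
  ev <- detect_events(cv, 0.5, cfg)
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$duration, rep(0.1, 5), tolerance = 0.02)
  expect_equal(ev$start, 0.2 * (0:4), tolerance = 0.002)
})

test_that("covariance above threshold everywhere yields no events", {
  cv <- make_cov(rep(1, 1000))
  ev <- detect_events(cv, 0.5, detection_config(window = 0.01))
  expect_identical(nrow(ev), 0L)
})

test_that("deadtime scales with the covariance window", {
  cfg8 <- detection_config(window = 0.008)
  cfg15 <- detection_config(window = 0.015)
  ev8 <- detect_events(make_cov(rep(1, 100)), 0.5, cfg8)
  ev15 <- detect_events(make_cov(rep(1, 100)), 0.5, cfg15)
  expect_lte(attr(ev8, "deadtime"), attr(ev15, "deadtime"))
  expect_equal(attr(ev8, "deadtime"), 0.016)
})

test_that("detection recalls truth events and rarely false-alarms", {
  hits <- 0; surv <- 0; fp <- 0; minutes <- 0
  for (s in 31:33) {
    cfg <- trap_sim_config(duration = 20, atp_conc = 4000, seed = s,
                           kinetics = kinetic_scheme(k_attach = 2))
    g <- generate_trace(cfg)
    a <- analyze_trace(g$trace, window = 0.008)
    ev <- a$events
    dead <- attr(ev, "deadtime")
    tt <- g$truth[g$truth$end - g$truth$start > 2 * dead, ]
    surv <- surv + nrow(tt)
    for (j in seq_len(nrow(tt))) {
      hits <- hits + any(abs(ev$start - tt$start[j]) < a$cfg$window &
                           abs(ev$end - tt$end[j]) < a$cfg$window)
    }
    for (j in seq_len(nrow(ev))) {
      fp <- fp + !any(pmin(ev$end[j], g$truth$end) -
                        pmax(ev$start[j], g$truth$start) > 0)
    }
    minutes <- minutes + 20 / 60
  }
  expect_gt(surv, 15)
  expect_gte(hits / surv, 0.95)
  expect_lte(fp / minutes, 2)
})

test_that("detection is invariant to a common offset on both beads", {
  cfg <- trap_sim_config(duration = 10, atp_conc = 4000, seed = 35,
                         kinetics = kinetic_scheme(k_attach = 2))
  g <- generate_trace(cfg)
  tr2 <- g$trace
  tr2$bead1_pos <- tr2$bead1_pos + 25
  tr2$bead2_pos <- tr2$bead2_pos + 25
  tr2$bead1_force <- tr2$config$trap_stiffness * tr2$bead1_pos
  tr2$bead2_force <- tr2$config$trap_stiffness * tr2$bead2_pos
  a1 <- analyze_trace(g$trace, window = 0.008)
  a2 <- analyze_trace(tr2, window = 0.008)
  expect_equal(a2$events$start, a1$events$start, tolerance = 1e-9)
  expect_equal(a2$events$end, a1$events$end, tolerance = 1e-9)
})

test_that("feedback-artifact pruning follows the duration and force clauses", {
  cfg <- detection_config(window = 0.01)
  tt <- seq(0, 1, by = 1e-3)
  ev <- data.frame(start = c(0.2, 0.515), end = c(0.5, 0.8),
                   duration = c(0.3, 0.285))
  class(ev) <- c("event_record", "data.frame")
  # force stays 3 pN above baseline through the 15 ms gap -> merged
  f_high <- ifelse(tt > 0.2 & tt < 0.8, 3, 0)
  m1 <- prune_feedback_artifacts(ev, tt, f_high, cfg, baseline = 0,
                                 baseline_sd = 0.5)
  expect_identical(nrow(m1), 1L)
  expect_equal(c(m1$start, m1$end), c(0.2, 0.8))
  # force returns to baseline inside the gap -> kept separate
  f_ret <- ifelse((tt > 0.2 & tt < 0.505) | (tt > 0.512 & tt < 0.8), 3, 0)
  m2 <- prune_feedback_artifacts(ev, tt, f_ret, cfg, baseline = 0,
                                 baseline_sd = 0.5)
  expect_identical(nrow(m2), 2L)
  # gap of 3 windows is never merged regardless of force
  ev3 <- data.frame(start = c(0.2, 0.53), end = c(0.5, 0.8),
                    duration = c(0.3, 0.27))
  class(ev3) <- c("event_record", "data.frame")
  m3 <- prune_feedback_artifacts(ev3, tt, f_high, cfg, baseline = 0,
                                 baseline_sd = 0.5)
  expect_identical(nrow(m3), 2L)
})

test_that("step measurement reads plateaus exactly on noiseless traces", {
  cfg <- noiseless_config(duration = 1, substep1 = 3.5, substep2 = 1.5)
  ev <- data.frame(start = 0.3, duration = 0.4, om_bound = FALSE,
                   substep2_time = 0.05)
  g <- generate_trace(cfg, forced_events = ev)
  dcfg <- detection_config(window = 0.008)
  expect_equal(measure_step(g$trace, 0.3, 0.7, dcfg), 5.0, tolerance = 1e-9)
  # flat zero trace measures zero
  flat <- make_trace(rep(0, 2000), rep(0, 2000), fs = 10e3)
  expect_equal(measure_step(flat, 0.05, 0.15, dcfg), 0)
  # missing post-event samples: step unavailable, not an error
  expect_true(is.na(measure_step(g$trace, 0.3, 0.999, dcfg)))
  # event shorter than the pre-dissociation offset: unavailable
  expect_true(is.na(measure_step(g$trace, 0.695, 0.7, dcfg)))
})

test_that("event force averages the interior and subtracts the baseline", {
  fs <- 10e3
  n <- 10000
  tt <- (seq_len(n) - 1) / fs
  tr <- make_trace(rep(0, n), rep(0, n), fs = fs)
  # constant 3 pN during [0.2, 0.5], zero outside
  tr$bead1_force <- ifelse(tt >= 0.2 & tt <= 0.5, 3, 0)
  dcfg <- detection_config(window = 0.008)
  expect_equal(event_force(tr, 0.2, 0.5, dcfg), 3, tolerance = 1e-6)
  # linear ramp 0 -> 4 pN across the interior averages to 2 pN
  tr$bead1_force <- ifelse(tt >= 0.2 & tt <= 0.5, (tt - 0.2) / 0.3 * 4, 0)
  expect_equal(event_force(tr, 0.2, 0.5, dcfg), 2, tolerance = 0.03)
  # too-short events give no force
  expect_true(is.na(event_force(tr, 0.2, 0.203, dcfg)))
})
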