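test_that("drug assignment follows the Langmuir occupancy", {
  cfg <- ensemble_config(n_heads = 75L)
  set.seed(91)
  expect_false(any(assign_om(cfg, 0, "myocyte")))
  # om = Kd: binomial(75, 0.5) over repeated draws
  n_bound <- sum(vapply(1:50, function(i) sum(assign_om(cfg, 1200, "myocyte")),
                        numeric(1)))
  expect_lt(abs(n_bound / (50 * 75) - 0.5), 3 * sqrt(0.25 / (50 * 75)))
  # om = 10 Kd: expected fraction 10/11
  n10 <- sum(vapply(1:50, function(i) sum(assign_om(cfg, 1000, "motility")),
                    numeric(1)))
  expect_lt(abs(n10 / (50 * 75) - 10 / 11), 3 * sqrt((10 / 121) / (50 * 75)))
  # explicit occupancy bypasses the concentration entirely
  expect_true(all(assign_om(cfg, 0, om_fraction = 1)))
})

test_that("attachment rates follow the cooperative kernel", {
  cfg <- ensemble_config(n_heads = 5L, pi_release_free = 15,
                         pi_release_om = 30, decay_length = 15)
  st <- init_state(cfg, om_flags = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # nothing bound, eps_min 0: fully off
  expect_equal(attachment_rate(1, st, cfg, eps_min_ca = 0), 0)
  # neighbour bound at distance 0 is impossible; bind head 2, probe head 2's
  # neighbours: head 1 and 3 at one spacing, head 5 at two spacings
  st$bound[2] <- TRUE; st$strain[2] <- 0
  r1 <- attachment_rate(1, st, cfg, eps_min_ca = 0)
  expect_equal(r1, 15 * exp(-14.3 / 15), tolerance = 1e-12)
  # at distance = decay_length the factor is exactly exp(-1)
  cfg2 <- ensemble_config(n_heads = 2L, spacing = 15, decay_length = 15)
  st2 <- init_state(cfg2)
  st2$bound[1] <- TRUE
  expect_equal(attachment_rate(2, st2, cfg2, eps_min_ca = 0),
               15 * exp(-1), tolerance = 1e-12)
  # eps_min floor dominates far from bound heads
  expect_equal(attachment_rate(4, st, cfg, eps_min_ca = 0.5), 15 * 0.5)
  # drug-bound heads attach at the raised scale; motility ignores regulation
  r5 <- attachment_rate(5, st, cfg, eps_min_ca = 0, mode = "motility")
  expect_equal(r5, 30)
})

test_that("detachment rates follow the Bell equation and variant overrides", {
  cfg <- model_variant("septa", ensemble_config(n_heads = 2L))
  st <- init_state(cfg, om_flags = c(FALSE, TRUE))
  st$bound <- c(TRUE, TRUE)
  st$strain <- c(0, 50)
  expect_equal(detachment_rate(1, st, cfg), 89)        # zero strain: k0
  expect_equal(detachment_rate(2, st, cfg), 9.4)       # drug: force-free
  st$strain[1] <- cfg$kT / (cfg$xb_stiffness * 1.3)    # F d = kT
  expect_equal(detachment_rate(1, st, cfg), 89 / exp(1), tolerance = 1e-12)
  # malik variant: drug-bound heads detach like drug-free ones
  cfgm <- model_variant("malik", ensemble_config(n_heads = 2L))
  stm <- init_state(cfgm, om_flags = c(FALSE, TRUE))
  stm$bound <- c(TRUE, TRUE); stm$strain <- c(1, 1)
  expect_equal(detachment_rate(2, stm, cfgm), detachment_rate(1, stm, cfgm))
})

test_that("R reference stepper and compiled kernel produce identical trajectories", {
  cfg <- ensemble_config(n_heads = 12L, seed = 3)
  om <- rep(c(TRUE, FALSE), 6)
  for (mode in c("motility", "isometric")) {
    set.seed(123)
    st <- init_state(cfg, om)
    for (i in 1:80) st <- gillespie_step(st, cfg, mode, eps_min_ca = 0.3)
    set.seed(123)
    out <- myotrap:::gillespie_run_cpp(
      12L, cfg$spacing, om, 80L, if (mode == "motility") 1L else 0L,
      cfg$pi_release_free, cfg$pi_release_om, cfg$eps_max, 0.3,
      cfg$decay_length, cfg$xb_stiffness, cfg$kT, cfg$step_free, cfg$step_om,
      cfg$detach_free[[1]], cfg$detach_free[[2]],
      1L, cfg$detach_om, cfg$om_bell[[1]], cfg$om_bell[[2]])
    expect_equal(st$time, out$time, tolerance = 1e-12)
    expect_equal(st$filament_pos, out$filament_pos, tolerance = 1e-12)
  }
})

test_that("waiting times are exponential at the instantaneous total rate", {
  cfg <- ensemble_config(n_heads = 8L)
  set.seed(131)
  st0 <- init_state(cfg, om_flags = rep(FALSE, 8))
  st0$bound[3] <- TRUE; st0$strain[3] <- 2
  rates <- vapply(1:8, function(i) {
    if (st0$bound[i]) detachment_rate(i, st0, cfg) else
      attachment_rate(i, st0, cfg, eps_min_ca = 0.2)
  }, numeric(1))
  R <- sum(rates)
  dts <- vapply(1:3000, function(i) {
    gillespie_step(st0, cfg, "isometric", eps_min_ca = 0.2)$time
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(dts, stats::pexp, rate = R))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-head occupancy matches the analytic two-state solution", {
  cfg <- ensemble_config(n_heads = 1L, n_steps = 4000L, n_runs = 20L,
                         step_free = 0, detach_free = c(k0 = 20, d = 0),
                         pi_release_free = 10, seed = 2)
  r <- run_isometric(cfg, om_conc = 0, eps_min_ca = 1)
  expect_lt(abs(r$bound_fraction - 10 / (10 + 20)), 0.02)
})

test_that("motility repositioning keeps the net spring force at zero", {
  cfg <- model_variant("septa", small_ensemble())
  r <- run_motility(cfg, om_conc = 300, seed = 7)
  expect_lt(r$max_force_imbalance, 1e-9)
})

test_that("a fully off filament is reported as an absorbing state", {
  cfg <- ensemble_config(n_heads = 4L, n_steps = 50L, n_runs = 3L, seed = 5)
  r <- run_isometric(cfg, om_conc = 0, eps_min_ca = 0)
  expect_identical(r$n_absorbed, 3)
  st <- gillespie_step(init_state(cfg), cfg, "isometric", eps_min_ca = 0)
  expect_true(isTRUE(st$absorbed))
})

test_that("drug-saturated isometric ensembles produce no net force under SEPTA", {
  cfg <- model_variant("septa",
                       ensemble_config(n_heads = 50L, n_steps = 600L,
                                       n_runs = 60L, seed = 6))
  r <- run_isometric(cfg, om_fraction = 1, eps_min_ca = 0.5)
  se <- r$sd_force / sqrt(cfg$n_runs)
  expect_lt(abs(r$mean_force), 4 * se + 0.5)
})

test_that("unloaded gliding is directional and drug-suppressed under SEPTA", {
  base <- ensemble_config(n_runs = 40L, seed = 8)
  septa <- model_variant("septa", base)
  v0 <- run_motility(septa, 0, seed = 10)
  expect_gt(v0$mean_velocity, 0)
  v_sat <- run_motility(septa, 1e6, seed = 11)
  expect_lt(abs(v_sat$mean_velocity), v0$mean_velocity / 10)
  # velocity decreases monotonically with drug occupancy (Spearman)
  sw <- sweep_conditions(base, "septa", mode = "motility",
                         om_grid = c(0, 30, 100, 300, 1000, 1e4), seed = 12)
  rho <- stats::cor(sw$om_bound_fraction, sw$mean_velocity,
                    method = "spearman")
  expect_equal(rho, -1)
})

test_that("force scaling is the affine map around the passive reference", {
  cfg <- ensemble_config()
  expect_equal(scale_force(10, 10, cfg), 0)
  expect_equal(scale_force(20, 10, cfg), 10 * 0.306)
  x <- c(5, 12, 30)
  s <- scale_force(x, 5, cfg)
  expect_identical(which.max(s), which.max(x))  # argmax preserved
})

test_that("calcium calibration reaches its target and is self-consistent", {
  cfg <- ensemble_config(n_heads = 40L, n_steps = 600L, n_runs = 80L,
                         seed = 14)
  cal <- calibrate_eps_min(cfg, target_activation = 0.3, pCa_ref = 6.4,
                           tol = 0.02)
  expect_lt(abs(cal$force_achieved / cal$force_max - 0.3), 0.05)
  expect_gt(cal$K_Ca, 0)
  # a calibrated config reproduces the target through the calcium Hill curve
  ccal <- apply_calibration(cfg, cal)
  r <- run_isometric(ccal, om_conc = 0, pCa = 6.4, seed = 15)
  expect_lt(abs(r$mean_force / cal$force_max - 0.3), 0.08)
  # target 100% saturates the baseline availability at eps_max
  cal1 <- calibrate_eps_min(cfg, target_activation = 1, pCa_ref = 6.4)
  expect_equal(cal1$eps_min_scale, 1)
})
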