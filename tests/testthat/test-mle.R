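test_that("truncated single-exponential MLE matches its closed form and optim", {
  set.seed(51)
  t0 <- stats::rexp(500, 10)
  f <- fit_single_exp(t0)
  expect_equal(f$k, 1 / mean(t0), tolerance = 1e-12)
  # shifted data with a deadtime
  t1 <- 0.016 + stats::rexp(500, 40)
  f1 <- fit_single_exp(t1, tmin = 0.016)
  expect_equal(f1$k, 1 / (mean(t1) - 0.016), tolerance = 1e-12)
  # numeric optimum agrees with the closed form to 1e-8 relative
  num <- stats::optimize(function(k) sum(log(k) - k * (t1 - 0.016)),
                         c(1, 200), maximum = TRUE, tol = 1e-12)$maximum
  expect_equal(f1$k, num, tolerance = 1e-8)
  expect_error(fit_single_exp(t1, tmin = 0.1), "below the deadtime")
  expect_error(fit_single_exp(rep(0.5, 10)), "degenerate")
})

test_that("unit weights reproduce the unweighted likelihood exactly", {
  set.seed(52)
  t0 <- 0.01 + stats::rexp(300, 30)
  f_un <- fit_single_exp(t0, tmin = 0.01)
  f_w <- fit_single_exp(t0, tmin = 0.01, weights = rep(1, 300))
  expect_identical(f_w$k, f_un$k)
  expect_identical(f_w$logL, f_un$logL)
  # molecule weights sum to the number of points
  mol <- rep(c("a", "b", "c"), c(200, 80, 20))
  expect_equal(sum(molecule_weights(mol)), 300)
})

test_that("all truncated densities integrate to one beyond the deadtime", {
  tmin <- 0.016
  int <- function(f) stats::integrate(f, tmin, Inf, rel.tol = 1e-9)$value
  expect_equal(int(function(t) 47.7 * exp(-47.7 * (t - tmin))), 1,
               tolerance = 1e-6)
  p <- 0.3; ka <- 52; kb <- 9.4
  expect_equal(int(function(t) p * ka * exp(-ka * (t - tmin)) +
                     (1 - p) * kb * exp(-kb * (t - tmin))), 1,
               tolerance = 1e-6)
  kF <- 89 * exp(-3 * 1.3 / 4.05)
  expect_equal(int(function(t) kF * exp(-kF * (t - tmin))), 1,
               tolerance = 1e-6)
})

test_that("two-exponential MLE recovers well-separated rates", {
  set.seed(53)
  n <- 4000
  pick <- stats::runif(n) < 0.5
  t0 <- ifelse(pick, stats::rexp(n, 50), stats::rexp(n, 5))
  f <- fit_double_exp(t0)
  expect_lt(abs(f$k_a - 50) / 50, 0.1)
  expect_lt(abs(f$k_b - 5) / 5, 0.1)
  expect_gte(f$k_a, f$k_b)
  expect_lt(abs(f$fraction_b - 0.5), 0.05)
})

test_that("single-exponential truth collapses the mixture (LLR not significant)", {
  set.seed(54)
  t0 <- stats::rexp(1500, 20)
  f1 <- fit_single_exp(t0)
  f2 <- fit_double_exp(t0)
  lt <- llr_test(f1, f2, df = 2)
  expect_gt(lt$p, 0.05)
})

test_that("global shared-rate fit beats condition-wise constrained fits", {
  set.seed(55)
  mk <- function(om, frac_b, n = 600) {
    pick <- stats::runif(n) < frac_b
    data.frame(om_nM = om,
               duration = ifelse(pick, stats::rexp(n, 9.4),
                                 stats::rexp(n, 52)),
               molecule_id = rep(c("m1", "m2", "m3"), length.out = n))
  }
  dat <- rbind(mk(0, 0), mk(100, 0.5), mk(10000, 0.97))
  g <- global_fit_exp(dat)
  expect_lt(abs(g$k_a - 52) / 52, 0.15)
  expect_lt(abs(g$k_b - 9.4) / 9.4, 0.15)
  expect_true(all(diff(g$fraction_b[order(as.numeric(names(g$fraction_b)))]) > 0))
})

test_that("rate estimator bias is under 2% at n = 1000", {
  bias <- vapply(1:20, function(s) {
    set.seed(400 + s)
    t0 <- 0.016 + stats::rexp(1000, 47.7)
    fit_single_exp(t0, tmin = 0.016)$k / 47.7 - 1
  }, numeric(1))
  expect_lt(abs(stats::median(bias)), 0.02)
})

test_that("llr_test handles identity and inverted inputs", {
  expect_equal(llr_test(-100, -100, 1)$p, 1)
  expect_equal(llr_test(-100, -100, 1)$statistic, 0)
  expect_error(llr_test(-90, -100, 1), "optimizer failure")
})

test_that("Bell fit is null-consistent and recovers imposed force dependence", {
  # d = 0 truth: estimated d near zero, LLR non-significant (seed checked)
  e0 <- sample_isometric_events(c(60, 0), c(-1, 7), n = 500, seed = 61)
  b0 <- fit_bell(e0$force_pN, e0$duration_s)
  expect_lt(abs(b0$d), 0.25)
  expect_gt(b0$p_vs_single, 0.05)
  # strong force dependence recovered within a loose band
  e1 <- sample_isometric_events(c(89, 1.3), c(-1, 7), n = 800, seed = 62,
                                deadtime = 0.002)
  b1 <- fit_bell(e1$force_pN, e1$duration_s, tmin = 0.002)
  expect_lt(abs(b1$d - 1.3), 0.3)
  expect_lt(abs(b1$k0 - 89) / 89, 0.2)
  expect_lt(b1$p_vs_single, 1e-6)
})

test_that("bootstrap CIs behave: degeneracy, scaling, and coverage", {
  # zero-variance data: CI collapses onto the point estimate
  d0 <- data.frame(value = rep(2, 50))
  b0 <- bootstrap_ci(function(d) list(m = mean(d$value)), d0, n_boot = 100,
                     seed = 1)
  expect_equal(unname(b0$ci[1, 1]), 2)
  expect_equal(unname(b0$ci[2, 1]), 2)
  expect_identical(b0$status, "ok")
  # CI width shrinks roughly as 1/sqrt(n)
  widths <- vapply(c(250, 1000, 4000), function(n) {
    set.seed(71)
    d <- data.frame(value = stats::rexp(n, 10))
    b <- bootstrap_ci(function(x) list(k = 1 / mean(x$value)), d,
                      n_boot = 200, seed = 2)
    diff(b$ci[, 1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_gt(widths[1] / widths[2], 1.5); expect_lt(widths[1] / widths[2], 2.7)
  expect_gt(widths[2] / widths[3], 1.5); expect_lt(widths[2] / widths[3], 2.7)
  # coverage of the 95% interval near nominal over 100 replications
  cover <- vapply(1:100, function(s) {
    set.seed(500 + s)
    d <- data.frame(value = stats::rexp(150, 10))
    b <- bootstrap_ci(function(x) list(k = 1 / mean(x$value)), d,
                      n_boot = 150, seed = s)
    b$ci[1, 1] <= 10 && 10 <= b$ci[2, 1]
  }, logical(1))
  expect_gte(mean(cover), 0.86)
})

test_that("exponential-plus-drift fit recovers constructed signals exactly", {
  tt <- seq(0, 3, by = 0.01)
  y <- 1.0 * exp(-2 * tt) + 0.1 * tt + 0.5
  f <- fit_exp_plus_linear(tt, y)
  expect_equal(f$amplitude, 1.0, tolerance = 1e-5)
  expect_equal(f$rate, 2.0, tolerance = 1e-4)
  expect_equal(f$slope, 0.1, tolerance = 1e-5)
  expect_equal(f$offset, 0.5, tolerance = 1e-5)
  # pure exponential: no drift
  f2 <- fit_exp_plus_linear(tt, 2 * exp(-1.5 * tt))
  expect_lt(abs(f2$slope), 1e-6)
  # pure line: no exponential amplitude
  f3 <- fit_exp_plus_linear(tt, 0.3 * tt + 1)
  expect_lt(abs(f3$amplitude), 1e-5)
})

test_that("two-component LLR test holds its nominal type-I error rate", {
  rej <- vapply(1:200, function(s) {
    set.seed(700 + s)
    t0 <- stats::rexp(150, 30)
    f1 <- fit_single_exp(t0)
    f2 <- fit_double_exp(t0)
    llr_test(f1, f2, df = 2)$p < 0.05
  }, logical(1))
  # binomial 3-sigma band around 5% at 200 trials
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.02)
})
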