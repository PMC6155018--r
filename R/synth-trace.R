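#' Generate a synthetic dumbbell trace with known ground truth
#'
#' Produces a two-bead position/force time series emulating a three-bead
#' optical trapping record. Each bead signal is the sum of a shared
#' ("filament") component and a bead-specific component, both
#' Ornstein-Uhlenbeck processes discretized exactly (AR(1) with coefficient
#' `exp(-dt/tau)`), so the autocorrelation is correct at any sample rate.
#' While a myosin head is bound the shared mode is stiffened by
#' `myosin_stiffness`, which lowers its variance and therefore the
#' inter-bead covariance - the signature used by covariance event detection.
#' Drug-free events additionally displace both beads by `substep1` at
#' attachment and by `substep2` at an exponentially distributed internal time
#' (ADP release); drug-bound events produce no displacement.
#'
#' @param config A [trap_sim_config()].
#' @param forced_events Optional data frame with columns `start`, `duration`,
#'   `om_bound` and optionally `substep2_time` (seconds, relative to the event
#'   start) overriding the stochastic event schedule; useful for constructing
#'   traces with programmed events.
#' @param molecule_id Label attached to the trace.
#' @return A list with elements `trace` (class `dumbbell_trace`) and `truth`
#'   (data frame of embedded events: `start`, `end`, `om_bound`, `step1`,
#'   `step2`, `substep2_time`, `applied_force`).
#' @export
generate_trace <- function(config, forced_events = NULL, molecule_id = "mol1") {
  stopifnot(inherits(config, "trap_sim_config"))
  set.seed(config$seed)
  fs <- config$sample_rate
  dt <- 1 / fs
  n <- as.integer(round(config$duration * fs))
  ks <- config$kinetics

  truth <- if (is.null(forced_events)) {
    schedule_events(config, n * dt)
  } else {
    coerce_forced_events(forced_events, config)
  }

  # shared-mode parameters (two beads move together: stiffness and drag double)
  k_shared_unbound <- 2 * config$trap_stiffness
  k_shared_bound <- k_shared_unbound + config$myosin_stiffness
  g_shared <- 2 * config$bead_drag
  var_shared_unbound <- ou_var(config$kT, k_shared_unbound)
  p <- config$noise_partition
  var_indep <- var_shared_unbound * (1 - p) / p
  tau_indep <- config$bead_drag / config$trap_stiffness

  # piecewise-stationary shared mode: segments alternate unbound/bound
  bound <- logical(n)
  if (nrow(truth) > 0L) {
    for (j in seq_len(nrow(truth))) {
      i0 <- max(1L, as.integer(floor(truth$start[j] * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling(truth$end[j] * fs)))
      if (i1 >= i0) bound[i0:i1] <- TRUE
    }
  }
  shared <- ou_piecewise(bound, dt,
                         tau = c(g_shared / k_shared_unbound,
                                 g_shared / k_shared_bound),
                         sd = sqrt(c(var_shared_unbound,
                                     ou_var(config$kT, k_shared_bound))))
  b1 <- shared + ou_stationary(n, dt, tau_indep, sqrt(var_indep))
  b2 <- shared + ou_stationary(n, dt, tau_indep, sqrt(var_indep))

  # programmed working-stroke displacement: first-order rise at attachment
  # and substep, fast trap-relaxation decay after detachment
  disp <- stroke_waveform(truth, n, fs, config$rise_time,
                          tau_relax = config$bead_drag / config$trap_stiffness)
  b1 <- b1 + disp
  b2 <- b2 + disp

  trace <- structure(list(
    time = (seq_len(n) - 1L) * dt,
    bead1_pos = b1, bead2_pos = b2,
    bead1_force = config$trap_stiffness * b1,
    bead2_force = config$trap_stiffness * b2,
    molecule_id = molecule_id,
    config = config
  ), class = "dumbbell_trace")
  list(trace = trace, truth = truth)
}

# stationary variance of an OU mode with stiffness k at thermal energy kT
ou_var <- function(kT, k) kT / k

# exact stationary AR(1) sample path of length n
ou_stationary <- function(n, dt, tau, sd) {
  if (sd == 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1L] <- stats::rnorm(1L, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# OU path whose (tau, sd) switch with the bound mask; exact AR(1) updates with
# piecewise-constant coefficients, continuous across switches
ou_piecewise <- function(bound, dt, tau, sd) {
  n <- length(bound)
  if (all(sd == 0)) return(numeric(n))
  idx <- bound + 1L                  # 1 = unbound, 2 = bound
  a <- exp(-dt / tau)[idx]
  s <- (sd * sqrt(1 - exp(-dt / tau)^2))[idx]
  z <- stats::rnorm(n)
  runs <- rle(idx)
  x <- numeric(n)
  pos <- 1L
  prev <- stats::rnorm(1L, sd = sd[idx[1L]])
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    seg <- pos:(pos + len - 1L)
    ar <- a[pos]
    innov <- s[pos] * z[seg]
    innov[1L] <- innov[1L] + ar * prev
    x[seg] <- as.numeric(stats::filter(innov, ar, method = "recursive"))
    prev <- x[pos + len - 1L]
    pos <- pos + len
  }
  x
}

# programmed displacement from the truth table: within each drug-free event
# the level approaches step1 (then step1 + step2) with time constant
# rise_time; after detachment the dumbbell relaxes back at the much faster
# trap relaxation time tau_relax = drag / stiffness
stroke_waveform <- function(truth, n, fs, rise_time, tau_relax) {
  disp <- numeric(n)
  if (nrow(truth) == 0L) return(disp)
  dt <- 1 / fs
  expo <- function(t, tau) if (tau > 0) exp(-pmax(t, 0) / tau) else
    as.numeric(t < 0)
  for (j in seq_len(nrow(truth))) {
    if (truth$om_bound[j]) next
    start <- truth$start[j]; end <- truth$end[j]
    t2 <- start + truth$substep2_time[j]
    i0 <- max(1L, as.integer(floor(start * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(end * fs)))
    if (i1 < i0) next
    tt <- (i0:i1 - 1L) * dt
    lvl <- truth$step1[j] * (1 - expo(tt - start, rise_time))
    after2 <- tt >= t2
    if (any(after2)) {
      lvl[after2] <- lvl[after2] +
        truth$step2[j] * (1 - expo(tt[after2] - t2, rise_time))
    }
    disp[i0:i1] <- disp[i0:i1] + lvl
    # relaxation tail (negligible past ~25 tau)
    lvl_end <- lvl[length(lvl)]
    itail <- (i1 + 1L):min(n, i1 + max(1L, ceiling(25 * tau_relax * fs)))
    if (i1 < n && lvl_end != 0) {
      ttail <- (itail - 1L) * dt
      disp[itail] <- disp[itail] + lvl_end * expo(ttail - end, tau_relax)
    }
  }
  disp
}

# stochastic event schedule; events that would overrun the trace are dropped
schedule_events <- function(config, total) {
  ks <- config$kinetics
  post_margin <- 0.05
  p_om <- config$om_conc / (config$om_conc + ks$om_kd)
  rows <- list()
  t <- 0
  if (ks$k_attach > 0) {
    repeat {
      start <- t + stats::rexp(1L, ks$k_attach)
      om <- stats::runif(1L) < p_om
      if (om) {
        dur <- stats::rexp(1L, ks$k_om_detach)
        sub2 <- NA_real_
      } else {
        dur <- stats::rexp(1L, detachment_rate_atp(config$atp_conc, ks))
        # the second displacement completes through whichever pathway commits
        # first: ADP release (substep2_rate) or the ATP-driven completion
        # that saturates at rigor_exit_rate; never later than detachment
        k_exit <- 1 / (1 / (ks$k_atp_binding * config$atp_conc) +
                         1 / ks$rigor_exit_rate)
        sub2 <- min(stats::rexp(1L, ks$substep2_rate + k_exit), dur)
      }
      if (start + dur > total - post_margin) break
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = start + dur, om_bound = om,
        step1 = if (om) 0 else config$substep1,
        step2 = if (om) 0 else config$substep2,
        substep2_time = sub2, applied_force = NA_real_
      )
      t <- start + dur
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      om_bound = logical(0), step1 = numeric(0),
                      step2 = numeric(0), substep2_time = numeric(0),
                      applied_force = numeric(0)))
  }
  do.call(rbind, rows)
}

coerce_forced_events <- function(ev, config) {
  stopifnot(all(c("start", "duration") %in% names(ev)))
  om <- if ("om_bound" %in% names(ev)) ev$om_bound else rep(FALSE, nrow(ev))
  sub2 <- if ("substep2_time" %in% names(ev)) ev$substep2_time else
    ifelse(om, NA_real_, pmin(ev$duration / 2, 0.02))
  data.frame(
    start = ev$start, end = ev$start + ev$duration, om_bound = om,
    step1 = ifelse(om, 0, config$substep1),
    step2 = ifelse(om, 0, config$substep2),
    substep2_time = sub2, applied_force = NA_real_
  )
}

#' @export
print.dumbbell_trace <- function(x, ...) {
  cat(sprintf("Dumbbell trace '%s': %d samples at %.0f kHz (%.1f s)\n",
              x$molecule_id, length(x$time), x$config$sample_rate / 1e3,
              length(x$time) / x$config$sample_rate))
  invisible(x)
}
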