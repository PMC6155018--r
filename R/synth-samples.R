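#' Sample deadtime-censored attachment durations
#'
#' Draws actomyosin attachment durations from the exponential mixture implied
#' by a [kinetic_scheme()]: each event is drug-bound with probability
#' `om / (om + om_kd)` and then exponential at `k_om_detach`; drug-free events
#' are exponential at the ATP-dependent detachment rate
#' [detachment_rate_atp()]. Durations below the instrumental deadtime are
#' discarded and regeneration continues until `n` survive, mimicking the
#' censoring of events an experiment cannot resolve.
#'
#' @param scheme A [kinetic_scheme()].
#' @param atp MgATP concentration (uM).
#' @param om Drug concentration (nM).
#' @param n Number of surviving durations required.
#' @param deadtime Minimum detectable duration (s).
#' @param seed Integer seed.
#' @param n_molecules Number of molecule labels to spread events over.
#' @return A `dwell_dataset` data frame with columns `molecule_id`, `atp_uM`,
#'   `om_nM`, `om_bound` (ground truth), `duration` (s).
#' @export
sample_dwells <- function(scheme, atp, om, n, deadtime = 0, seed = 1L,
                          n_molecules = 5L) {
  stopifnot(n > 0, deadtime >= 0, atp >= 0, om >= 0)
  set.seed(seed)
  k_free <- detachment_rate_atp(atp, scheme)
  p_om <- om / (om + scheme$om_kd)
  accept <- p_om * exp(-scheme$k_om_detach * deadtime) +
    (1 - p_om) * exp(-k_free * deadtime)
  if (accept < 0.01) {
    stop("sample_dwells: degenerate configuration, deadtime censors > 99% of events")
  }
  dur <- numeric(0)
  omb <- logical(0)
  while (length(dur) < n) {
    m <- ceiling((n - length(dur)) / accept * 1.2) + 10L
    is_om <- stats::runif(m) < p_om
    d <- ifelse(is_om, stats::rexp(m, scheme$k_om_detach),
                stats::rexp(m, k_free))
    keep <- d >= deadtime
    dur <- c(dur, d[keep])
    omb <- c(omb, is_om[keep])
  }
  dur <- dur[seq_len(n)]
  omb <- omb[seq_len(n)]
  out <- data.frame(
    molecule_id = paste0("mol", rep_len(seq_len(n_molecules), n)),
    atp_uM = atp, om_nM = om, om_bound = omb, duration = dur
  )
  class(out) <- c("dwell_dataset", "data.frame")
  attr(out, "deadtime") <- deadtime
  out
}

#' Sample working-stroke amplitudes from a two-Gaussian mixture
#'
#' Per drug concentration, step amplitudes are drawn from
#' `fraction * N(mean_full, sd) + (1 - fraction) * N(mean_zero, sd)`,
#' the two-population model in which drug-free interactions produce a full
#' working stroke and drug-bound interactions essentially none.
#'
#' @param mix_means Length-2 numeric: means of the full-stroke and
#'   zero-stroke components (nm).
#' @param mix_sd Shared component standard deviation (nm).
#' @param om_concs Drug concentrations (nM), one dataset per value.
#' @param fractions Full-stroke fraction per concentration (same length as
#'   `om_concs`, each in \[0, 1\]).
#' @param n_per_conc Events per concentration.
#' @param seed Integer seed.
#' @param n_molecules Molecule labels per concentration.
#' @return A `step_dataset` data frame with columns `molecule_id`, `om_nM`,
#'   `step_nm`, `from_full` (ground-truth component).
#' @export
sample_steps <- function(mix_means = c(5.46, 0.18), mix_sd = 7.5,
                         om_concs = c(0, 50, 100, 200, 500, 10000),
                         fractions = langmuir_fraction(om_concs, 101,
                                                       complement = TRUE),
                         n_per_conc = 500L, seed = 1L, n_molecules = 5L) {
  stopifnot(length(mix_means) == 2L, mix_sd > 0,
            length(fractions) == length(om_concs),
            all(fractions >= 0 & fractions <= 1), n_per_conc > 0)
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(om_concs), function(i) {
    full <- stats::runif(n_per_conc) < fractions[i]
    step <- stats::rnorm(n_per_conc,
                         mean = ifelse(full, mix_means[1L], mix_means[2L]),
                         sd = mix_sd)
    data.frame(
      molecule_id = paste0("mol", rep_len(seq_len(n_molecules), n_per_conc)),
      om_nM = om_concs[i], step_nm = step, from_full = full
    )
  }))
  class(out) <- c("step_dataset", "data.frame")
  out
}

#' Sample isometric-feedback events obeying the Bell equation
#'
#' Draws (force, duration) pairs as produced by an isometric feedback
#' experiment: forces from a stated distribution (default uniform) and
#' durations exponential at the force-dependent rate
#' `k(F) = k0 * exp(-F * d / kT)`, left-truncated at the deadtime.
#'
#' @param bell Length-2 numeric `c(k0, d)`: unloaded rate (s^-1) and distance
#'   parameter (nm).
#' @param force_range Length-2 numeric: bounds of the uniform force law (pN).
#' @param n Number of events.
#' @param deadtime Minimum duration (s); durations are `deadtime + Exp(k(F))`.
#' @param seed Integer seed.
#' @param kT Thermal energy (pN nm).
#' @param n_molecules Molecule labels.
#' @return Data frame with columns `molecule_id`, `force_pN`, `duration_s`.
#' @export
sample_isometric_events <- function(bell = c(k0 = 89, d = 1.3),
                                    force_range = c(-1, 7),
                                    n = 600L, deadtime = 0, seed = 1L,
                                    kT = 4.05, n_molecules = 4L) {
  stopifnot(n > 0, length(bell) == 2L, bell[1L] > 0, deadtime >= 0, kT > 0)
  k0 <- bell[[1L]]; d <- bell[[2L]]
  fmax <- max(abs(force_range))
  if (!is.finite(k0 * exp(fmax * abs(d) / kT))) {
    stop("sample_isometric_events: distance parameter overflows the rate scale")
  }
  set.seed(seed)
  force <- stats::runif(n, force_range[1L], force_range[2L])
  k <- k0 * exp(-force * d / kT)
  data.frame(
    molecule_id = paste0("mol", rep_len(seq_len(n_molecules), n)),
    force_pN = force,
    duration_s = deadtime + stats::rexp(n, k)
  )
}
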