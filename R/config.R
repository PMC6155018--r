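#' Kinetic scheme for synthetic actomyosin events
#'
#' Bundles the detachment and arrival kinetics used by the synthetic-data
#' generators. Rates describe a two-pathway picture of actomyosin detachment:
#' drug-free heads detach through ADP release followed by ATP binding, so the
#' observed single-exponential detachment rate is ATP dependent
#' (second order `k_atp_binding` at low MgATP, saturating at `k_adp`), while
#' drug-bound heads detach at a slow, ATP- and force-independent rate
#' `k_om_detach`.
#'
#' @param k_atp_binding Apparent second-order rate constant for ATP-induced
#'   detachment at low MgATP (uM^-1 s^-1). Default 3.0.
#' @param k_adp Rate-limiting detachment rate at saturating MgATP (s^-1),
#'   i.e. ADP release. Default 47.7.
#' @param k_om_detach Detachment rate of drug-bound heads (s^-1). Default 9.4.
#' @param k_attach Event arrival rate while unbound (s^-1). Default 0.8.
#' @param om_kd Dissociation constant governing the probability that a given
#'   binding event occurs with the drug bound, `om / (om + om_kd)` (nM).
#'   Default 100.
#' @param bell_k0 Unloaded detachment rate for the Bell equation (s^-1).
#'   Default 89.
#' @param bell_d Bell distance parameter (nm). Default 1.3.
#' @param substep2_rate Rate at which an attached drug-free head completes its
#'   second working-stroke substep (ADP release as seen in the displacement
#'   record, s^-1). Default 52.
#' @param rigor_exit_rate Saturating rate of detachment once the second substep
#'   has completed (s^-1); the ATP pathway `k_atp_binding * atp` is capped by
#'   this value inside a trace. Default 500.
#' @return An object of class `kinetic_scheme` (a validated list).
#' @export
kinetic_scheme <- function(k_atp_binding = 3.0,
                           k_adp = 47.7,
                           k_om_detach = 9.4,
                           k_attach = 0.8,
                           om_kd = 100,
                           bell_k0 = 89,
                           bell_d = 1.3,
                           substep2_rate = 52,
                           rigor_exit_rate = 500) {
  ks <- list(
    k_atp_binding = k_atp_binding, k_adp = k_adp,
    k_om_detach = k_om_detach, k_attach = k_attach, om_kd = om_kd,
    bell_k0 = bell_k0, bell_d = bell_d,
    substep2_rate = substep2_rate, rigor_exit_rate = rigor_exit_rate
  )
  rates <- unlist(ks)
  if (!all(is.finite(rates))) stop("kinetic_scheme: all rates must be finite")
  if (any(rates[names(rates) != "bell_d"] < 0)) {
    stop("kinetic_scheme: rates must be >= 0")
  }
  if (om_kd <= 0) stop("kinetic_scheme: om_kd must be > 0")
  structure(ks, class = "kinetic_scheme")
}

#' Effective drug-free detachment rate at a given MgATP concentration
#'
#' Linear in ATP at low concentrations (`k_atp_binding * atp`) and saturating
#' at `k_adp`; the two regimes are joined by a sharp minimum so the low-ATP
#' branch stays exactly linear up to the crossover.
#'
#' @param atp MgATP concentration (uM).
#' @param scheme A [kinetic_scheme()].
#' @return Detachment rate (s^-1).
#' @export
detachment_rate_atp <- function(atp, scheme = kinetic_scheme()) {
  stopifnot(atp >= 0)
  pmin(scheme$k_atp_binding * atp, scheme$k_adp)
}

#' Configuration for the synthetic dumbbell-trace generator
#'
#' @param sample_rate Sampling rate (Hz). Default 50e3 (configurable up to the
#'   experimental 250e3).
#' @param duration Trace length (s).
#' @param trap_stiffness Stiffness of each optical trap (pN nm^-1).
#' @param bead_drag Viscous drag coefficient of one bead (pN s nm^-1).
#' @param myosin_stiffness Effective crossbridge stiffness added to the shared
#'   (filament) mode while a head is bound (pN nm^-1).
#' @param kT Thermal energy (pN nm); 4.05 corresponds to 20 C. Set to 0 for
#'   noiseless traces in tests.
#' @param substep1,substep2 Working-stroke substep amplitudes (nm).
#' @param rise_time First-order response time applied to programmed
#'   displacements (s).
#' @param atp_conc MgATP concentration (uM).
#' @param om_conc Drug concentration (nM).
#' @param kinetics A [kinetic_scheme()].
#' @param noise_partition Fraction of each bead's unbound positional variance
#'   carried by the shared (filament) mode; strictly between 0 and 1.
#' @param seed Integer seed consumed by [generate_trace()].
#' @return An object of class `trap_sim_config`.
#' @export
trap_sim_config <- function(sample_rate = 50e3,
                            duration = 60,
                            trap_stiffness = 0.07,
                            bead_drag = 5e-6,
                            myosin_stiffness = 1.0,
                            kT = 4.05,
                            substep1 = 4.2,
                            substep2 = 1.5,
                            rise_time = 1e-3,
                            atp_conc = 4000,
                            om_conc = 0,
                            kinetics = kinetic_scheme(),
                            noise_partition = 0.6,
                            seed = 1L) {
  cfg <- list(
    sample_rate = sample_rate, duration = duration,
    trap_stiffness = trap_stiffness, bead_drag = bead_drag,
    myosin_stiffness = myosin_stiffness, kT = kT,
    substep1 = substep1, substep2 = substep2, rise_time = rise_time,
    atp_conc = atp_conc, om_conc = om_conc, kinetics = kinetics,
    noise_partition = noise_partition, seed = as.integer(seed)
  )
  num <- unlist(cfg[setdiff(names(cfg), "kinetics")])
  if (!all(is.finite(num))) stop("trap_sim_config: non-finite field")
  if (sample_rate <= 0) stop("trap_sim_config: sample_rate must be > 0")
  if (trap_stiffness <= 0 || myosin_stiffness <= 0 || bead_drag <= 0) {
    stop("trap_sim_config: stiffnesses and drag must be > 0")
  }
  if (kT < 0) stop("trap_sim_config: kT must be >= 0")
  if (noise_partition <= 0 || noise_partition >= 1) {
    stop("trap_sim_config: noise_partition must lie strictly in (0, 1)")
  }
  n <- sample_rate * duration
  if (abs(n - round(n)) > 1e-8) {
    stop("trap_sim_config: duration * sample_rate must be a whole number of samples")
  }
  if (!inherits(kinetics, "kinetic_scheme")) {
    stop("trap_sim_config: kinetics must be a kinetic_scheme")
  }
  structure(cfg, class = "trap_sim_config")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Actomyosin kinetic scheme\n")
  cat(sprintf("  ATP-induced detachment : %.3g uM^-1 s^-1 (saturating at %.3g s^-1)\n",
              x$k_atp_binding, x$k_adp))
  cat(sprintf("  drug-bound detachment  : %.3g s^-1   arrival: %.3g s^-1\n",
              x$k_om_detach, x$k_attach))
  cat(sprintf("  drug Kd                : %.3g nM\n", x$om_kd))
  cat(sprintf("  Bell k0, d             : %.3g s^-1, %.3g nm\n", x$bell_k0, x$bell_d))
  invisible(x)
}

#' @export
print.trap_sim_config <- function(x, ...) {
  cat("Dumbbell trace simulation config\n")
  cat(sprintf("  %.0f s at %.0f kHz, trap %.3g pN/nm, kT %.3g pN nm\n",
              x$duration, x$sample_rate / 1e3, x$trap_stiffness, x$kT))
  cat(sprintf("  substeps %.2f + %.2f nm, ATP %.3g uM, drug %.3g nM, seed %d\n",
              x$substep1, x$substep2, x$atp_conc, x$om_conc, x$seed))
  invisible(x)
}
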