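#' Configuration of the thin-filament crossbridge ensemble simulator
#'
#' Parameterizes a modified-Gillespie Monte Carlo of myosin heads (two states:
#' bound / unbound) interacting with one infinitely stiff thin filament.
#' Cooperative thin-filament activation lets heads near an already bound head
#' attach at the maximal rate `pi_release * eps_max`, decaying exponentially
#' with the distance to the nearest bound head (decay length `decay_length`),
#' floored by a calcium-set baseline availability `eps_min(Ca)`. Drug-bound
#' heads are assigned per run from the Langmuir occupancy at the simulated
#' concentration (no exchange during a run) and may differ from drug-free
#' heads in stroke size, detachment law and attachment-rate scale.
#'
#' @param n_heads Number of heads (default 75, three thick filaments).
#' @param spacing Axial spacing between heads (nm).
#' @param xb_stiffness Crossbridge stiffness (pN nm^-1).
#' @param kT Thermal energy (pN nm).
#' @param step_free Working stroke of drug-free heads (nm).
#' @param step_om Working stroke of drug-bound heads (nm, 0 by default).
#' @param pi_release_free,pi_release_om Attachment-rate scale (solution
#'   phosphate-release rate, s^-1) for drug-free and drug-bound heads; the
#'   drug roughly doubles it.
#' @param eps_max Maximal thin-filament availability (dimensionless, 1).
#' @param eps_min_max Availability at saturating calcium (defaults to
#'   `eps_max`).
#' @param decay_length Cooperativity decay length (nm). The default keeps an
#'   isolated cluster subcritical (two nearest neighbours recruited at
#'   `2 * eps_max * pi_release * exp(-spacing / decay_length)` must not
#'   outpace loaded detachment), so activation requires the calcium baseline
#'   and collapses at pCa 9.
#' @param ca_hill Length-2 numeric `c(K_Ca, n_H)`: half-activation calcium
#'   (molar) and Hill coefficient for the baseline availability.
#' @param detach_free Length-2 numeric `c(k0, d)`: Bell parameters of
#'   drug-free detachment (s^-1, nm).
#' @param detach_om Force-independent detachment rate of drug-bound heads
#'   (s^-1); used when the active model variant makes drug-bound detachment
#'   constant.
#' @param om_kd_motility,om_kd_myocyte Drug dissociation constants (nM) used
#'   to convert concentration to bound-head probability in the two modes.
#' @param n_steps Gillespie transitions per run.
#' @param n_runs Replicate runs per condition.
#' @param force_scale Constant factor applied when scaling simulated forces
#'   to experimental units (after passive-force subtraction).
#' @param seed Integer seed.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_heads = 75L, spacing = 14.3,
                            xb_stiffness = 1.0, kT = 4.05,
                            step_free = 5.4, step_om = 0,
                            pi_release_free = 15, pi_release_om = 30,
                            eps_max = 1.0, eps_min_max = eps_max,
                            decay_length = 15,
                            ca_hill = c(K_Ca = 2.3e-6, n_H = 1),
                            detach_free = c(k0 = 89, d = 1.3),
                            detach_om = 9.4,
                            om_kd_motility = 100, om_kd_myocyte = 1200,
                            n_steps = 1000L, n_runs = 200L,
                            force_scale = 0.306, seed = 1L) {
  cfg <- list(n_heads = as.integer(n_heads), spacing = spacing,
              xb_stiffness = xb_stiffness, kT = kT,
              step_free = step_free, step_om = step_om,
              pi_release_free = pi_release_free, pi_release_om = pi_release_om,
              eps_max = eps_max, eps_min_max = eps_min_max,
              decay_length = decay_length, ca_hill = ca_hill,
              detach_free = detach_free, detach_om = detach_om,
              om_detach_const = TRUE, om_bell = detach_free,
              om_kd_motility = om_kd_motility, om_kd_myocyte = om_kd_myocyte,
              n_steps = as.integer(n_steps), n_runs = as.integer(n_runs),
              force_scale = force_scale, seed = as.integer(seed))
  stopifnot(cfg$n_heads >= 1L, cfg$spacing > 0, cfg$xb_stiffness > 0,
            cfg$kT > 0, all(c(pi_release_free, pi_release_om, detach_om) >= 0),
            eps_min_max >= 0, eps_min_max <= eps_max + 1e-12,
            decay_length > 0, cfg$n_steps >= 1L, cfg$n_runs >= 1L)
  structure(cfg, class = "ensemble_config")
}

#' Model variants for the drug's mechanism of action
#'
#' Returns a copy of `config` with the drug-bound head behaviour overridden
#' to one of the candidate mechanisms:
#' \describe{
#'   \item{malik}{raised phosphate release only: full stroke, drug-bound
#'     detachment identical to drug-free (Bell).}
#'   \item{pta}{prolonged time of attachment: full stroke, slow
#'     force-independent detachment.}
#'   \item{se}{stroke eliminated: no stroke, detachment as drug-free.}
#'   \item{septa}{stroke eliminated + prolonged attachment: no stroke, slow
#'     force-independent detachment (the mechanism supported by the
#'     single-molecule measurements).}
#'   \item{fd}{10-fold increased force sensitivity: full stroke, Bell
#'     detachment with `d` scaled by 10.}
#'   \item{fd_pta}{10-fold force sensitivity and no stroke: Bell with
#'     `d * 10`, stroke eliminated.}
#' }
#' All variants keep the raised attachment-rate scale `pi_release_om`.
#'
#' @param name Variant name.
#' @param config Base [ensemble_config()].
#' @return The modified `ensemble_config`.
#' @export
model_variant <- function(name = c("septa", "malik", "pta", "se", "fd", "fd_pta"),
                          config = ensemble_config()) {
  name <- match.arg(name)
  k0 <- config$detach_free[[1L]]; d <- config$detach_free[[2L]]
  cfg <- config
  cfg$variant <- name
  switch(name,
    malik = { cfg$step_om <- cfg$step_free; cfg$om_detach_const <- FALSE
              cfg$om_bell <- c(k0 = k0, d = d) },
    pta = { cfg$step_om <- cfg$step_free; cfg$om_detach_const <- TRUE },
    se = { cfg$step_om <- 0; cfg$om_detach_const <- FALSE
           cfg$om_bell <- c(k0 = k0, d = d) },
    septa = { cfg$step_om <- 0; cfg$om_detach_const <- TRUE },
    fd = { cfg$step_om <- cfg$step_free; cfg$om_detach_const <- FALSE
           cfg$om_bell <- c(k0 = k0, d = 10 * d) },
    fd_pta = { cfg$step_om <- 0; cfg$om_detach_const <- FALSE
               cfg$om_bell <- c(k0 = k0, d = 10 * d) }
  )
  cfg
}

#' Assign drug-bound flags to heads
#'
#' Each head is independently drug-bound with probability
#' `om / (om + Kd)` where `Kd` is selected by mode; flags stay fixed for a
#' whole run (no exchange during a simulation).
#'
#' @param config An [ensemble_config()].
#' @param om_conc Drug concentration (nM); ignored when `om_fraction` given.
#' @param mode `"motility"` or `"myocyte"` (isometric).
#' @param om_fraction Optional explicit bound probability, bypassing the
#'   Langmuir conversion (used when sweeping occupancy directly).
#' @return Logical vector of length `n_heads`.
#' @export
assign_om <- function(config, om_conc, mode = c("myocyte", "motility"),
                      om_fraction = NULL) {
  mode <- match.arg(mode)
  p <- if (!is.null(om_fraction)) om_fraction else {
    kd <- if (mode == "motility") config$om_kd_motility else config$om_kd_myocyte
    langmuir_fraction(om_conc, kd)
  }
  stats::runif(config$n_heads) < p
}

# baseline availability at a calcium concentration (Hill function)
eps_min_at_ca <- function(config, pCa) {
  ca <- 10^(-pCa)
  K <- config$ca_hill[[1L]]; nH <- config$ca_hill[[2L]]
  config$eps_min_max * ca^nH / (ca^nH + K^nH)
}

# per-head transition rates for the current state; mirrors the C++ kernel
head_rates <- function(state, config, mode, eps_min_ca) {
  n <- config$n_heads
  pos <- (seq_len(n) - 1L) * config$spacing
  rates <- numeric(n)
  bound_pos <- pos[state$bound]
  for (i in seq_len(n)) {
    if (!state$bound[i]) {
      f_head <- if (state$om[i]) config$pi_release_om else config$pi_release_free
      eps <- if (mode == "motility") config$eps_max else {
        coop <- if (length(bound_pos)) {
          config$eps_max * exp(-min(abs(pos[i] - bound_pos)) / config$decay_length)
        } else 0
        max(eps_min_ca, coop)
      }
      rates[i] <- f_head * eps
    } else {
      r <- if (state$om[i]) {
        if (config$om_detach_const) config$detach_om else {
          F <- config$xb_stiffness * state$strain[i]
          config$om_bell[[1L]] * exp(-F * config$om_bell[[2L]] / config$kT)
        }
      } else {
        F <- config$xb_stiffness * state$strain[i]
        config$detach_free[[1L]] * exp(-F * config$detach_free[[2L]] / config$kT)
      }
      rates[i] <- min(r, 1e6)
    }
  }
  rates
}

#' Attachment rate of one unbound head
#'
#' `f_head * max(eps_min(Ca), eps_max * exp(-d_near / lambda))` where
#' `d_near` is the distance to the nearest bound head and `f_head` is the
#' (possibly drug-raised) phosphate-release scale; with regulation disabled
#' (motility mode) the rate is `f_head * eps_max` everywhere.
#'
#' @param head Head index (1-based), must be unbound.
#' @param state Simulation state (list with `bound`, `om`, `strain`).
#' @param config An [ensemble_config()].
#' @param eps_min_ca Calcium-set baseline availability.
#' @param mode `"isometric"` or `"motility"`.
#' @return Rate (s^-1).
#' @export
attachment_rate <- function(head, state, config, eps_min_ca = 0,
                            mode = "isometric") {
  stopifnot(!state$bound[head])
  head_rates(state, config, mode, eps_min_ca)[head]
}

#' Detachment rate of one bound head
#'
#' Drug-free heads follow the Bell equation
#' `k0 * exp(-F * d / kT)` with `F = xb_stiffness * strain` (positive =
#' resisting); drug-bound heads detach per the active model variant
#' (force-independent constant under the stroke-eliminated/prolonged
#' mechanism). Rates are clamped at 1e6 s^-1.
#'
#' @inheritParams attachment_rate
#' @return Rate (s^-1).
#' @export
detachment_rate <- function(head, state, config) {
  stopifnot(state$bound[head])
  head_rates(state, config, "isometric", 0)[head]
}

#' Initialize an ensemble simulation state
#'
#' @param config An [ensemble_config()].
#' @param om_flags Logical drug-bound flags (from [assign_om()]).
#' @return State list: `bound`, `om`, `strain`, `filament_pos`, `time`.
#' @export
init_state <- function(config, om_flags = rep(FALSE, config$n_heads)) {
  list(bound = rep(FALSE, config$n_heads), om = om_flags,
       strain = numeric(config$n_heads), filament_pos = 0, time = 0)
}

#' One modified-Gillespie transition (reference R implementation)
#'
#' Advances the state by one transition: time advances exponentially at the
#' instantaneous total rate, the transition is chosen proportionally to the
#' per-head rates, attaching heads draw a thermal strain
#' `N(0, sqrt(kT / xb_stiffness))` plus their working stroke, and in motility
#' mode the filament repositions after every transition so the net spring
#' force is zero. The random draw order matches the compiled kernel exactly,
#' so both produce identical trajectories from the same seed.
#'
#' @param state State from [init_state()].
#' @param config An [ensemble_config()].
#' @param mode `"isometric"` or `"motility"`.
#' @param eps_min_ca Calcium-set baseline availability (isometric mode).
#' @return The updated state; `state$absorbed` is set when the total rate is
#'   zero (nothing bound and no baseline activation).
#' @export
gillespie_step <- function(state, config, mode = "isometric", eps_min_ca = 0) {
  rates <- head_rates(state, config, mode, eps_min_ca)
  R <- sum(rates)
  if (R <= 0) { state$absorbed <- TRUE; return(state) }
  u1 <- stats::runif(1L)
  state$time <- state$time - log(u1) / R
  u2 <- stats::runif(1L)
  pick <- which(u2 * R <= cumsum(rates))[1L]
  if (!state$bound[pick]) {
    z <- stats::rnorm(1L)
    s <- z * sqrt(config$kT / config$xb_stiffness) +
      if (state$om[pick]) config$step_om else config$step_free
    state$bound[pick] <- TRUE
    state$strain[pick] <- s
  } else {
    state$bound[pick] <- FALSE
    state$strain[pick] <- 0
  }
  if (mode == "motility" && any(state$bound)) {
    delta <- mean(state$strain[state$bound])
    state$strain[state$bound] <- state$strain[state$bound] - delta
    state$filament_pos <- state$filament_pos + delta
  }
  state
}

run_ensemble <- function(config, om_conc, mode, pCa = NA, om_fraction = NULL,
                         seed = config$seed) {
  set.seed(seed)
  eps_min_ca <- if (mode == "motility") 0 else {
    if (is.null(attr(config, "eps_min_ca_override"))) {
      eps_min_at_ca(config, pCa)
    } else attr(config, "eps_min_ca_override")
  }
  kd_mode <- if (mode == "motility") "motility" else "myocyte"
  res <- vapply(seq_len(config$n_runs), function(r) {
    om_flags <- assign_om(config, om_conc, kd_mode, om_fraction)
    out <- gillespie_run_cpp(
      config$n_heads, config$spacing, om_flags, config$n_steps,
      if (mode == "motility") 1L else 0L,
      config$pi_release_free, config$pi_release_om,
      config$eps_max, eps_min_ca, config$decay_length,
      config$xb_stiffness, config$kT,
      config$step_free, config$step_om,
      config$detach_free[[1L]], config$detach_free[[2L]],
      as.integer(config$om_detach_const), config$detach_om,
      config$om_bell[[1L]], config$om_bell[[2L]]
    )
    c(velocity = if (out$time > 0) out$filament_pos / out$time else 0,
      force = out$mean_force_last_half,
      bound = out$bound_fraction, om_bound = out$om_bound_fraction,
      imbalance = out$max_force_imbalance, absorbed = out$absorbed)
  }, numeric(6))
  structure(list(
    mode = mode, om_conc = om_conc, pCa = pCa, om_fraction = om_fraction,
    velocity = res["velocity", ], force = res["force", ],
    mean_velocity = mean(res["velocity", ]), sd_velocity = stats::sd(res["velocity", ]),
    mean_force = mean(res["force", ]), sd_force = stats::sd(res["force", ]),
    bound_fraction = mean(res["bound", ]),
    om_bound_fraction = mean(res["om_bound", ]),
    max_force_imbalance = max(res["imbalance", ]),
    n_absorbed = sum(res["absorbed", ]),
    config = config
  ), class = "sim_result")
}

#' Simulate unloaded filament gliding (motility mode)
#'
#' Runs `n_runs` independent replicates without thin-filament regulation;
#' the filament repositions to zero net force after every transition and the
#' velocity is the total distance travelled divided by the elapsed time.
#'
#' @param config An [ensemble_config()] (possibly via [model_variant()]).
#' @param om_conc Drug concentration (nM); occupancy uses `om_kd_motility`.
#' @param seed Seed.
#' @return A `sim_result` with `mean_velocity`, `sd_velocity` (nm s^-1) and
#'   per-run values.
#' @export
run_motility <- function(config, om_conc = 0, seed = config$seed) {
  run_ensemble(config, om_conc, "motility", seed = seed)
}

#' Simulate isometric force production (myocyte mode)
#'
#' The filament is held fixed; calcium sets the baseline thin-filament
#' availability through the Hill function in the config, and the mean total
#' spring force over the final half of the transitions is recorded.
#'
#' @param config An [ensemble_config()].
#' @param om_conc Drug concentration (nM); occupancy uses `om_kd_myocyte`.
#' @param pCa -log10 calcium concentration.
#' @param om_fraction Optional explicit drug-bound head probability
#'   (bypasses the Langmuir conversion).
#' @param eps_min_ca Optional explicit baseline availability overriding the
#'   calcium Hill function.
#' @param seed Seed.
#' @return A `sim_result` with `mean_force`, `sd_force` (pN, unscaled) and
#'   per-run values.
#' @export
run_isometric <- function(config, om_conc = 0, pCa = 6.4, om_fraction = NULL,
                          eps_min_ca = NULL, seed = config$seed) {
  if (!is.null(eps_min_ca)) attr(config, "eps_min_ca_override") <- eps_min_ca
  run_ensemble(config, om_conc, "isometric", pCa = pCa,
               om_fraction = om_fraction, seed = seed)
}

#' Scale simulated forces to experimental units
#'
#' Subtracts the simulated passive force (0 drug, pCa 9) and multiplies by
#' the constant calibration factor; the same factor applies across all
#' conditions.
#'
#' @param raw_forces Simulated forces (pN).
#' @param passive_ref Simulated force at pCa 9 with no drug, same config.
#' @param config An [ensemble_config()] (supplies `force_scale`).
#' @return Scaled forces.
#' @export
scale_force <- function(raw_forces, passive_ref, config) {
  (raw_forces - passive_ref) * config$force_scale
}

#' Factorial sweep over drug and calcium grids
#'
#' @param config An [ensemble_config()].
#' @param variant Variant name passed to [model_variant()].
#' @param om_grid Drug concentrations (nM); or `NULL`.
#' @param pCa_grid pCa values (isometric mode only).
#' @param mode `"isometric"` or `"motility"`.
#' @param om_fraction_grid Optional explicit occupancy grid replacing
#'   `om_grid`.
#' @param seed Base seed; each cell derives its own.
#' @return Tidy data frame: `variant`, `om_nM` (or `om_fraction`), `pCa`,
#'   `mean_velocity`/`mean_force` with SDs, `bound_fraction`,
#'   `om_bound_fraction`.
#' @export
sweep_conditions <- function(config, variant = "septa", om_grid = 0,
                             pCa_grid = NA, mode = c("isometric", "motility"),
                             om_fraction_grid = NULL, seed = config$seed) {
  mode <- match.arg(mode)
  cfg <- model_variant(variant, config)
  use_frac <- !is.null(om_fraction_grid)
  oms <- if (use_frac) om_fraction_grid else om_grid
  grid <- expand.grid(om = oms, pCa = pCa_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell_seed <- (seed + 7919L * i) %% .Machine$integer.max
    res <- if (mode == "motility") {
      run_motility(cfg, grid$om[i], seed = cell_seed)
    } else {
      run_isometric(cfg,
                    om_conc = if (use_frac) 0 else grid$om[i],
                    pCa = grid$pCa[i],
                    om_fraction = if (use_frac) grid$om[i] else NULL,
                    seed = cell_seed)
    }
    data.frame(variant = variant,
               om_nM = if (use_frac) NA_real_ else grid$om[i],
               om_fraction = if (use_frac) grid$om[i] else NA_real_,
               pCa = grid$pCa[i],
               mean_velocity = res$mean_velocity, sd_velocity = res$sd_velocity,
               mean_force = res$mean_force, sd_force = res$sd_force,
               bound_fraction = res$bound_fraction,
               om_bound_fraction = res$om_bound_fraction)
  })
  do.call(rbind, rows)
}

#' Calibrate the calcium baseline to a target fractional activation
#'
#' Bisects the baseline availability scale `m` (so that
#' `eps_min = m * eps_max`) until the zero-drug isometric force equals
#' `target_activation` times the force at saturating calcium
#' (`eps_min = eps_max`). Also returns the implied half-activation calcium
#' `K_Ca` placing that availability at `pCa_ref` with the config's Hill
#' coefficient.
#'
#' @param config An [ensemble_config()].
#' @param target_activation Fraction of maximal force (0-1).
#' @param pCa_ref Reference pCa the calibration is anchored to.
#' @param tol Convergence tolerance as a fraction of the target force.
#' @param max_iter Bisection iteration cap.
#' @param seed Seed (shared by every bisection evaluation so the force map
#'   is deterministic in `m`).
#' @return List with `eps_min_scale`, `K_Ca` (molar), `force_target`,
#'   `force_achieved`, `force_max`.
#' @export
calibrate_eps_min <- function(config, target_activation = 0.15, pCa_ref = 6.4,
                              tol = 0.01, max_iter = 30L, seed = config$seed) {
  stopifnot(target_activation > 0, target_activation <= 1)
  force_at <- function(m) {
    run_isometric(config, om_conc = 0, eps_min_ca = m * config$eps_max,
                  seed = seed)$mean_force
  }
  f_max <- force_at(1)
  target <- target_activation * f_max
  if (target_activation >= 1) {
    return(list(eps_min_scale = 1, K_Ca = 0, force_target = target,
                force_achieved = f_max, force_max = f_max))
  }
  lo <- 0; hi <- 1
  f_lo <- force_at(1e-6)
  if (f_lo > target) stop("calibrate_eps_min: target unreachable (floor force too high)")
  m <- 0.5; f_m <- NA
  for (it in seq_len(max_iter)) {
    m <- (lo + hi) / 2
    f_m <- force_at(m)
    if (abs(f_m - target) <= tol * target) break
    if (f_m > target) hi <- m else lo <- m
  }
  nH <- config$ca_hill[[2L]]
  ca_ref <- 10^(-pCa_ref)
  scale_rel <- m * config$eps_max / config$eps_min_max
  scale_rel <- min(max(scale_rel, 1e-12), 1 - 1e-12)
  K_Ca <- ca_ref * ((1 - scale_rel) / scale_rel)^(1 / nH)
  list(eps_min_scale = m, K_Ca = K_Ca, force_target = target,
       force_achieved = f_m, force_max = f_max)
}

#' Apply a calcium calibration to a config
#'
#' Sets `K_Ca` so the baseline availability at `pCa_ref` equals the
#' calibrated `eps_min_scale * eps_max`.
#'
#' @param config An [ensemble_config()].
#' @param calibration Result of [calibrate_eps_min()].
#' @return The updated config.
#' @export
apply_calibration <- function(config, calibration) {
  config$ca_hill[[1L]] <- calibration$K_Ca
  config
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Ensemble simulation (%s): %d runs x %d steps, %d heads\n",
              x$mode, x$config$n_runs, x$config$n_steps, x$config$n_heads))
  if (x$mode == "motility") {
    cat(sprintf("  velocity: %.1f +/- %.1f nm/s\n", x$mean_velocity, x$sd_velocity))
  } else {
    cat(sprintf("  force (last half): %.2f +/- %.2f pN, bound fraction %.2f\n",
                x$mean_force, x$sd_force, x$bound_fraction))
  }
  invisible(x)
}
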