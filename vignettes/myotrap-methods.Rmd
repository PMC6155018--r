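---
title: "Models and methods behind myotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myotrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrap)
```

# What the package models

Omecamtiv mecarbil (OM) is a small-molecule cardiac inotrope that binds
beta-cardiac myosin. In single-molecule optical trapping, its two signatures
are a suppressed working stroke (the ~5.4 nm displacement of an actin
filament per attachment collapses to ~0.4 nm) and a roughly five-fold
prolonged, force- and ATP-independent attachment. `myotrap` implements the
analysis chain by which such measurements are made and interpreted, plus an
ensemble simulator that connects them to muscle-level behaviour:

1. a synthetic-data generator for dumbbell (three-bead) trap records with
   known ground truth,
2. covariance-based binding-event detection with step and force measurement,
3. time-forward/backward ensemble averaging of the working stroke,
4. weighted maximum-likelihood fitting of deadtime-censored dwell-time and
   step-size mixtures, Bell-equation force dependence, and bootstrap CIs,
5. three-parameter EC50 dose-response fits, and
6. a modified-Gillespie Monte Carlo of 75 myosin heads on one cooperatively
   activated thin filament.

Everything below states the model actually implemented, the defaults and
their units, and the choices made where the design was genuinely open.

# The synthetic dumbbell trace

Each bead position is the sum of a *shared* (filament) mode and a
bead-specific mode, both Ornstein-Uhlenbeck (OU) processes. The discrete
update is exact - an AR(1) with coefficient `exp(-dt/tau)` and the
stationary innovation variance - so autocorrelation is correct at any sample
rate (default 50 kHz; the hardware-faithful 250 kHz is configurable but
five-fold more expensive for no statistical gain in these analyses).

The shared mode sees stiffness `2 * trap_stiffness` when unbound (two traps
in parallel; default 0.07 pN/nm per trap) plus `myosin_stiffness` (default
1 pN/nm) while a head is bound. Binding therefore drops the shared-mode
variance, and with it the inter-bead covariance - the detection signature.
`noise_partition` (default 0.6) sets the fraction of each bead's unbound
variance carried by the shared mode. The thermal scale is `kT = 4.05 pN nm`
(20 degrees C) everywhere, including the Bell fits; setting `kT = 0` gives
noiseless traces used by the exactness tests.

Events arrive at `k_attach` (default 0.8 s^-1) while unbound. Each event is
drug-bound with Langmuir probability `om / (om + om_kd)`. Drug-free events
displace both beads by `substep1 = 4.2 nm` at attachment and `substep2 =
1.5 nm` at an internal time; drug-bound events displace nothing. Programmed
displacements rise with a first-order response (`rise_time`, default 1 ms)
and decay after detachment at the much faster trap relaxation time
`bead_drag / trap_stiffness` (~0.07 ms): the filament is dragged by the
myosin but springs back on release.

**Dwell-time model.** Drug-free detachment is linear in MgATP at low
concentrations (`k_atp_binding = 3.0 uM^-1 s^-1`) and saturates at `k_adp =
47.7 s^-1`; the package joins the regimes with a sharp minimum,
`k(ATP) = min(k_atp_binding * ATP, k_adp)`. A hyperbolic (series-resistor)
interpolation was considered and rejected: with a 47.7 s^-1 ceiling it bends
the 0.2-10 uM range visibly (18 rather than 30 s^-1 at 10 uM), contradicting
the observed linearity of the low-ATP detachment rates that the recovery
analyses verify. Drug-bound events detach at `k_om_detach = 9.4 s^-1`
regardless of ATP.

**Substep timing.** The second displacement completes through whichever
pathway commits first: ADP release (`substep2_rate = 52 s^-1`) or the
ATP-driven completion whose rate saturates at `rigor_exit_rate = 500 s^-1`.
At 200 nM MgATP the second substep therefore lands ~20 ms after attachment -
slow enough that start-aligned ensemble averages resolve an initial ~4.2 nm
level, and long post-stroke dwells make end-aligned averages read the full
5.7 nm. At 4 mM it lands ~2 ms after attachment, so per-event step
measurements read the full stroke while a distinct second step is no longer
resolvable. This is the one place where two printed observations (an early
plateau at low ATP, full-stroke event measurements at saturating ATP) pin
the generator more tightly than any single mechanistic scheme; the race
between the two completion pathways is the simplest model satisfying both.

# Event detection

`sliding_covariance()` computes the sample covariance of the two bead force
(or position) signals over a centred window of odd sample count (default
10 ms; 8 ms at saturating ATP, 15 ms at sub-micromolar ATP), in O(n) via
running sums. Edge samples without a full window carry no value.

`covariance_threshold()` fits the covariance distribution with a
two-component Gaussian mixture. Because bound samples can be a small
minority (a few percent of a saturating-ATP record), default mixture inits
tend to split the dominant unbound peak; the implementation instead runs EM
(mclust, model "V") from two provisional splits - mid-range and low-tail -
and keeps the higher-likelihood solution. The detection threshold minimizes
the summed misclassification areas of the weighted component densities.
Traces whose fitted components either collapse (means within 0.1 pooled SD)
or overlap beyond separability (Ashman's D < 2) are reported as "no events
detectable" rather than thresholded.

`detect_events()` takes maximal below-threshold intervals, interpolates the
threshold crossings linearly between samples (ties toward the earlier
sample), and discards events shorter than the deadtime
`deadtime_factor * window` (default factor 2, i.e. 16 ms at an 8 ms window,
30 ms at 15 ms - shrinking the window never lengthens the deadtime).

**Finite-window boundary bias and measurement-window placement.** A detected
boundary can sit up to half a covariance window inside the true event,
because the crossing fires once enough of the window has changed state.
Worse, samples *inside* the covariance window at the crossing are correlated
with the crossing time itself, so any measurement window within half a
window of a detected boundary inherits a selection offset (empirically up to
~1 nm on the post-event baseline). `analyze_trace()` therefore places the
1 ms pre-dissociation window at `max(7 ms, window/2 + 2.5 ms)` before the
detected end and the 1 ms baseline at `max(4 ms, window/2 + 2 ms)` after it.
At the 8 ms window these reduce to the conventional 7 ms / 4 ms placements;
at 15 ms they move just outside the window's reach. An explicit
boundary-shift correction was tried and rejected: it inflates noise
excursions past the deadtime filter.

The total stroke of one event is the pre-dissociation mean minus the
baseline mean of the bead-averaged displacement; the event force averages
the motor-bead force over the event interior (2 ms margins) minus the same
baseline convention. Under isometric feedback, brief covariance transients
that split one interaction in two are pruned by the standard two-clause
rule: an unbound gap shorter than two windows whose motor force never
returns within one baseline SD of baseline is merged.

# Ensemble averaging

`ensemble_average()` aligns events at their detected start or end and
averages the bead-averaged displacement with per-molecule equal weighting
(each molecule's events share `1/n_events` weight). Events shorter than the
horizon contribute only their extent (running-count normalization; no tail
interpolation). `extract_substeps()` reads the first substep from the
start-aligned plateau 5-15 ms after attachment, the total from the
end-aligned level just before detachment minus the post-detachment
baseline, and the second substep as the difference. With the generator's
52 s^-1 substep completion at low ATP, the 5-15 ms plateau carries some
second-substep contamination (~0.5 nm high on average); the total is the
robust quantity, and the recovery tests treat it as such.

# Maximum-likelihood fitting

All dwell likelihoods are left-truncated at the deadtime: the single
exponential `f(t) = k exp(-k (t - tmin))` has the weighted closed form
`k = sum(w) / sum(w (t - tmin))`; mixtures are maximized by Nelder-Mead
simplex from deterministic multi-starts (rate ratios 2-16, fractions
0.25-0.75; log/logit parameterization; reltol 1e-10); component labels
follow `k_a >= k_b`. Weights make each molecule (and, in global fits, each
condition) contribute equally while summing to the number of points, so
weighted and unweighted log-likelihoods are directly comparable. Global
dwell fits share both rates across drug concentrations and free the
per-condition slow fraction; note the fitted fractions are post-censoring
mixture weights (censoring enriches the slow component), exactly as for any
truncated-mixture fit to deadtime-limited data.

The step-size model is a two-Gaussian mixture with means and widths shared
across concentrations and per-condition full-stroke fractions. It is
maximized by a weighted EM with shared M-steps, polished by the simplex.
With component separation (~5.3 nm) below the widths (~7.5 nm), single
conditions cannot justify two components; only the pooled multi-condition
likelihood identifies the shared means, and even then the (means, fractions)
profile has a near-ridge: at 500 events per condition the larger mean has a
sampling SD of ~0.55 nm and the minority fraction at the highest
concentration ~0.12-0.14 absolute. The recovery tests assert at ~2.5 sigma
of that measured spread; consistency was verified separately at 8000 events
per condition, where the fit recovers the generating parameters essentially
exactly. A single shared width for both components is available
(`shared_sd = TRUE`) but widens the ridge and is not the default.

The Bell fit maximizes the unbinned likelihood of durations with per-event
rates `k0 exp(-F d / kT)` (kT fixed, `|d| <= 20 nm` box to prevent
overflow), and reports a Wilks chi-square LLR p-value against the `d = 0`
truncated-exponential null, whose closed form also serves as the nested
log-likelihood. Bootstrap CIs resample events with replacement *within each
molecule* (the resampling unit is a design choice; within-molecule
resampling preserves the molecule-weighting structure), with 200-500 rounds
and 2.5/97.5 percentiles; refit failures are dropped and counted, with a
warning status above 10%.

`fit_exp_plus_linear()` (stopped-flow transients) profiles the rate over a
linear least-squares solve of amplitude, slope and offset - exact separable
least squares rather than a 4-parameter search.

# Dose-response

`fit_ec50()` fits `y(c) = Max + (Min - Max) c / (c + EC50)` (Hill slope 1)
by Levenberg-Marquardt (minpack.lm), optionally weighted by `1/SE^2`, with
the EC50 standard error from the fit covariance. Concentration zero is in
the model's domain, so no log transform is needed. Degenerate (constant)
responses are flagged by an AIC comparison against the constant model. The
fit is exactly scale-equivariant in concentration.

# The crossbridge ensemble simulator

Seventy-five heads spaced 14.3 nm apart interact with one infinitely stiff
thin filament; heads are bound or unbound, ATP hydrolysis is not resolved.
Per Gillespie step, the time advance is exponential at the summed rates and
one head transitions. Attaching heads draw thermal strain
`N(0, sqrt(kT / xb_stiffness))` plus their working stroke (5.4 nm drug-free;
0 under stroke-eliminating variants). Detachment is Bell
(`k0 = 89 s^-1, d = 1.3 nm`) for drug-free heads and, under the
stroke-eliminated/prolonged-attachment (SEPTA) mechanism, a constant
9.4 s^-1 for drug-bound heads. Drug occupancy is assigned per head per run
from the Langmuir isotherm (Kd 100 nM for motility, 1.2 uM for myocyte
simulations) and never exchanges within a run. In motility mode the
filament repositions after every transition so the net spring force is zero
(verified to 1e-9 pN) and velocity is distance over elapsed time; in
isometric mode the filament is fixed and force is the sojourn-time-weighted
mean of the total spring force over the final half of the steps.

Cooperative activation: an unbound head attaches at
`f * max(eps_min(Ca), eps_max * exp(-d_near / lambda))`, with `f` the
solution phosphate-release scale (15 s^-1 drug-free, 30 s^-1 drug-bound -
the drug roughly doubles phosphate release), `d_near` the distance to the
nearest bound head, and `eps_min(Ca)` a Hill function of calcium (nH = 1 by
default; the simulated force-pCa relation is accordingly shallower than
permeabilized-myocyte data, a known limitation of this activation model).
The decay length `lambda` defaults to 15 nm, chosen so that an isolated
cluster is *subcritical*: with two nearest neighbours recruited at
`2 * f * eps_max * exp(-spacing / lambda) ~ 11.6 s^-1` against loaded
detachment ~16 s^-1, clusters need the calcium baseline to persist and the
filament switches off at pCa 9. At 30 nm the same algebra crosses unity and
a single ignition event self-sustains indefinitely, which destroys the
passive-force control condition; the knob is exposed for sensitivity
analyses.

`calibrate_eps_min()` bisects the baseline availability until the zero-drug
force at a reference pCa (6.4) is a target fraction (15%) of the force at
saturating availability, then back-solves the Hill `K_Ca`; a fixed seed per
evaluation makes the force map deterministic in the bisection variable.
Forces reported against experimental data are scaled by subtracting the
simulated passive force (pCa 9, no drug) and multiplying by the constant
0.306, one factor for all conditions.

Six drug-mechanism variants are provided (`model_variant()`): raised
phosphate release only ("malik"), prolonged attachment ("pta"), stroke
eliminated ("se"), both ("septa"), and ten-fold increased force sensitivity
with and without the stroke ("fd", "fd_pta"). Under SEPTA at 15% activation
the simulated isometric force is biphasic in drug occupancy with its peak
near 25-30% drug-bound heads and collapse at saturation; the
phosphate-release-only variant rises monotonically and leaves gliding
velocity flat; SEPTA cuts saturating-drug gliding velocity more than
ten-fold; and sub-stoichiometric occupancy shifts the force-pCa relation
leftward (calcium sensitization). Several ensemble parameters
(`eps_max`, `f`, `lambda`, crossbridge stiffness) are literature-anchored
defaults rather than values printed in the available text, so these
ensemble results are reproduced as qualitative and band-level quantities
(e.g. the force peak within 15-45% occupancy), not to printed precision.

# Problem sizes and reproducibility

Every generator and simulation takes an integer seed and is bit-reproducible
given one. The test-suite and acceptance analyses use desk-scale sizes
chosen for stable statistics: 2000 censored dwells per rate recovery, 800
dwells and 500 steps per concentration in the global fits, 600 isometric
events for the Bell fit, 5000 steps per concentration for the EC50 (a
precision choice - the EC50's sampling SE at that size, ~6 nM, is well
inside the effect being recovered), five-six synthetic molecules of 30-40 s
each for the trace pipelines (~100-300 detected events), and 200-500 runs
of 1000 Gillespie steps per simulated condition (the full 1000 x 1000 of a
production study is a flag away).

# What passing the synthetic benchmarks does and does not show

The generator reproduces the statistical structures the analyses assume:
OU noise with a covariance drop on binding, exponential dwell mixtures with
censoring, Gaussian step mixtures, Bell-distributed isometric durations. It
does not emulate instrument drift, bead-linkage compliance series effects,
nonlinear trap potentials, hydrodynamic coupling between beads, or
feedback-loop dynamics (isometric "traces" are reduced to force-duration
pairs). Recovery on these benchmarks therefore validates the estimators and
their censoring/weighting logic - not robustness to every artifact of real
trap data. Likewise the thin-filament simulator omits thick-filament
regulation, explicit nucleotide states, filament compliance and 3D lattice
geometry; its purpose is mechanistic discrimination between drug-action
hypotheses, not quantitative muscle mechanics.
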