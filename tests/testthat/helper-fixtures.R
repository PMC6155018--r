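# shared fixture builders; everything is generated in code at test time

# minimal dumbbell trace wrapping explicit bead signals
make_trace <- function(b1, b2, fs = 1000, trap_stiffness = 0.07,
                       molecule_id = "m1") {
  n <- length(b1)
  cfg <- trap_sim_config(sample_rate = fs, duration = n / fs,
                         trap_stiffness = trap_stiffness, kT = 4.05,
                         seed = 1L)
  structure(list(time = (seq_len(n) - 1L) / fs,
                 bead1_pos = b1, bead2_pos = b2,
                 bead1_force = trap_stiffness * b1,
                 bead2_force = trap_stiffness * b2,
                 molecule_id = molecule_id, config = cfg),
            class = "dumbbell_trace")
}

# covariance signal wrapping explicit values (for threshold/detection tests)
make_cov <- function(value, fs = 1000, window_used = 0.005) {
  structure(list(time = (seq_along(value) - 1L) / fs, value = value,
                 window_used = window_used, sample_rate = fs),
            class = "cov_signal")
}

# noiseless trace with programmed events (exact steps)
noiseless_config <- function(duration, fs = 10e3, substep1 = 4.2,
                             substep2 = 1.5, seed = 1L) {
  trap_sim_config(sample_rate = fs, duration = duration, kT = 0,
                  rise_time = 0, substep1 = substep1, substep2 = substep2,
                  seed = seed)
}

# small ensemble config for fast simulator tests
small_ensemble <- function(...) {
  ensemble_config(n_heads = 30L, n_steps = 400L, n_runs = 30L, seed = 11L, ...)
}
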