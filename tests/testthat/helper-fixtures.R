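# Shared fixtures for the test suite. Everything is generated in code.

# A small network spec that still exhibits the calibrated single-cell
# dynamics (population sizes reduced only where the test is structural).
tiny_spec <- function(seed = 1, ...) {
  connectivity_spec(n_i = 20, n_e = 40, n_readout = 2, seed = seed, ...)
}

# Hand-built two-cell network: one driven interneuron (index 1) projecting
# through a single synapse of the given class onto one clamped readout.
# Readout is an E cell for class "IE" and an I cell for class "II".
two_cell_net <- function(class = "IE", weight = 1, delay = 0.8,
                         ii_g = 0.42) {
  spec <- connectivity_spec(n_i = 2, n_e = 1, n_readout = 1, p_ii = 0,
                            p_ie = 0, p_ei = 0, p_gap = 0, ii_g = ii_g,
                            seed = 1)
  chem <- data.frame(pre = 1L,
                     post = if (class == "IE") 1L else 2L,
                     class = class, weight = weight, delay = delay)
  gap <- data.frame(a = integer(0), b = integer(0), g = numeric(0))
  structure(list(spec = spec, chemical = chem, gap = gap,
                 readout_i = 2L, readout_e = 1L),
            class = "mec_network")
}

# Deterministic drive: constant-peak theta at 8 Hz
quick_drive <- function(n_cycles = 3) drive_spec(n_cycles = n_cycles)

# Closed-form normalized bi-exponential PSC kernel (peak = 1 at t_peak)
biexp_kernel <- function(t, tau_rise, tau_decay) {
  bp <- biexp_peak(tau_rise, tau_decay)
  out <- bp$norm * (exp(-t / tau_decay) - exp(-t / tau_rise))
  out[t < 0] <- 0
  out
}
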