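#' Simulated optogenetic theta-drive specification
#'
#' The optogenetic stimulus is a rectified ("biased to only positive values")
#' sinusoidal conductance at 8 Hz with reversal 0 mV:
#' `g(t) = peak * (1 - cos(2*pi*f*t)) / 2`, so each theta cycle starts and
#' ends at zero conductance and crests mid-cycle. Per-interneuron peaks are
#' drawn Normal(4, 0.4) nS (truncated at 0); every stellate cell gets a 3 nS
#' peak. The first theta cycle is discarded from analysis, so the default 41
#' simulated cycles give 40 analyzed ones.
#'
#' @param freq theta frequency (Hz)
#' @param peak_i_mean,peak_i_sd mean and SD of the per-interneuron peak drive
#'   conductance (nS)
#' @param peak_e peak drive conductance per stellate cell (nS)
#' @param e_rev drive reversal potential (mV)
#' @param n_cycles simulated theta cycles (first one discarded by analysis)
#' @return Object of class `drive_spec`.
#' @export
drive_spec <- function(freq = 8, peak_i_mean = 4, peak_i_sd = 0.4,
                       peak_e = 3, e_rev = 0, n_cycles = 41) {
  if (freq <= 0 || n_cycles < 1) stop("freq and n_cycles must be positive")
  if (peak_i_mean < 0 || peak_e < 0 || peak_i_sd < 0)
    stop("peak conductances must be >= 0")
  structure(list(freq = freq, peak_i_mean = peak_i_mean,
                 peak_i_sd = peak_i_sd, peak_e = peak_e, e_rev = e_rev,
                 n_cycles = n_cycles),
            class = "drive_spec")
}

#' Theta-drive conductance waveform
#'
#' @param spec a [drive_spec()]
#' @param t time (ms), vectorized, `>= 0`
#' @param peak per-cell peak conductance (nS)
#' @return Conductance (nS): `peak * (1 - cos(2*pi*f*t/1000)) / 2`,
#'   nonnegative, zero at cycle boundaries, maximum `peak` at mid-cycle.
#' @export
theta_drive <- function(spec, t, peak) {
  stopifnot(inherits(spec, "drive_spec"))
  if (any(t < 0)) stop("t must be >= 0")
  peak * (1 - cos(2 * pi * spec$freq * t / 1000)) / 2
}

#' Synaptic kinetics of the three connection classes
#'
#' I->I: bi-exponential conductance (rise 0.3 ms, decay 4 ms) reversing at
#' -75 mV (hyperpolarizing) or -55 mV (shunting variant, I->I only).
#' I->E: bi-exponential (rise 0.4 ms, decay 6 ms), reversal -65 mV.
#' E->I: single-exponential decay (1 ms), reversal 0 mV (AMPA).
#' Bi-exponential conductances are normalized so a unit-weight spike reaches
#' a peak conductance of exactly the weight.
#'
#' @param gaba_rev_ii reversal potential of the I->I GABA_A synapse (mV);
#'   -75 hyperpolarizing (default) or -55 shunting
#' @param gaba_rev_ie reversal potential of the I->E synapse (mV)
#' @param ampa_rev reversal potential of the E->I synapse (mV)
#' @return Object of class `synapse_params`: per-class list with `tau_rise`,
#'   `tau_decay` (ms) and `e_rev` (mV).
#' @export
synapse_params <- function(gaba_rev_ii = -75, gaba_rev_ie = -65,
                           ampa_rev = 0) {
  structure(list(
    II = list(tau_rise = 0.3, tau_decay = 4, e_rev = gaba_rev_ii),
    IE = list(tau_rise = 0.4, tau_decay = 6, e_rev = gaba_rev_ie),
    EI = list(tau_rise = NA_real_, tau_decay = 1, e_rev = ampa_rev)),
    class = "synapse_params")
}

#' Peak time and normalization of a bi-exponential synapse
#'
#' For `g(t) = N w (exp(-t/tau_d) - exp(-t/tau_r))` the peak occurs at
#' `t_peak = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)` and `N` is
#' chosen so the peak conductance equals the weight `w`.
#'
#' @param tau_rise,tau_decay time constants (ms), `0 < tau_rise < tau_decay`
#' @return List with `t_peak` (ms) and `norm` (dimensionless `N`).
#' @export
biexp_peak <- function(tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need 0 < tau_rise < tau_decay")
  t_peak <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- 1 / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
  list(t_peak = t_peak, norm = norm)
}

#' Gap-junction (electrical synapse) current
#'
#' Ohmic coupling `i = g * (v_peer - v_self)`; the current into one cell of a
#' pair is exactly minus the current into the other.
#'
#' @param v_self,v_peer membrane potentials (mV)
#' @param g gap-junction conductance (nS), `>= 0`
#' @return Current into the `self` cell (pA, depolarizing positive).
#' @export
gap_junction_current <- function(v_self, v_peer, g) {
  if (any(g < 0)) stop("g must be >= 0")
  g * (v_peer - v_self)
}
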