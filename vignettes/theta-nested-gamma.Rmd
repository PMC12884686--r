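---
title: "Modeling theta-nested gamma oscillations in an mEC E-I-I network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling theta-nested gamma oscillations in an mEC E-I-I network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecgamma)
```

## The model

`mecgamma` simulates a medial entorhinal cortex (mEC) circuit of 100
fast-spiking PV+ interneurons (I cells) and 400 stellate cells (E cells)
under a simulated optogenetic theta drive, and analyses the resulting
theta-nested gamma oscillations with a Morlet-wavelet pipeline. The central
scientific question it addresses is how the strength of the
excitatory-to-inhibitory (E→I) synaptic conductance moves the network
between two gamma mechanisms:

* **ING** (interneuron network gamma): mutual inhibition among tonically
  driven interneurons produces a fast rhythm (~140-150 Hz here) that
  requires no phasic excitation at all;
* **PING** (pyramidal-interneuron network gamma, "E cells recover first"
  variant): with strong E→I coupling, the excitatory population's recovery
  from inhibition paces a slower rhythm (~85-95 Hz at 60 nS here), and
  interneuron firing is entrained by excitatory volleys.

Both cell types are single-compartment conductance-based models (units
package-wide: mV, ms, nS, pF, pA, so 1 nS x 1 mV = 1 pA). The interneuron
has a fast Na+ current (m^3 h), two delayed-rectifier K+ currents (Kv1: a^4;
Kv3: n^4) and a leak, with reversal potentials E_Na = 50, E_K = -90,
E_L = -65 mV. Gating rates follow
\[
\alpha(V) = k_1(\theta - V)\,/\,(e^{(\theta-V)/\sigma_1} - 1), \qquad
\beta(V) = k_2\, e^{V/\sigma_2},
\]
with activation kinetics $dx/dt = \alpha(1-x) - \beta x$ and the swapped
form for inactivation. The stellate cell is a classic Hodgkin-Huxley set
(m^3 h Na+, n^4 K+, leak; rest near -65 mV) with per-cell multiplicative
Gaussian jitter on its maximal conductances and two Ornstein-Uhlenbeck (OU)
conductance-noise processes: excitatory (reversal 0 mV, tau 10.49 ms) and
inhibitory (reversal -75 mV, tau 2.728 ms), both with stationary mean
0.9 nS, advanced with the exact OU discretization so their statistics are
step-size independent. The noise SD is a calibrated 0.4 nS: the source
description prints 0.02 nS yet simultaneously calls the noise "large"
enough to keep the theta drive from synchronizing the E population, and
the two cannot both hold (0.02 nS is a ~1.5 pA ripple). With the literal
value the stellate population locks into population-wide gamma-cycle
skipping and its spike-histogram autocorrelogram reads the skip frequency
(~65 Hz) rather than the network gamma frequency; the functional value
restores the staggered participation the model itself describes
(`e_cell_noise_params(sd_g = 0.02)` gives the literal reading).

The theta drive is a rectified 8 Hz sinusoidal *conductance* reversing at
0 mV, `g(t) = peak (1 - cos 2 pi f t)/2`, with per-interneuron peaks drawn
Normal(4, 0.4) nS and 3 nS for every stellate cell. Connectivity is random
with fixed probabilities (I→I 30%, I→E 40%, E→I 30%; E cells mutually
unconnected), gap junctions join 18% of interneuron pairs, I→E weights are
log-normal with the arithmetic mean scaled by 2.5, and all chemical synapses
have uniform 0.6-1 ms delays. Synaptic kinetics: I→I bi-exponential
0.3/4 ms reversing at -75 mV (hyperpolarizing; -55 mV in the shunting
variant), I→E bi-exponential 0.4/6 ms at -65 mV, E→I single-exponential
1 ms decay at 0 mV. Five cells of each population are voltage-clamped at
0 mV as readouts; their recorded current is the synaptic current only,
mirroring experimental IPSC isolation.

## What had to be calibrated, and why

The model's *structure* and every printed constant above are fixed. Several
quantities are not available in closed form (they are deferred to prior
work or simply not stated) and are therefore package calibration, chosen
once against the network-level behaviours the model is known to produce
(pure ING near 147 Hz under the default drive; a ~10 Hz slowdown at
E→I = 6 nS; a PING transition into the 60-100 Hz band at 60 nS):

* **PV maximal conductances and capacitance** — `pv_cell_params()` defaults
  Cm = 20 pF, gNa = 1000, gKv3 = 150, gKv1 = 10, gL = 2 nS. Two properties
  drove the scale: the printed Kv3 gate activates at unusually low voltages
  (half-activation near -52 mV), so a large gKv3 walls off spike initiation
  under a slow conductance ramp; and the theta drive (4 nS) must be
  suprathreshold. Small total conductance keeps the membrane time constant
  comparable to the gating time constants, which is what makes tonic
  firing under a slowly rising drive possible at all.
* **The h gate** — the printed h-row of the gating table is dynamically
  degenerate: its alpha rate is negative at every voltage (sigma1 = -20 mV
  in a form that is positive only for positive slopes), which pins h at 1
  under the swapped kinetics; reading the two slopes as transposed instead
  centres inactivation near -16 mV, which strands the cell on a stable
  depolarized plateau after one spike. Phase-plane analysis shows that with
  the printed low-threshold n gate, *any* h centred above about -30 mV
  leaves such a plateau. The default model therefore substitutes the
  Wang-Buzsaki fast-spiking h gate (phi = 5) for this one row
  (`h_form = "wb"`); the literal row remains available (`h_form = "table"`)
  and the printed table is exported verbatim by `pv_kinetics()`.
* **Interneuron heterogeneity** — the source circuit's interneurons are
  strongly heterogeneous; `pv_cell_params(jitter_cv = 0.1)` jitters the
  four PV conductances multiplicatively, sharing the fixed heterogeneity
  seed with the stellate jitter so connectivity seeds vary the graph only.
* **Stellate excitability** — gK = 700 nS (with gNa = 4800, gL = 12 nS,
  Cm = 25 pF) sets how strongly the E population participates per theta
  cycle, which in turn sets how much the weak-excitation (6 nS) condition
  recruits extra inhibition and slows the rhythm.
* **Synaptic weight scales** — the I→I peak conductance (0.5 nS) sets the
  pure-ING frequency; the I→E log-normal base mean (0.3 nS before the
  x2.5 scaling; CV = 1, a documented choice since only the mean scaling is
  constrained) sets IPSC amplitude and E-cell gamma locking; the
  gap-junction conductance (0.3 nS) gives a ~1-5% coupling coefficient
  between resting interneurons.
* **E→I interpretation** — the swept "average total E→I conductance"
  divides by the expected in-degree (0.30 x 400 = 120), so each connection
  carries `ei_gmax / 120`; `ei_total = FALSE` switches to the
  per-connection reading.

## The analysis pipeline

Clamp traces (sampled at 2 kHz by default) are band-pass filtered 50-200 Hz
with a zero-phase (forward-reverse) 4th-order Butterworth filter, then
transformed with the analytic Morlet wavelet (omega0 = 6 rad/s, 32 scales
per octave, analyzed range 30-250 Hz; scale-to-frequency mapping
f = omega0/(2 pi s)). The transform is computed on the continuous trace and
then segmented by theta cycle, which avoids interior edge artifacts; the
first cycle is discarded, any cycle containing |current| > 3,000 pA is
excluded, and the power surface is averaged over the remaining cycles. The
scalogram is normalized so a sinusoid of amplitude A attains power A^2 at
its matching scale.

The gamma peak is the global maximum over 50-200 Hz; its bandwidth is the
full width at half maximum along frequency at the peak's theta phase, and
its SNR is peak power over the whole-scalogram mean (the plain reading of
"five multiples above the average"; a band-restricted mean would only make
the criterion stricter for narrowband signals). Quality control removes
peaks with power below 20 pA^2 (Thy1 mode; 10 in PV mode), bandwidth above
100 Hz (110 in PV mode), or SNR below 5 - thresholds are inclusive for
passing since removals are phrased as strict inequalities. Total gamma
power sums 60-140 Hz inside the cone of influence (e-folding time
sqrt(2) s of the wavelet envelope, applied at the recording edges). Welch
PSDs use 40 Hann-windowed segments at 50% overlap. Spike statistics:
30-bin spike-phase histograms and 10 Hz-bin ISI-frequency histograms, both
normalized per theta cycle, and a population spike-time histogram whose
autocorrelogram yields the network frequency as the reciprocal lag of the
first substantial peak (parabolic refinement; peaks below half the height
of the strongest candidate are treated as ripple, which guards against
reporting a subharmonic when the population intermittently skips cycles).

## The surrogate generator

`surrogate_spec()` produces traces with known ground truth - a gamma
carrier (60-140 Hz) under the same raised-cosine theta envelope as the
drive, white noise, and optional single-sample +/-5,000 pA artifacts - and
gamma-locked spike trains with geometric cycle skipping (each gamma crest
inside a theta participation window fires with probability `p_fire`).
Surrogates emulate the *structure* the pipeline must parse, not the
biophysics: amplitudes are stationary across cycles, noise is white rather
than synaptic, and spikes are crest-locked rather than integrate-and-fire.
Passing recovery tests on surrogates therefore validates the measurement
chain (frequency recovery within one scale step, exact artifact exclusion,
QC behaviour), not the realism of the network model.

## Numerical choices

Fixed-step integration at dt = 0.025 ms: exponential-Euler for the membrane
equation with all terms in conductance form (gap-junction peers frozen
within the step) and for the gates (rates frozen within the step); exact
per-step decay for synaptic conductances; per-edge delays rounded to the
grid; spike detection by upward crossing of 0 mV with a 1 ms detection-only
refractory. Initial conditions: V uniform on [-70, -60] mV with gates at
steady state. The alpha-rate removable singularity at V = theta is
evaluated by series expansion. Determinism: (network, runtime seed, dt)
fully determine a simulation; connectivity, heterogeneity and runtime noise
use three separate seed streams so campaigns vary connectivity only.
Halving dt leaves early spike times within 0.1 ms and the tonic ISI within
0.01 ms of a dt/16 reference; accumulated spike-time *phase* over long
tonic trains drifts linearly in time at any fixed step size, which is why
convergence is stated for early spikes and the ISI rather than for
end-of-run spike times.

## Known limitations

* The PV gating table could not be used as printed (degenerate h row); the
  default cell is a calibrated reconstruction, and quantities that depend
  on its phase-resetting curve need not match the original model. The
  clearest casualty is the shunting control: with E_GABA(I→I) = -55 mV and
  no E→I coupling, the original network loses its rhythm, whereas this
  package's interneurons - whose interspike voltage rides well below
  -55 mV because of the deep Kv3 AHP toward E_K = -90 mV - experience
  -55 mV GABA as effectively excitatory and still synchronize (the
  corresponding acceptance test is deliberately left failing rather than
  reinterpreted). The companion observation, robust gamma under shunting
  once E→I = 60 nS is restored, does reproduce.
* At strong E→I the interneurons here fire about one spike per gamma cycle
  rather than multi-spike bursts, so the burst-based regime classifier
  (`classify_regime()`, gap = half the gamma period, 1.5 spikes/burst,
  both exposed in config) can remain below its PING threshold even when
  the frequency transition itself is complete; the frequency and power
  signatures of the ING-to-PING transition are the robust observables.
* Stellate cells participate more strongly per theta cycle than the
  experimentally reported ~1.5 spikes, and the calibrated cell is an
  intrinsic pacemaker (~50 Hz free-running without input or noise) whose
  in-network rate is shaped by inhibition and noise rather than strictly
  drive-gated; interneurons, by contrast, are silent without drive, which
  is the property the model's logic rests on.
* Raising E→I from 0 to 6 nS lowers the frequency by ~3 Hz here (one
  wavelet scale step) versus ~10 Hz in the source: with a decorrelated E
  population the phase-advance effect of excitation on interneurons
  nearly cancels the extra recruited inhibition. The effect direction and
  the full monotonic transition are robust; the size of this first step
  is not.
* Test and acceptance runs use a reduced profile (11 simulated theta
  cycles, 10 analyzed, 3 seeds) chosen so the full suite exercises the
  complete 500-cell model many times; the acceptance script runs the full
  41-cycle protocol.

## Reproducing the headline numbers

```r
net <- build_network(connectivity_spec(seed = 1, ei_gmax = 0))
sim <- run_simulation(net, drive = drive_spec(n_cycles = 41))
analyze_readouts(sim)          # ~143 Hz pure-ING peak in every E readout
sweep_ei(c(0, 6, 12, 24, 60))  # the frequency/power transition
```

`scripts/acceptance.R` automates this: it reruns the pure-ING and weak
excitation conditions over three connectivity seeds at full scale and
reports the wavelet peak frequency, the E-population autocorrelogram
frequency, the 0-to-6 nS frequency reduction, and the weak-regime median
frequency.
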