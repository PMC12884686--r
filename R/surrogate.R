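#' Surrogate theta-nested gamma recording specification
#'
#' Defines ground-truth surrogate data for validating the analysis pipeline
#' without running the network model: a gamma-band carrier under a raised
#' cosine theta envelope (the same phase convention as the simulator's
#' drive), white measurement noise, optional injected large artifacts
#' (single samples of +/- 5,000 pA, unambiguously above the 3,000 pA
#' exclusion criterion), and gamma-phase-locked spike trains with geometric
#' cycle skipping.
#'
#' @param theta_freq theta frequency (Hz)
#' @param gamma_freq gamma carrier frequency (Hz); must exceed `theta_freq`
#' @param gamma_amp peak carrier amplitude (pA) at the envelope crest
#' @param noise_sd white-noise SD (pA)
#' @param artifact_rate expected artifacts per 40 cycles
#' @param n_cycles simulated theta cycles
#' @param p_fire per-gamma-cycle firing probability of the spike model
#' @param jitter_ms SD of Gaussian spike-time jitter (ms)
#' @param window theta-phase participation window (fractions of the cycle)
#' @param seed RNG seed
#' @return Object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(theta_freq = 8, gamma_freq = 100,
                           gamma_amp = 50, noise_sd = 0,
                           artifact_rate = 0, n_cycles = 41,
                           p_fire = 1, jitter_ms = 0,
                           window = c(0.25, 0.75), seed = 1) {
  if (gamma_freq <= theta_freq) stop("gamma_freq must exceed theta_freq")
  if (gamma_amp < 0 || noise_sd < 0) stop("amplitudes must be >= 0")
  if (p_fire < 0 || p_fire > 1) stop("p_fire must lie in [0, 1]")
  structure(list(theta_freq = theta_freq, gamma_freq = gamma_freq,
                 gamma_amp = gamma_amp, noise_sd = noise_sd,
                 artifact_rate = artifact_rate, n_cycles = n_cycles,
                 p_fire = p_fire, jitter_ms = jitter_ms, window = window,
                 seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Generate a surrogate current trace with known ground truth
#'
#' `trace = envelope(t) * A * sin(2 pi f_gamma t) + noise + artifacts`, with
#' `envelope = (1 - cos(2 pi f_theta t)) / 2`. Artifact cycles are drawn at
#' random (sparing the first cycle, which the analysis discards anyway) and
#' receive one +/-5,000 pA sample each.
#'
#' @param spec a [surrogate_spec()]
#' @param fs sampling rate (Hz)
#' @return List with `trace` (pA), `time` (ms), `fs`, and `truth` (list:
#'   `gamma_freq`, `artifact_cycles`, `peak_power` - squared crest amplitude
#'   of the noiseless carrier, `cycle_peak_power` per cycle).
#' @export
generate_current_trace <- function(spec, fs = 2000) {
  stopifnot(inherits(spec, "surrogate_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  spc <- round(fs / spec$theta_freq)
  n <- spc * spec$n_cycles
  t_s <- (seq_len(n) - 1) / fs
  env <- (1 - cos(2 * pi * spec$theta_freq * t_s)) / 2
  carrier <- sin(2 * pi * spec$gamma_freq * t_s)
  trace <- env * spec$gamma_amp * carrier
  if (spec$noise_sd > 0) trace <- trace + rnorm(n, sd = spec$noise_sd)

  n_art <- rbinom(1, spec$n_cycles, min(1, spec$artifact_rate / 40))
  art_cycles <- integer(0)
  if (n_art > 0) {
    art_cycles <- sort(sample(2:spec$n_cycles, min(n_art, spec$n_cycles - 1)))
    for (c in art_cycles) {
      i <- (c - 1) * spc + sample.int(spc, 1)
      trace[i] <- trace[i] + sample(c(-5000, 5000), 1)
    }
  }

  cyc <- rep(seq_len(spec$n_cycles), each = spc)
  cpp <- vapply(seq_len(spec$n_cycles), function(c)
    max((env[cyc == c] * spec$gamma_amp)^2), 1.0)

  list(trace = trace, time = t_s * 1000, fs = fs,
       truth = list(gamma_freq = spec$gamma_freq,
                    artifact_cycles = art_cycles,
                    peak_power = spec$gamma_amp^2,
                    cycle_peak_power = cpp))
}

#' Generate gamma-locked surrogate spike trains with cycle skipping
#'
#' Spikes are placed at gamma-cycle crests inside the theta participation
#' window, each crest occupied independently with probability `p_fire`
#' (geometric cycle skipping: consecutive-spike intervals concentrate at the
#' gamma period and its integer multiples), with optional Gaussian jitter.
#'
#' @param spec a [surrogate_spec()]
#' @param n_cells number of spike trains
#' @return List of numeric vectors of spike times (ms), one per cell.
#' @export
generate_spike_trains <- function(spec, n_cells) {
  stopifnot(inherits(spec, "surrogate_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)

  theta_t <- 1000 / spec$theta_freq
  gamma_t <- 1000 / spec$gamma_freq
  crests <- seq(gamma_t / 2, spec$n_cycles * theta_t, by = gamma_t)
  ph <- (crests %% theta_t) / theta_t
  crests <- crests[ph >= spec$window[1] & ph <= spec$window[2]]

  lapply(seq_len(n_cells), function(i) {
    keep <- runif(length(crests)) < spec$p_fire
    s <- crests[keep]
    if (spec$jitter_ms > 0) s <- s + rnorm(length(s), sd = spec$jitter_ms)
    sort(s[s >= 0])
  })
}
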