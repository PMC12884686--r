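#' Quality-control criteria for gamma-peak analysis
#'
#' Exclusion thresholds applied to cycle-averaged scalograms: recordings with
#' low average peak gamma power (< 20 pA^2 in Thy1 mode, < 10 pA^2 in PV
#' mode), broad scalogram peaks (> 100 Hz, resp. > 110 Hz bandwidth) or peak
#' power less than five times the scalogram average (SNR < 5) are flagged;
#' theta cycles containing currents above 3,000 pA are excluded before
#' averaging. Threshold boundaries are inclusive for passing (removals are
#' phrased as strict inequalities). Total gamma power is summed over the
#' 60-140 Hz band; the peak is searched over the band-passed 50-200 Hz range.
#'
#' @param mode `"thy1"` (default) or `"pv"`
#' @param min_peak_power minimum acceptable peak power (pA^2)
#' @param max_bandwidth maximum acceptable full width at half maximum (Hz)
#' @param min_snr minimum peak power / scalogram mean
#' @param artifact_threshold per-cycle absolute-current exclusion limit (pA)
#' @param gamma_band band for total gamma power (Hz)
#' @param peak_band band searched for the scalogram peak (Hz)
#' @return Object of class `qc_criteria`.
#' @export
qc_criteria <- function(mode = c("thy1", "pv"),
                        min_peak_power = NULL, max_bandwidth = NULL,
                        min_snr = 5, artifact_threshold = 3000,
                        gamma_band = c(60, 140), peak_band = c(50, 200)) {
  mode <- match.arg(mode)
  if (is.null(min_peak_power))
    min_peak_power <- if (mode == "thy1") 20 else 10
  if (is.null(max_bandwidth))
    max_bandwidth <- if (mode == "thy1") 100 else 110
  stopifnot(min_peak_power > 0, max_bandwidth > 0, min_snr > 0,
            artifact_threshold > 0)
  structure(list(mode = mode, min_peak_power = min_peak_power,
                 max_bandwidth = max_bandwidth, min_snr = min_snr,
                 artifact_threshold = artifact_threshold,
                 gamma_band = gamma_band, peak_band = peak_band),
            class = "qc_criteria")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-reverse (zero-phase) filtering with a 4th-order Butterworth
#' band-pass, the standard pre-processing of current traces before wavelet
#' analysis. The DC component is fully rejected.
#'
#' @param x numeric trace (pA)
#' @param fs sampling rate (Hz); must exceed `2 * high`
#' @param low,high band edges (Hz)
#' @return Filtered trace, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 50, high = 200) {
  if (fs <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Geometric frequency grid, `n_per_octave` scales per octave
scalogram_freqs <- function(range, n_per_octave = 32) {
  2^(seq(log2(range[1]), log2(range[2]), by = 1 / n_per_octave))
}

#' Analytic Morlet continuous wavelet transform
#'
#' FFT-based CWT with the analytic Morlet wavelet (default omega0 = 6 rad/s).
#' The frequency grid is geometric with `scales_per_octave` scales per
#' octave; the scale-to-frequency mapping is `f = omega0 / (2 pi s)`. The
#' filter bank is normalized so that a pure sinusoid of amplitude A yields
#' squared magnitude A^2 at its matching scale (analytic-envelope
#' convention), making scalogram power directly comparable to the squared
#' amplitude of band-limited current oscillations.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param freq_range analyzed frequency range (Hz)
#' @param scales_per_octave scales per octave (32)
#' @param omega0 Morlet nondimensional frequency (6)
#' @return List with `freqs` (Hz), `power` (matrix freq x time), and `coi`
#'   (e-folding distance from each trace edge, in seconds, per frequency).
#' @export
morlet_cwt <- function(x, fs, freq_range = c(30, 250),
                       scales_per_octave = 32, omega0 = 6) {
  n <- length(x)
  freqs <- scalogram_freqs(freq_range, scales_per_octave)
  nfft <- nextn(n, 2)
  xf <- fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * fs * (0:(nfft - 1)) / nfft        # rad/s, one-sided use
  pos <- w <= pi * fs                              # keep analytic half
  pow <- matrix(0, nrow = length(freqs), ncol = n)
  scales <- omega0 / (2 * pi * freqs)              # seconds
  for (k in seq_along(freqs)) {
    psi <- numeric(nfft)
    psi[pos] <- 2 * exp(-((scales[k] * w[pos] - omega0)^2) / 2)
    psi[1] <- 0                                    # reject DC
    wt <- fft(xf * psi, inverse = TRUE) / nfft
    pow[k, ] <- Mod(wt[seq_len(n)])^2
  }
  coi <- sqrt(2) * scales                          # e-folding time (s)
  list(freqs = freqs, power = pow, coi = coi)
}

#' Cycle-averaged Morlet scalogram of a theta-nested current trace
#'
#' Computes the analytic Morlet scalogram of the (optionally band-passed)
#' trace over the continuous recording, segments it by theta cycle, discards
#' the first cycle and any cycle whose raw current exceeds the artifact
#' threshold, and averages the power surface across the remaining cycles.
#' The cone-of-influence mask marks (frequency, phase) points whose
#' contributing samples all lie farther than the wavelet e-folding time from
#' the recording edges.
#'
#' @param trace current trace (pA), sampled at `fs`
#' @param fs sampling rate (Hz)
#' @param theta_freq theta frequency (Hz); `fs/theta_freq` must be a whole
#'   number of samples
#' @param criteria a [qc_criteria()]
#' @param freq_range analyzed range (Hz)
#' @param scales_per_octave,omega0 wavelet parameters
#' @param bandpass apply [bandpass_filter()] (50-200 Hz) before the CWT
#' @param discard_first drop the first theta cycle
#' @return Object of class `mec_scalogram`: `freqs` (Hz), `phase` (radians,
#'   bin centers across the theta cycle), `power` (freq x phase, pA^2),
#'   `coi_mask` (logical, same shape), `n_cycles_used`, `excluded` (data
#'   frame of excluded cycles and reasons), `fs`, `theta_freq`.
#' @export
cycle_average_scalogram <- function(trace, fs, theta_freq = 8,
                                    criteria = qc_criteria(),
                                    freq_range = c(30, 250),
                                    scales_per_octave = 32, omega0 = 6,
                                    bandpass = TRUE, discard_first = TRUE) {
  spc <- fs / theta_freq
  if (abs(spc - round(spc)) > 1e-9)
    stop("fs must be an integer multiple of theta_freq")
  spc <- round(spc)
  n_cyc <- length(trace) %/% spc
  if (n_cyc < 2) stop("trace must span at least 2 theta cycles")
  n_use <- n_cyc * spc
  trace <- trace[seq_len(n_use)]

  cyc_of <- rep(seq_len(n_cyc), each = spc)
  art <- vapply(seq_len(n_cyc), function(c)
    any(abs(trace[cyc_of == c]) > criteria$artifact_threshold), TRUE)

  x <- if (bandpass) bandpass_filter(trace, fs) else trace
  cw <- morlet_cwt(x, fs, freq_range, scales_per_octave, omega0)

  excl <- data.frame(cycle = integer(0), reason = character(0))
  if (discard_first)
    excl <- rbind(excl, data.frame(cycle = 1L, reason = "first_cycle"))
  if (any(art))
    excl <- rbind(excl, data.frame(cycle = which(art), reason = "artifact"))
  keep <- setdiff(seq_len(n_cyc), excl$cycle)
  if (!length(keep))
    stop("all theta cycles excluded: ",
         paste(sprintf("cycle %d (%s)", excl$cycle, excl$reason),
               collapse = ", "))

  nf <- length(cw$freqs)
  pow <- matrix(0, nf, spc)
  for (c in keep)
    pow <- pow + cw$power[, ((c - 1) * spc + 1):(c * spc), drop = FALSE]
  pow <- pow / length(keep)

  # COI: a (freq, phase) cell is clean if in every kept cycle the absolute
  # sample time is at least the e-folding time from both recording edges
  t_end <- n_use / fs
  phase_t <- (seq_len(spc) - 0.5) / fs             # within-cycle time (s)
  first_kept <- min(keep); last_kept <- max(keep)
  coi_mask <- matrix(TRUE, nf, spc)
  for (k in seq_len(nf)) {
    tmin <- (first_kept - 1) * spc / fs + phase_t
    tmax <- (last_kept - 1) * spc / fs + phase_t
    coi_mask[k, ] <- (tmin >= cw$coi[k]) & (t_end - tmax >= cw$coi[k])
  }

  structure(
    list(freqs = cw$freqs, phase = 2 * pi * (seq_len(spc) - 0.5) / spc,
         power = pow, coi_mask = coi_mask, n_cycles_used = length(keep),
         excluded = excl, fs = fs, theta_freq = theta_freq,
         omega0 = omega0, scales_per_octave = scales_per_octave),
    class = "mec_scalogram")
}

#' Locate and quality-control the gamma peak of a scalogram
#'
#' Finds the global maximum of the cycle-averaged power surface within the
#' peak search band, measures its full width at half maximum along frequency
#' (at the peak's theta phase), computes the SNR as peak power over the
#' whole-scalogram mean, and applies the QC thresholds. QC failures are
#' reason-coded, not raised.
#'
#' @param scal an [cycle_average_scalogram()] result
#' @param criteria a [qc_criteria()]
#' @return Object of class `gamma_peak`: `frequency` (Hz), `power` (pA^2),
#'   `phase` (radians), `bandwidth` (Hz), `snr`, `passed_qc`, `reasons`.
#' @export
find_gamma_peak <- function(scal, criteria = qc_criteria()) {
  stopifnot(inherits(scal, "mec_scalogram"))
  sel <- scal$freqs >= criteria$peak_band[1] &
         scal$freqs <= criteria$peak_band[2]
  sub <- scal$power[sel, , drop = FALSE]
  idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  fi <- which(sel)[idx[1]]
  pi_ <- idx[2]
  pk_f <- scal$freqs[fi]
  pk_p <- scal$power[fi, pi_]
  snr <- pk_p / mean(scal$power)

  # FWHM along frequency at the peak phase (whole analyzed range)
  prof <- scal$power[, pi_]
  half <- pk_p / 2
  lo <- fi
  while (lo > 1 && prof[lo - 1] >= half) lo <- lo - 1
  hi <- fi
  while (hi < length(prof) && prof[hi + 1] >= half) hi <- hi + 1
  bw <- scal$freqs[hi] - scal$freqs[lo]

  reasons <- character(0)
  if (pk_p < criteria$min_peak_power) reasons <- c(reasons, "low_power")
  if (bw > criteria$max_bandwidth) reasons <- c(reasons, "broad_peak")
  if (snr < criteria$min_snr) reasons <- c(reasons, "low_snr")

  structure(list(frequency = pk_f, power = pk_p,
                 phase = scal$phase[pi_], bandwidth = bw, snr = snr,
                 passed_qc = length(reasons) == 0L, reasons = reasons),
            class = "gamma_peak")
}

#' Total gamma power of a cycle-averaged scalogram
#'
#' Sums power over scales with centre frequency inside the gamma band
#' (60-140 Hz) and over theta phases inside the cone-of-influence mask.
#'
#' @inheritParams find_gamma_peak
#' @return Total power (pA^2).
#' @export
total_gamma_power <- function(scal, criteria = qc_criteria()) {
  stopifnot(inherits(scal, "mec_scalogram"))
  sel <- scal$freqs >= criteria$gamma_band[1] &
         scal$freqs <= criteria$gamma_band[2]
  sum(scal$power[sel, , drop = FALSE] *
        scal$coi_mask[sel, , drop = FALSE])
}

#' Welch power spectral density
#'
#' Hann-windowed Welch estimate with `n_segments` segments at the given
#' overlap (the default 40 segments at 50% overlap over a 5 s trace gives a
#' segment length of `floor(N / 20.5)` samples).
#'
#' @param x trace (pA)
#' @param fs sampling rate (Hz)
#' @param n_segments number of segments
#' @param overlap fractional overlap between consecutive segments
#' @param demean remove the trace mean first
#' @return Data frame with `freq` (Hz) and `psd` (pA^2/Hz).
#' @export
welch_psd <- function(x, fs, n_segments = 40, overlap = 0.5, demean = TRUE) {
  n <- length(x)
  denom <- n_segments - (n_segments - 1) * overlap
  seg <- floor(n / denom)
  if (seg < 8) stop("trace too short for the requested segmentation")
  step <- round(seg * (1 - overlap))
  if (demean) x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  u <- sum(w^2)
  starts <- seq(1, n - seg + 1, by = step)
  acc <- numeric(seg)
  for (s in starts) {
    xf <- fft(x[s:(s + seg - 1)] * w)
    acc <- acc + Mod(xf)^2
  }
  acc <- acc / length(starts)
  nf <- seg %/% 2 + 1
  psd <- acc[seq_len(nf)] / (fs * u)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]           # one-sided
  data.frame(freq = (seq_len(nf) - 1) * fs / seg, psd = psd)
}

#' Spike-phase histogram over the theta cycle
#'
#' Each spike is assigned to one of `n_bins` equal phase bins of its theta
#' cycle (bin width `2*pi/n_bins` radians); counts are normalized by the
#' number of analyzed cycles. Spikes outside the analyzed window are dropped
#' and counted in the `n_outside` diagnostic.
#'
#' @param spikes spike times (ms)
#' @param theta_freq theta frequency (Hz)
#' @param n_cycles number of analyzed cycles
#' @param n_bins phase bins (30)
#' @param t0 start of the analyzed window (ms)
#' @return List with `counts` (per-cycle normalized, length `n_bins`),
#'   `phase` (bin centres, radians) and `n_outside`.
#' @export
spike_phase_histogram <- function(spikes, theta_freq = 8, n_cycles,
                                  n_bins = 30, t0 = 0) {
  stopifnot(n_cycles >= 1)
  period <- 1000 / theta_freq
  t_end <- t0 + n_cycles * period
  inside <- spikes >= t0 & spikes < t_end
  ph <- ((spikes[inside] - t0) %% period) / period
  bins <- pmin(floor(ph * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins) / n_cycles
  list(counts = counts, phase = 2 * pi * (seq_len(n_bins) - 0.5) / n_bins,
       n_outside = sum(!inside))
}

#' Interspike-interval frequency histogram
#'
#' Converts consecutive interspike intervals to instantaneous frequencies
#' (1000/ISI Hz) and bins them at 10 Hz resolution, normalized by the number
#' of theta cycles.
#'
#' @param spikes sorted spike times (ms)
#' @param n_cycles number of analyzed cycles
#' @param bin_hz bin width (Hz)
#' @param max_hz upper edge of the last bin (Hz)
#' @return List with `counts` (per-cycle) and `freq` (bin centres, Hz).
#' @export
isi_frequency_histogram <- function(spikes, n_cycles, bin_hz = 10,
                                    max_hz = 500) {
  breaks <- seq(0, max_hz, by = bin_hz)
  if (length(spikes) < 2) {
    counts <- numeric(length(breaks) - 1)
  } else {
    if (is.unsorted(spikes)) stop("spikes must be sorted")
    f <- 1000 / diff(spikes)
    f <- f[f < max_hz]
    counts <- tabulate(findInterval(f, breaks), nbins = length(breaks) - 1) /
      n_cycles
  }
  list(counts = counts, freq = breaks[-length(breaks)] + bin_hz / 2)
}

#' Oscillation frequency from a spike-histogram autocorrelogram
#'
#' Computes the autocorrelation of a population spike-time histogram and
#' returns the reciprocal of the lag of the first local maximum beyond zero
#' lag, refined by parabolic interpolation. If no secondary peak rises above
#' the noise floor the result is reported as absent (`NA` with a reason
#' attribute), not as a number.
#'
#' @param counts histogram counts (regular bins)
#' @param bin_ms bin width (ms)
#' @param lag_range lags searched (ms)
#' @param min_height minimum normalized autocorrelation at the peak
#' @return Frequency (Hz), or `NA` with `attr(, "reason")`.
#' @export
histogram_autocorr_frequency <- function(counts, bin_ms = 1,
                                         lag_range = c(2, 50),
                                         min_height = 0.05) {
  x <- counts - mean(counts)
  if (all(x == 0)) {
    out <- NA_real_; attr(out, "reason") <- "flat_histogram"; return(out)
  }
  max_lag <- min(length(x) - 2L, ceiling(lag_range[2] / bin_ms))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) * bin_ms
  # local maxima within the searched window; the fundamental is the first
  # peak of comparable height to the strongest one (subharmonics at
  # multiples of the period can never exceed it, but early spurious ripples
  # below half its height are ignored)
  cand <- which(diff(sign(diff(ac))) == -2) + 1L
  cand <- cand[lags[cand] >= lag_range[1] & lags[cand] <= lag_range[2]]
  cand <- cand[ac[cand] >= min_height]
  if (!length(cand)) {
    out <- NA_real_; attr(out, "reason") <- "no_secondary_peak"; return(out)
  }
  cand <- cand[ac[cand] >= 0.5 * max(ac[cand])]
  k <- cand[1]
  # parabolic refinement of the peak lag
  num <- ac[k - 1] - ac[k + 1]
  den <- ac[k - 1] - 2 * ac[k] + ac[k + 1]
  shift <- if (den != 0) 0.5 * num / den else 0
  lag <- (k - 1 + shift) * bin_ms
  1000 / lag
}

#' @export
print.mec_scalogram <- function(x, ...) {
  cat(sprintf(
    "Cycle-averaged Morlet scalogram: %d scales (%.0f-%.0f Hz, %d/octave)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$scales_per_octave))
  cat(sprintf("  %d theta cycles averaged at %g Hz theta; %d excluded\n",
              x$n_cycles_used, x$theta_freq, nrow(x$excluded)))
  invisible(x)
}

#' @export
plot.mec_scalogram <- function(x, ...) {
  image(x$phase, log2(x$freqs), t(x$power), xlab = "theta phase (rad)",
        ylab = "frequency (log2 Hz)", yaxt = "n", ...)
  at <- pretty(log2(x$freqs))
  axis(2, at = at, labels = round(2^at))
  invisible(x)
}

#' @export
print.gamma_peak <- function(x, ...) {
  cat(sprintf(
    "Gamma peak: %.1f Hz, %.1f pA^2 (SNR %.1f, bandwidth %.0f Hz) - QC %s\n",
    x$frequency, x$power, x$snr, x$bandwidth,
    if (x$passed_qc) "pass" else paste("FAIL:", paste(x$reasons,
                                                      collapse = ", "))))
  invisible(x)
}
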