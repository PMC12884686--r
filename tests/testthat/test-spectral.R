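fs <- 2000

test_that("the band-pass filter rejects DC, passes 100 Hz and is zero-phase", {
  t <- seq(0, 2, by = 1 / fs)[-1]
  mid <- seq(fs / 2, length(t) - fs / 2)       # avoid filter edge transients
  expect_lt(max(abs(bandpass_filter(rep(5, length(t)), fs)[mid])), 5e-9 * 5)
  s100 <- sin(2 * pi * 100 * t)
  out <- bandpass_filter(s100, fs)
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.05)
  # zero phase: cross-correlation peaks at lag 0
  cc <- ccf(out[mid], s100[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 10 Hz attenuated by more than 20 dB
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(max(abs(bandpass_filter(s10, fs)[mid])), 10^(-20 / 20))
  expect_error(bandpass_filter(s100, fs = 300), "sampling rate")
})

test_that("the cycle-averaged scalogram recovers a known carrier frequency", {
  g <- generate_current_trace(surrogate_spec(gamma_freq = 100,
                                             gamma_amp = 50, seed = 1))
  scal <- cycle_average_scalogram(g$trace, g$fs)
  pk <- find_gamma_peak(scal)
  step <- 2^(1 / 32)
  expect_lt(abs(log(pk$frequency / 100)), log(step) + 1e-9)
  expect_true(pk$passed_qc)
  # frequency grid is geometric with ratio 2^(1/32), power nonnegative
  expect_equal(unique(round(diff(log2(scal$freqs)), 10)), 1 / 32)
  expect_true(all(scal$power >= 0))
  # zero trace -> all-zero scalogram
  z <- cycle_average_scalogram(rep(0, 2000), fs, theta_freq = 8)
  expect_true(all(z$power == 0))
})

test_that("artifact-bearing cycles are excluded without disturbing the rest", {
  base <- generate_current_trace(surrogate_spec(gamma_freq = 100,
                                                gamma_amp = 50, seed = 4))
  dirty <- base$trace
  spc <- round(base$fs / 8)
  dirty[10 * spc + 17] <- 5000                 # contaminate cycle 11
  s_clean <- cycle_average_scalogram(base$trace, base$fs)
  s_dirty <- cycle_average_scalogram(dirty, base$fs)
  expect_true(11 %in% s_dirty$excluded$cycle)
  expect_equal(s_dirty$n_cycles_used, s_clean$n_cycles_used - 1)
  # averaged surface changes by less than 1% at the peak
  expect_equal(max(s_dirty$power), max(s_clean$power), tolerance = 0.01)
})

test_that("QC reason-codes low power, broad peaks and low SNR", {
  set.seed(5)
  noise <- rnorm(2000 * 3, sd = 30)
  scal <- cycle_average_scalogram(noise, fs)
  pk <- find_gamma_peak(scal)
  expect_false(pk$passed_qc)
  expect_true("low_snr" %in% pk$reasons || "broad_peak" %in% pk$reasons)
  # inclusive boundary: a peak power of exactly 20 pA^2 passes Thy1 QC
  fake <- structure(list(
    freqs = scalogram_freqs(c(30, 250)),
    phase = seq(0.1, 2 * pi, length.out = 50),
    power = matrix(0, length(scalogram_freqs(c(30, 250))), 50),
    coi_mask = matrix(TRUE, length(scalogram_freqs(c(30, 250))), 50),
    n_cycles_used = 40, excluded = data.frame(), fs = fs, theta_freq = 8,
    omega0 = 6, scales_per_octave = 32), class = "mec_scalogram")
  fi <- which.min(abs(fake$freqs - 100))
  fake$power[fi, 25] <- 20
  fake$power[fake$power == 0] <- 1e-9          # keep SNR above threshold
  pk20 <- find_gamma_peak(fake)
  expect_equal(pk20$power, 20)
  expect_true(pk20$passed_qc)
})

test_that("total gamma power is band-limited and near-additive", {
  z <- cycle_average_scalogram(rep(0, 2000), fs)
  expect_equal(total_gamma_power(z), 0)
  a <- generate_current_trace(surrogate_spec(gamma_freq = 80,
                                             gamma_amp = 40, seed = 6))
  b <- generate_current_trace(surrogate_spec(gamma_freq = 120,
                                             gamma_amp = 40, seed = 6))
  ta <- total_gamma_power(cycle_average_scalogram(a$trace, fs))
  tb <- total_gamma_power(cycle_average_scalogram(b$trace, fs))
  tab <- total_gamma_power(cycle_average_scalogram(a$trace + b$trace, fs))
  expect_equal(tab, ta + tb, tolerance = 0.1)
  # power confined to 175 Hz contributes little to the 60-140 Hz band
  hi <- generate_current_trace(surrogate_spec(gamma_freq = 175,
                                              gamma_amp = 40, seed = 6))
  thi <- total_gamma_power(cycle_average_scalogram(hi$trace, fs))
  expect_lt(thi, 0.1 * ta)
})

test_that("Welch PSD locates a sinusoid and satisfies Parseval", {
  t <- seq(0, 5, by = 1 / fs)[-1]
  s <- sin(2 * pi * 100 * t)
  p <- welch_psd(s, fs)
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(p$freq[which.max(p$psd)] - 100), df + 1e-9)
  set.seed(8)
  w <- rnorm(length(t), sd = 2)
  pw <- welch_psd(w, fs)
  expect_equal(sum(pw$psd) * df, var(w), tolerance = 0.05)
  # white spectrum is flat after 40-segment averaging
  band <- pw$psd[pw$freq >= 60 & pw$freq <= 140]
  expect_lt(max(band) / min(band), 3)
  expect_error(welch_psd(s[1:100], fs), "too short")
})

test_that("spike-phase histogram normalizes by cycles and flags outsiders", {
  h0 <- spike_phase_histogram(numeric(0), 8, n_cycles = 40)
  expect_true(all(h0$counts == 0))
  # one spike at the crest of each of 40 cycles -> one bin at exactly 1
  crest <- 62.5 + 125 * (0:39)
  h1 <- spike_phase_histogram(crest, 8, n_cycles = 40)
  expect_equal(sum(h1$counts), 1)
  expect_equal(max(h1$counts), 1)
  expect_equal(which.max(h1$counts), 16)       # crest bin (phase pi)
  # uniform spikes are flat within multinomial 99% bands
  set.seed(10)
  u <- runif(1e4, 0, 40 * 125)
  hu <- spike_phase_histogram(u, 8, n_cycles = 40)
  expected <- 1e4 / 30 / 40
  se <- sqrt(1e4 * (1 / 30) * (29 / 30)) / 40
  expect_true(all(abs(hu$counts - expected) < 2.58 * se * 1.5))
  # outsiders counted, not binned
  ho <- spike_phase_histogram(c(10, 6000), 8, n_cycles = 40)
  expect_equal(ho$n_outside, 1)
})

test_that("ISI-frequency histogram bins instantaneous rates per cycle", {
  h <- isi_frequency_histogram(seq(0, 400, by = 10), n_cycles = 40)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$freq[which.max(h$counts)], 105)  # 100 Hz falls in (100,110]
  expect_true(all(isi_frequency_histogram(5, n_cycles = 40)$counts == 0))
  # 7 and 14 ms ISIs appear at ~143 and ~71 Hz in the right proportion
  sp <- cumsum(c(0, rep(c(7, 7, 14), 50)))
  hm <- isi_frequency_histogram(sp, n_cycles = 40)
  i143 <- which(hm$freq == 145); i71 <- which(hm$freq == 75)
  expect_equal(hm$counts[i143] / hm$counts[i71], 2, tolerance = 0.02)
})

test_that("autocorrelogram frequency finds periodicity or reports absence", {
  t <- seq(0, 999, by = 1)
  per <- as.numeric(t %% 7 == 0)
  f <- histogram_autocorr_frequency(per, bin_ms = 1)
  expect_equal(f, 1000 / 7, tolerance = 0.01)
  flat <- histogram_autocorr_frequency(rep(3, 500), bin_ms = 1)
  expect_true(is.na(flat))
  expect_equal(attr(flat, "reason"), "flat_histogram")
  # Poisson spikes rate-modulated at 100 Hz
  set.seed(12)
  lam <- 2 * (1 + 0.8 * sin(2 * pi * 100 * t / 1000))
  pois <- rpois(length(t), lam)
  fp <- histogram_autocorr_frequency(pois, bin_ms = 1)
  expect_equal(fp, 100, tolerance = 0.12)
})

test_that("scaling a trace scales power quadratically, not frequency or SNR", {
  g <- generate_current_trace(surrogate_spec(gamma_freq = 110, gamma_amp = 30,
                                             noise_sd = 5, seed = 13))
  s1 <- cycle_average_scalogram(g$trace, g$fs)
  s3 <- cycle_average_scalogram(3 * g$trace, g$fs)
  p1 <- find_gamma_peak(s1); p3 <- find_gamma_peak(s3)
  expect_equal(p3$power / p1$power, 9, tolerance = 1e-6)
  expect_equal(p3$frequency, p1$frequency)
  expect_equal(p3$snr, p1$snr, tolerance = 1e-6)
})

test_that("peak recovery holds across the gamma band at moderate noise", {
  step <- 2^(1 / 32)
  hits <- 0; n_tot <- 0
  for (f in c(60, 100, 140)) for (r in 1:5) {
    # amplitude/noise chosen for a power SNR of ~10 at the crest
    g <- generate_current_trace(surrogate_spec(gamma_freq = f,
                                               gamma_amp = 30,
                                               noise_sd = 30 / sqrt(2 * 10),
                                               seed = 100 * f + r))
    pk <- find_gamma_peak(cycle_average_scalogram(g$trace, g$fs))
    n_tot <- n_tot + 1
    if (abs(log(pk$frequency / f)) <= log(step) + 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_tot, 0.95)
})
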