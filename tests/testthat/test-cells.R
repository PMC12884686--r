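test_that("PV membrane derivative follows the driving-force convention", {
  p <- pv_cell_params()
  st <- cell_state(-40, c(m = 0.3, h = 0.8, n = 0.2, a = 0.1))
  # all conductances zero -> dV/dt = 0 at any V
  p0 <- pv_cell_params(g_na = 0, g_kv1 = 0, g_kv3 = 0, g_leak = 0)
  expect_equal(pv_membrane_derivative(p0, st), 0)
  # leak only, V = E_L -> rest
  pl <- pv_cell_params(g_na = 0, g_kv1 = 0, g_kv3 = 0, g_leak = 10)
  expect_equal(pv_membrane_derivative(pl, cell_state(-65,
    c(m = 0, h = 1, n = 0, a = 0))), 0)
  # term-by-term oracle with drive, synaptic and gap currents
  v <- st$v; g <- st$gates
  i_na <- p$g_na * g[["m"]]^3 * g[["h"]] * (p$e_na - v)
  i_k1 <- p$g_kv1 * g[["a"]]^4 * (p$e_k - v)
  i_k3 <- p$g_kv3 * g[["n"]]^4 * (p$e_k - v)
  i_l <- p$g_leak * (p$e_leak - v)
  i_drv <- 2.5 * (0 - v)
  expect_equal(
    pv_membrane_derivative(p, st, g_drive = 2.5, i_syn = -30, i_gap = 12),
    (i_na + i_k1 + i_k3 + i_l + i_drv - 30 + 12) / p$cm, tolerance = 1e-12)
  expect_error(pv_cell_params(cm = 0), "positive")
  expect_error(pv_cell_params(g_na = -1), ">= 0")
})

test_that("OU exact update has the correct stationary moments", {
  prm <- ou_process_params(mean_g = 0.9, sd_g = 0.02, tau = 2.728,
                           e_rev = -75)
  # degenerate: sd 0 keeps the mean forever
  expect_equal(ou_step(ou_process_params(0.9, 0, tau = 2.728, e_rev = 0),
                       0.9, 0.5), 0.9)
  # 1e6 total samples: 1000 chains x 1000 sequential steps
  set.seed(7)
  nch <- 1000L
  g <- rnorm(nch, 0.9, 0.02)
  acc_m <- 0; acc_s <- 0; nacc <- 0
  lag_tau <- round(prm$tau)  # lag ~ tau with dt = 1 ms
  hist <- matrix(NA_real_, nch, 1000)
  for (k in 1:1000) {
    g <- ou_step(prm, g, dt = 1)
    hist[, k] <- g
  }
  expect_equal(mean(hist), 0.9, tolerance = 0.001)
  expect_equal(sd(hist), 0.02, tolerance = 0.002 / 0.02)
  # autocorrelation at lag tau ~ e^-1 (exact discretization is
  # dt-independent, so lag 2.728 ms is interpolated between integer lags)
  r1 <- cor(as.vector(hist[, 1:(1000 - 3)]), as.vector(hist[, 4:1000]))
  r0 <- cor(as.vector(hist[, 1:(1000 - 2)]), as.vector(hist[, 3:1000]))
  r_tau <- r0 + (r1 - r0) * (prm$tau - 2)  # linear interp between lags 2, 3
  expect_equal(r_tau, exp(-1), tolerance = 0.05)
  expect_error(ou_step(prm, 0.9, 0), "positive")
})

test_that("exact OU statistics are step-size independent", {
  prm <- ou_process_params(0.9, 0.02, tau = 10.49, e_rev = 0)
  set.seed(11)
  for (dt in c(0.025, 1)) {
    g <- rep(0.9, 4000)
    for (k in seq_len(round(50 / dt))) g <- ou_step(prm, g, dt)
    expect_equal(sd(g), 0.02, tolerance = 0.1)
    expect_equal(mean(g), 0.9, tolerance = 0.001)
  }
})

test_that("stellate conductance jitter is truncated and unbiased", {
  p <- e_cell_params(jitter_cv = 0.5)  # exaggerated CV to exercise truncation
  set.seed(3)
  pop <- jitter_e_population(p, 4000)
  expect_true(all(pop$g_na >= 0 & pop$g_k >= 0 & pop$g_leak >= 0))
  # population mean within 3 SE of nominal (truncation bias negligible at
  # the default CV; allow the analytic SE of the untruncated Gaussian)
  p2 <- e_cell_params()
  pop2 <- jitter_e_population(p2, 4000)
  se <- p2$g_na * p2$jitter_cv / sqrt(4000)
  expect_lt(abs(mean(pop2$g_na) - p2$g_na), 3 * se)
})

test_that("E-cell membrane derivative includes multiplicative OU conductances", {
  p <- e_cell_params()
  noise <- e_cell_noise_params()
  st <- cell_state(-60, c(m = 0.1, h = 0.6, n = 0.3),
                   ou_g = c(e_noise = 1.2, i_noise = 0.7))
  base <- e_membrane_derivative(p, cell_state(-60, st$gates), g_drive = 1)
  full <- e_membrane_derivative(p, st, g_drive = 1, noise = noise)
  expected_noise <- (1.2 * (0 - -60) + 0.7 * (-75 - -60)) / p$cm
  expect_equal(full - base, expected_noise, tolerance = 1e-12)
})
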