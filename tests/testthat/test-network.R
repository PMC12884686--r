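test_that("network sampling honors the printed connection statistics", {
  spec <- connectivity_spec(seed = 5)
  net <- build_network(spec)
  ch <- net$chemical
  # structural invariants
  expect_false(any(ch$pre == ch$post & ch$class == "II"))
  expect_true(all(ch$delay >= 0.6 & ch$delay <= 1.0))
  expect_true(all(ch$weight > 0 | ch$class == "EI"))  # EI weight 0 when ei_gmax 0
  expect_true(all(ch$class %in% c("II", "IE", "EI")))  # no E-E class exists
  expect_false(any(duplicated(net$gap[c("a", "b")])))
  expect_length(net$readout_i, 5)
  expect_length(net$readout_e, 5)
  # binomial edge-count concentration over 15 seeds (99% interval)
  classes <- list(II = c(100 * 99, 0.30), IE = c(100 * 400, 0.40),
                  EI = c(400 * 100, 0.30), gap = c(choose(100, 2), 0.18))
  counts <- sapply(1:15, function(sd) {
    n <- build_network(connectivity_spec(seed = sd))
    c(II = sum(n$chemical$class == "II"),
      IE = sum(n$chemical$class == "IE"),
      EI = sum(n$chemical$class == "EI"),
      gap = nrow(n$gap))
  })
  for (cl in names(classes)) {
    np <- classes[[cl]][1] * classes[[cl]][2]
    s <- sqrt(np * (1 - classes[[cl]][2]))
    expect_true(all(abs(counts[cl, ] - np) < 2.58 * s + 3 * s / sqrt(15)),
                info = cl)
  }
})

test_that("zero probabilities give empty edge lists", {
  net <- build_network(connectivity_spec(p_ii = 0, p_ie = 0, p_ei = 0,
                                         p_gap = 0, seed = 1))
  expect_equal(nrow(net$chemical), 0)
  expect_equal(nrow(net$gap), 0)
})

test_that("the same seed reproduces the graph exactly", {
  a <- build_network(connectivity_spec(seed = 42))
  b <- build_network(connectivity_spec(seed = 42))
  expect_identical(a, b)
  c <- build_network(connectivity_spec(seed = 43))
  expect_false(identical(a$chemical, c$chemical))
})

test_that("log-normal weights have the scaled mean and stay positive", {
  expect_length(sample_lognormal_weights(0, 1), 0)
  set.seed(9)
  w <- sample_lognormal_weights(1e5, base_mean = 1, scale = 2.5, cv = 1)
  expect_true(all(w > 0))
  expect_equal(mean(w), 2.5, tolerance = 0.05 / 2.5)
  # degenerate distribution at cv = 0
  expect_equal(sample_lognormal_weights(10, 2, 2.5, cv = 0), rep(5, 10))
  expect_error(sample_lognormal_weights(5, 0), "positive")
})

test_that("E->I weights implement the mean-total-conductance convention", {
  net <- build_network(connectivity_spec(seed = 1, ei_gmax = 60))
  w <- net$chemical$weight[net$chemical$class == "EI"]
  expect_equal(unique(w), 60 / (0.30 * 400))
  netp <- build_network(connectivity_spec(seed = 1, ei_gmax = 0.5,
                                          ei_total = FALSE))
  wp <- netp$chemical$weight[netp$chemical$class == "EI"]
  expect_equal(unique(wp), 0.5)
})

test_that("graph serialization round-trips losslessly", {
  net <- build_network(tiny_spec(seed = 8))
  dir <- withr::local_tempdir()
  write_network(net, dir)
  back <- read_network(dir)
  expect_equal(back$spec, net$spec)
  expect_equal(back$chemical, net$chemical, tolerance = 1e-12)
  expect_equal(back$gap, net$gap, tolerance = 1e-12)
  expect_equal(back$readout_i, net$readout_i)
  expect_equal(back$readout_e, net$readout_e)
})

test_that("spec validation rejects malformed input", {
  expect_error(connectivity_spec(p_ii = 1.2), "\\[0, 1\\]")
  expect_error(connectivity_spec(delay_range = c(1, 0.6)), "low < high")
  expect_error(connectivity_spec(n_i = 0), "positive")
})

test_that("a model configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  pv <- pv_cell_params(g_na = 1234, jitter_cv = 0.07)
  sp <- connectivity_spec(seed = 11, ei_gmax = 24)
  sy <- synapse_params(gaba_rev_ii = -55)
  write_model_config(path, pv = pv, spec = sp, syn = sy)
  back <- read_model_config(path)
  expect_equal(back$pv, pv)
  expect_equal(back$spec, sp)
  expect_equal(back$syn, sy)
  expect_equal(back$drive, drive_spec())
})
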