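# encode the gating table for the C++ core; the inactivation flag is 0
# (activation), 1 (swapped form) or 2 (hardcoded Wang-Buzsaki h, phi = 5)
pv_kin_matrix <- function(pv) {
  kin <- pv$kinetics
  m <- do.call(rbind, lapply(kin[c("m", "h", "n", "a")], function(k)
    c(k$theta, k$sigma1, k$sigma2, k$k1, k$k2, as.numeric(k$is_inactivation))))
  if (identical(pv$h_form, "wb")) m["h", 6] <- 2
  m
}

#' Integrate the E-I-I network under simulated optogenetic theta drive
#'
#' Runs the full conductance-based network: unclamped cells are integrated
#' with a fixed-step exponential-Euler scheme (gating rates and peer voltages
#' frozen within a step), readout cells are held at exactly `v_hold` by an
#' algebraic constraint while their synaptic current is recorded, spikes are
#' detected as upward crossings of 0 mV (1 ms detection refractory) and
#' propagated through the per-edge delays (rounded to the integration grid).
#' The pair `(network, seed, dt)` fully determines the result.
#'
#' The recorded clamp current reports synaptic current only (the experimental
#' isolation of IPSCs at 0 mV); set `include_drive_in_clamp = TRUE` to add
#' the cell's own drive current for sensitivity checks. Clamped cells are
#' detached from gap junctions unless `readout_gap = TRUE` (a node pinned at
#' the holding potential would act as a current sink).
#'
#' @param net an [build_network()] object
#' @param drive a [drive_spec()]
#' @param syn a [synapse_params()]
#' @param pv a [pv_cell_params()]
#' @param ecell an [e_cell_params()]
#' @param noise list as from [e_cell_noise_params()], or `NULL` to disable
#'   the OU conductance noise
#' @param dt integration step (ms); default 0.025
#' @param record_dt sampling interval of the recorded traces (ms)
#' @param seed integer seed of the runtime RNG stream (initial conditions,
#'   drive-peak heterogeneity draw, OU noise); defaults to the connectivity
#'   seed plus a fixed offset so campaigns need only one seed list
#' @param jitter_seed seed for the stellate conductance-jitter draw; fixed by
#'   default so different connectivity seeds share one heterogeneous
#'   population (set to `NULL` to draw from the runtime stream instead)
#' @param v_hold holding potential of the readout cells (mV)
#' @param readout_gap keep clamped interneurons in the gap-junction graph
#' @param include_drive_in_clamp add the drive current to recorded traces
#' @return Object of class `mec_simulation`: spike times per cell
#'   (`spikes_i`, `spikes_e`, ms), clamp-current traces (`clamp_i`,
#'   `clamp_e`; matrices time x readout, pA), `time` (ms), `drive`
#'   (normalized envelope), sampling rate `fs` (Hz), and the configuration
#'   used.
#' @examples
#' net <- build_network(connectivity_spec(n_i = 20, n_e = 40, seed = 1))
#' sim <- run_simulation(net, drive = drive_spec(n_cycles = 3))
#' summary(sim)
#' @export
run_simulation <- function(net, drive = drive_spec(), syn = synapse_params(),
                           pv = pv_cell_params(), ecell = e_cell_params(),
                           noise = e_cell_noise_params(),
                           dt = 0.025, record_dt = 0.5,
                           seed = net$spec$seed + 10000L,
                           jitter_seed = 1000L,
                           v_hold = 0, readout_gap = FALSE,
                           include_drive_in_clamp = FALSE) {
  stopifnot(inherits(net, "mec_network"), inherits(drive, "drive_spec"),
            inherits(syn, "synapse_params"))
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms")
  stride <- round(record_dt / dt)
  if (abs(stride * dt - record_dt) > 1e-9)
    stop("record_dt must be a multiple of dt")
  spec <- net$spec
  duration <- drive$n_cycles * 1000 / drive$freq
  n_steps <- round(duration / dt)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # population heterogeneity (shared across connectivity seeds by default)
  if (!is.null(jitter_seed)) set.seed(jitter_seed)
  else set.seed(seed)
  epop <- jitter_e_population(ecell, spec$n_e)
  ipop <- jitter_pv_population(pv, spec$n_i)

  set.seed(seed)
  peaks_i <- pmax(0, rnorm(spec$n_i, drive$peak_i_mean, drive$peak_i_sd))
  peaks_e <- rep(drive$peak_e, spec$n_e)
  v0_i <- runif(spec$n_i, -70, -60)
  v0_e <- runif(spec$n_e, -70, -60)

  clamp_i <- seq_len(spec$n_i) %in% net$readout_i
  clamp_e <- seq_len(spec$n_e) %in% net$readout_e

  ch <- net$chemical
  dsteps <- as.integer(pmax(1L, round(ch$delay / dt)))
  cls <- ch$class
  ii <- which(cls == "II"); ie <- which(cls == "IE"); ei <- which(cls == "EI")

  gap <- net$gap
  if (!readout_gap && nrow(gap))
    gap <- gap[!(gap$a %in% net$readout_i | gap$b %in% net$readout_i), ,
               drop = FALSE]

  ou_on <- !is.null(noise)
  if (!ou_on) noise <- e_cell_noise_params()
  ou_par <- rbind(
    with(noise$e_noise, c(mean_g, sd_g, tau, e_rev)),
    with(noise$i_noise, c(mean_g, sd_g, tau, e_rev)))

  pv_kin <- pv_kin_matrix(pv)

  res <- run_network_cpp(
    n_i = spec$n_i, n_e = spec$n_e,
    pv_par = c(pv$cm, pv$e_na, pv$e_k, pv$e_leak),
    i_gna = ipop$g_na, i_gkv1 = ipop$g_kv1, i_gkv3 = ipop$g_kv3,
    i_gl = ipop$g_leak,
    pv_kin = pv_kin,
    e_cm = ecell$cm, e_gna = epop$g_na, e_gk = epop$g_k, e_gl = epop$g_leak,
    e_rev = c(ecell$e_na, ecell$e_k, ecell$e_leak),
    ou_par = ou_par, ou_on = ou_on,
    peaks_i = peaks_i, peaks_e = peaks_e, drive_freq = drive$freq,
    ii_pre = ch$pre[ii], ii_post = ch$post[ii], ii_w = ch$weight[ii],
    ii_d = dsteps[ii],
    ie_pre = ch$pre[ie], ie_post = ch$post[ie], ie_w = ch$weight[ie],
    ie_d = dsteps[ie],
    ei_pre = ch$pre[ei], ei_post = ch$post[ei], ei_w = ch$weight[ei],
    ei_d = dsteps[ei],
    gap_a = gap$a, gap_b = gap$b, gap_g = gap$g,
    syn_par = c(syn$II$tau_rise, syn$II$tau_decay, syn$II$e_rev,
                syn$IE$tau_rise, syn$IE$tau_decay, syn$IE$e_rev,
                syn$EI$tau_decay, syn$EI$e_rev),
    clamp_i = clamp_i, clamp_e = clamp_e, v_hold = v_hold,
    dt = dt, n_steps = n_steps, record_stride = stride,
    v0_i = v0_i, v0_e = v0_e,
    include_drive_in_clamp = include_drive_in_clamp)

  structure(
    list(spikes_i = res$spikes_i, spikes_e = res$spikes_e,
         clamp_i = res$clamp_i, clamp_e = res$clamp_e,
         time = res$time, drive = res$drive,
         fs = 1000 / record_dt, dt = dt, record_dt = record_dt,
         duration = duration, theta_freq = drive$freq,
         n_cycles = drive$n_cycles, seed = seed,
         readout_i = net$readout_i, readout_e = net$readout_e,
         spec = spec, drive_spec = drive, syn = syn,
         first_cycle_discarded = TRUE),
    class = "mec_simulation")
}

#' Simulate a built network (S3 method)
#'
#' Convenience wrapper around [run_simulation()]: `simulate(net)` runs the
#' network under the default theta drive.
#'
#' @param object an `mec_network`
#' @param nsim number of simulations (each advances the runtime seed by one)
#' @param seed base runtime seed (default: connectivity seed + offset)
#' @param ... passed to [run_simulation()]
#' @return A single `mec_simulation` if `nsim = 1`, else a list of them.
#' @export
simulate.mec_network <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$spec$seed + 10000L
  sims <- lapply(seq_len(nsim) - 1L, function(k)
    run_simulation(object, seed = seed + k, ...))
  if (nsim == 1) sims[[1]] else sims
}

#' Run a single isolated model cell
#'
#' Integrates one PV+ interneuron or one stellate cell with no synaptic
#' input, either under a constant drive conductance (`drive_freq = 0`) or
#' under the theta waveform. Used for calibration and convergence checks.
#'
#' @param type `"pv"` or `"e"`
#' @param g_drive peak (or constant) drive conductance (nS), reversal 0 mV
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param drive_freq drive frequency in Hz; 0 means constant drive
#' @param v0 initial membrane potential (mV)
#' @param pv,ecell cell parameter objects
#' @param noise OU noise for the E cell (`NULL` disables; the default)
#' @param record_dt trace sampling interval (ms)
#' @param record_v also return the sampled voltage trace
#' @return List with `spikes` (ms), `time`, optionally `v` (mV), and the
#'   firing `rate` (Hz).
#' @export
run_single_cell <- function(type = c("pv", "e"), g_drive = 4,
                            duration = 1000, dt = 0.025, drive_freq = 0,
                            v0 = -65, pv = pv_cell_params(),
                            ecell = e_cell_params(), noise = NULL,
                            record_dt = dt, record_v = FALSE) {
  type <- match.arg(type)
  n_i <- if (type == "pv") 1L else 0L
  n_e <- if (type == "e") 1L else 0L
  ou_on <- !is.null(noise)
  if (!ou_on) noise <- e_cell_noise_params()
  ou_par <- rbind(
    with(noise$e_noise, c(mean_g, sd_g, tau, e_rev)),
    with(noise$i_noise, c(mean_g, sd_g, tau, e_rev)))
  pv_kin <- pv_kin_matrix(pv)
  e0 <- integer(0)
  res <- run_network_cpp(
    n_i = n_i, n_e = n_e,
    pv_par = c(pv$cm, pv$e_na, pv$e_k, pv$e_leak),
    i_gna = rep(pv$g_na, n_i), i_gkv1 = rep(pv$g_kv1, n_i),
    i_gkv3 = rep(pv$g_kv3, n_i), i_gl = rep(pv$g_leak, n_i),
    pv_kin = pv_kin,
    e_cm = ecell$cm,
    e_gna = rep(ecell$g_na, n_e), e_gk = rep(ecell$g_k, n_e),
    e_gl = rep(ecell$g_leak, n_e),
    e_rev = c(ecell$e_na, ecell$e_k, ecell$e_leak),
    ou_par = ou_par, ou_on = ou_on,
    peaks_i = rep(g_drive, n_i), peaks_e = rep(g_drive, n_e),
    drive_freq = drive_freq,
    ii_pre = e0, ii_post = e0, ii_w = numeric(0), ii_d = e0,
    ie_pre = e0, ie_post = e0, ie_w = numeric(0), ie_d = e0,
    ei_pre = e0, ei_post = e0, ei_w = numeric(0), ei_d = e0,
    gap_a = e0, gap_b = e0, gap_g = numeric(0),
    syn_par = c(0.3, 4, -75, 0.4, 6, -65, 1, 0),
    clamp_i = rep(FALSE, n_i), clamp_e = rep(FALSE, n_e), v_hold = 0,
    dt = dt, n_steps = round(duration / dt),
    record_stride = max(1L, round(record_dt / dt)),
    v0_i = rep(v0, n_i), v0_e = rep(v0, n_e),
    include_drive_in_clamp = FALSE, record_v = record_v)
  spikes <- if (type == "pv") res$spikes_i[[1]] else res$spikes_e[[1]]
  list(spikes = spikes, time = res$time,
       v = if (record_v) (if (type == "pv") res$v_i[, 1] else res$v_e[, 1]),
       rate = 1000 * length(spikes) / duration,
       v_final = if (type == "pv") res$v_final_i[1] else res$v_final_e[1])
}

#' @export
print.mec_simulation <- function(x, ...) {
  cat(sprintf(
    "mEC network simulation: %d I + %d E cells, %g theta cycles at %g Hz\n",
    x$spec$n_i, x$spec$n_e, x$n_cycles, x$theta_freq))
  cat(sprintf("  duration %g ms, dt %g ms, runtime seed %d\n",
              x$duration, x$dt, x$seed))
  cat(sprintf("  readouts clamped: %d I, %d E; traces sampled at %g kHz\n",
              length(x$readout_i), length(x$readout_e), x$fs / 1000))
  invisible(x)
}

#' @export
summary.mec_simulation <- function(object, ...) {
  unclamped_i <- setdiff(seq_len(object$spec$n_i), object$readout_i)
  unclamped_e <- setdiff(seq_len(object$spec$n_e), object$readout_e)
  n_cyc <- object$n_cycles
  rate_i <- vapply(object$spikes_i[unclamped_i], length, 1L) / n_cyc
  rate_e <- vapply(object$spikes_e[unclamped_e], length, 1L) / n_cyc
  out <- list(
    spikes_per_cycle_i = mean(rate_i),
    spikes_per_cycle_e = mean(rate_e),
    active_frac_i = mean(rate_i > 0),
    active_frac_e = mean(rate_e > 0),
    clamp_e_sd = apply(object$clamp_e, 2, sd))
  class(out) <- "summary.mec_simulation"
  out
}

#' @export
print.summary.mec_simulation <- function(x, ...) {
  cat(sprintf("I cells: %.2f spikes/theta cycle (%.0f%% active)\n",
              x$spikes_per_cycle_i, 100 * x$active_frac_i))
  cat(sprintf("E cells: %.2f spikes/theta cycle (%.0f%% active)\n",
              x$spikes_per_cycle_e, 100 * x$active_frac_e))
  cat(sprintf("E readout clamp-current SD (pA): %s\n",
              paste(sprintf("%.1f", x$clamp_e_sd), collapse = ", ")))
  invisible(x)
}

#' Population spike-time histogram
#'
#' Bins all spikes of one population into fixed-width time bins over the
#' analyzed window (first theta cycle discarded by default).
#'
#' @param sim an `mec_simulation`
#' @param population `"e"` or `"i"`
#' @param bin_ms bin width (ms)
#' @param discard_first drop spikes from the first theta cycle
#' @return List with `counts`, bin `centers` (ms) and `bin_ms`.
#' @export
population_histogram <- function(sim, population = c("e", "i"), bin_ms = 1,
                                 discard_first = TRUE) {
  population <- match.arg(population)
  sp <- if (population == "e") sim$spikes_e else sim$spikes_i
  ro <- if (population == "e") sim$readout_e else sim$readout_i
  sp <- unlist(sp[setdiff(seq_along(sp), ro)], use.names = FALSE)
  t0 <- if (discard_first) 1000 / sim$theta_freq else 0
  sp <- sp[sp >= t0 & sp <= sim$duration]
  breaks <- seq(t0, sim$duration + bin_ms, by = bin_ms)
  counts <- tabulate(findInterval(sp, breaks), nbins = length(breaks) - 1L)
  list(counts = counts, centers = breaks[-length(breaks)] + bin_ms / 2,
       bin_ms = bin_ms)
}

#' @export
plot.mec_simulation <- function(x, what = c("raster", "clamp"), ...) {
  what <- match.arg(what)
  if (what == "raster") {
    n_i <- x$spec$n_i
    plot(NULL, xlim = c(0, x$duration), ylim = c(0, n_i + x$spec$n_e),
         xlab = "time (ms)", ylab = "cell", ...)
    for (i in seq_along(x$spikes_i)) {
      s <- x$spikes_i[[i]]
      if (length(s)) points(s, rep(i, length(s)), pch = ".", col = "blue")
    }
    for (j in seq_along(x$spikes_e)) {
      s <- x$spikes_e[[j]]
      if (length(s)) points(s, rep(n_i + j, length(s)), pch = ".",
                            col = "red")
    }
  } else {
    plot(x$time, x$clamp_e[, 1], type = "l", xlab = "time (ms)",
         ylab = "clamp current (pA)", ...)
  }
  invisible(x)
}
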