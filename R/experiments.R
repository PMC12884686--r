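#' Analyze the clamped readout cells of a simulation
#'
#' Runs the full spectral pipeline on each recorded clamp trace: band-pass,
#' cycle-averaged Morlet scalogram with artifact/first-cycle exclusion, gamma
#' peak with QC, and total gamma power.
#'
#' @param sim an [run_simulation()] result
#' @param population `"e"` (default) or `"i"` readouts
#' @param criteria a [qc_criteria()]
#' @return Data frame, one row per readout: `readout`, `peak_freq` (Hz),
#'   `peak_power` (pA^2), `total_power` (pA^2), `snr`, `bandwidth` (Hz),
#'   `qc_pass`, `qc_reasons`, `n_cycles_used`.
#' @export
analyze_readouts <- function(sim, population = c("e", "i"),
                             criteria = qc_criteria()) {
  population <- match.arg(population)
  tr <- if (population == "e") sim$clamp_e else sim$clamp_i
  ids <- if (population == "e") sim$readout_e else sim$readout_i
  out <- lapply(seq_along(ids), function(k) {
    res <- tryCatch({
      scal <- cycle_average_scalogram(tr[, k], fs = sim$fs,
                                      theta_freq = sim$theta_freq,
                                      criteria = criteria)
      pk <- find_gamma_peak(scal, criteria)
      data.frame(readout = ids[k], peak_freq = pk$frequency,
                 peak_power = pk$power,
                 total_power = total_gamma_power(scal, criteria),
                 snr = pk$snr, bandwidth = pk$bandwidth,
                 qc_pass = pk$passed_qc,
                 qc_reasons = paste(pk$reasons, collapse = ";"),
                 n_cycles_used = scal$n_cycles_used)
    }, error = function(e) NULL)
    if (is.null(res)) {
      # recording unusable (e.g. every cycle artifact-contaminated):
      # excluded from analysis, like an experimental recording would be
      res <- data.frame(readout = ids[k], peak_freq = NA_real_,
                        peak_power = NA_real_, total_power = NA_real_,
                        snr = NA_real_, bandwidth = NA_real_,
                        qc_pass = FALSE, qc_reasons = "recording_excluded",
                        n_cycles_used = 0L)
    }
    res
  })
  do.call(rbind, out)
}

run_condition <- function(ei_gmax, ie_scale, seed, base_spec, drive, syn,
                          criteria, ...) {
  spec_args <- unclass(base_spec)
  spec_args$ei_gmax <- ei_gmax
  spec_args$ie_base_mean <- base_spec$ie_base_mean * ie_scale
  spec_args$seed <- as.integer(seed)
  net <- build_network(do.call(connectivity_spec, spec_args))
  sim <- run_simulation(net, drive = drive, syn = syn, ...)
  rows <- analyze_readouts(sim, "e", criteria)
  cbind(data.frame(ei_gmax = ei_gmax, ie_scale = ie_scale,
                   gaba_rev = syn$II$e_rev, seed = seed), rows)
}

#' Sweep the E-to-I synaptic conductance
#'
#' The main in-silico campaign: for each (conductance, seed) pair a network
#' is built, simulated under the theta drive, and the clamp currents of the
#' five E readout cells are analyzed. Individual run failures are recorded
#' and the campaign continues.
#'
#' @param conductances E->I mean total conductances (nS); at least two values
#'   including 0 for the canonical sweep, but any nonempty set is accepted
#' @param seeds connectivity seeds
#' @param base_spec a [connectivity_spec()] used as the template
#' @param drive a [drive_spec()]
#' @param syn a [synapse_params()]
#' @param criteria a [qc_criteria()]
#' @param ... passed to [run_simulation()] (e.g. `dt`)
#' @return Object of class `mec_sweep`: data frame with one row per
#'   (condition, seed, readout) plus an `errors` attribute.
#' @export
sweep_ei <- function(conductances, seeds = 1:3,
                     base_spec = connectivity_spec(),
                     drive = drive_spec(), syn = synapse_params(),
                     criteria = qc_criteria(), ...) {
  stopifnot(length(conductances) >= 1, all(conductances >= 0))
  rows <- list()
  errors <- list()
  for (g in conductances) for (sd in seeds) {
    r <- tryCatch(
      run_condition(g, 1, sd, base_spec, drive, syn, criteria, ...),
      error = function(e)
        structure(conditionMessage(e), failed_condition = c(g, sd)))
    if (is.character(r)) errors[[length(errors) + 1L]] <- r
    else rows[[length(rows) + 1L]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_sweep()
  attr(out, "errors") <- errors
  class(out) <- c("mec_sweep", class(out))
  out
}

empty_sweep <- function() {
  data.frame(ei_gmax = numeric(0), ie_scale = numeric(0),
             gaba_rev = numeric(0), seed = integer(0), readout = integer(0),
             peak_freq = numeric(0), peak_power = numeric(0),
             total_power = numeric(0), snr = numeric(0),
             bandwidth = numeric(0), qc_pass = logical(0),
             qc_reasons = character(0), n_cycles_used = integer(0))
}

#' Factorial E-to-I x I-to-E campaign
#'
#' Full factorial sweep over E->I conductance and a multiplicative scale on
#' the mean of the log-normal I->E weights, across seeds.
#'
#' @param ei_grid E->I conductances (nS)
#' @param ie_grid I->E mean scale factors (1 = the template's mean)
#' @inheritParams sweep_ei
#' @return An `mec_sweep` (see [sweep_ei()]).
#' @export
heatmap_ei_ie <- function(ei_grid, ie_grid, seeds = 1:9,
                          base_spec = connectivity_spec(),
                          drive = drive_spec(), syn = synapse_params(),
                          criteria = qc_criteria(), ...) {
  stopifnot(length(ei_grid) >= 1, length(ie_grid) >= 1)
  rows <- list()
  errors <- list()
  for (g in ei_grid) for (s in ie_grid) for (sd in seeds) {
    r <- tryCatch(
      run_condition(g, s, sd, base_spec, drive, syn, criteria, ...),
      error = function(e)
        structure(conditionMessage(e), failed_condition = c(g, s, sd)))
    if (is.character(r)) errors[[length(errors) + 1L]] <- r
    else rows[[length(rows) + 1L]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_sweep()
  attr(out, "errors") <- errors
  class(out) <- c("mec_sweep", class(out))
  out
}

#' Shunting-inhibition control
#'
#' Replaces the I->I GABA_A reversal with the shunting value (-55 mV by
#' default) while I->E and the E-cell noise keep their own reversals, and
#' reports gamma presence (QC pass of the scalogram peak) per condition.
#'
#' @param conductances E->I conductances to test (canonically `c(0, 60)` nS)
#' @param gaba_rev_ii shunting I->I reversal potential (mV)
#' @inheritParams sweep_ei
#' @return An `mec_sweep` with an additional `gamma_present` summary
#'   attribute (named logical per conductance: any QC-passing readout).
#' @export
shunting_control <- function(conductances = c(0, 60), seeds = 1:3,
                             gaba_rev_ii = -55,
                             base_spec = connectivity_spec(),
                             drive = drive_spec(),
                             criteria = qc_criteria(), ...) {
  syn <- synapse_params(gaba_rev_ii = gaba_rev_ii)
  out <- sweep_ei(conductances, seeds, base_spec, drive, syn, criteria, ...)
  pres <- vapply(conductances, function(g)
    any(out$qc_pass[out$ei_gmax == g]), TRUE)
  names(pres) <- as.character(conductances)
  attr(out, "gamma_present") <- pres
  out
}

#' Classify a run as ING- or PING-dominated from interneuron burst structure
#'
#' In the ING regime interneurons fire single spikes at the network period;
#' with strong E->I drive their firing groups into bursts and the network
#' period is set by the interburst interval. Spikes of each unclamped
#' interneuron are grouped into bursts using a gap threshold of half the
#' gamma period; the run is labeled PING-dominated when the mean number of
#' spikes per burst among active cells exceeds `burst_thresh` and the median
#' interburst interval matches the network gamma period within 20%.
#'
#' @param sim an [run_simulation()] result
#' @param gamma_freq QC-passing network gamma frequency (Hz)
#' @param burst_thresh spikes-per-burst threshold (1.5)
#' @param min_spikes minimum total I spikes for a defined label
#' @return Object of class `regime_label`: `label` (`"ING-dominated"`,
#'   `"PING-dominated"` or `"undefined"`), `spikes_per_burst`,
#'   `interburst_ms`, `network_period_ms`, `reason` (when undefined).
#' @export
classify_regime <- function(sim, gamma_freq, burst_thresh = 1.5,
                            min_spikes = 100) {
  period <- 1000 / gamma_freq
  gap <- period / 2
  unclamped <- setdiff(seq_along(sim$spikes_i), sim$readout_i)
  spb <- c(); ibi <- c(); total <- 0
  for (i in unclamped) {
    s <- sim$spikes_i[[i]]
    s <- s[s >= 1000 / sim$theta_freq]      # skip the discarded first cycle
    total <- total + length(s)
    if (length(s) < 2) next
    d <- diff(s)
    burst_id <- cumsum(c(1, d >= gap))
    sizes <- tabulate(burst_id)
    spb <- c(spb, mean(sizes))
    starts <- s[!duplicated(burst_id)]
    if (length(starts) > 1) ibi <- c(ibi, diff(starts))
    NULL
  }
  if (total < min_spikes || !length(spb)) {
    return(structure(list(label = "undefined", spikes_per_burst = NA_real_,
                          interburst_ms = NA_real_,
                          network_period_ms = period,
                          reason = "insufficient_spikes"),
                     class = "regime_label"))
  }
  mean_spb <- mean(spb)
  med_ibi <- median(ibi[ibi <= 3 * period])  # within-cycle intervals only
  ping <- mean_spb > burst_thresh && is.finite(med_ibi) &&
    abs(med_ibi - period) / period <= 0.2
  structure(list(label = if (ping) "PING-dominated" else "ING-dominated",
                 spikes_per_burst = mean_spb, interburst_ms = med_ibi,
                 network_period_ms = period, reason = NULL),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  if (x$label == "undefined")
    cat(sprintf("Regime: undefined (%s)\n", x$reason))
  else
    cat(sprintf(
      "Regime: %s (%.2f spikes/burst, interburst %.1f ms vs period %.1f ms)\n",
      x$label, x$spikes_per_burst, x$interburst_ms, x$network_period_ms))
  invisible(x)
}

#' Summarize a sweep table by condition
#'
#' Medians across seeds and readouts of the QC-passing rows, per
#' (E->I conductance, I->E scale) condition.
#'
#' @param object an `mec_sweep`
#' @param ... unused
#' @return Data frame with per-condition medians (`median_freq`,
#'   `median_power`, `median_total_power`), QC pass fraction and row counts.
#' @export
summary.mec_sweep <- function(object, ...) {
  key <- interaction(object$ei_gmax, object$ie_scale, drop = TRUE)
  parts <- split(as.data.frame(object), key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- d[d$qc_pass, , drop = FALSE]
    data.frame(ei_gmax = d$ei_gmax[1], ie_scale = d$ie_scale[1],
               gaba_rev = d$gaba_rev[1],
               median_freq = if (nrow(ok)) median(ok$peak_freq) else NA_real_,
               median_power = if (nrow(ok)) median(ok$peak_power) else NA_real_,
               median_total_power =
                 if (nrow(ok)) median(ok$total_power) else NA_real_,
               qc_frac = mean(d$qc_pass), n = nrow(d))
  }))
  out <- out[order(out$ie_scale, out$ei_gmax), ]
  rownames(out) <- NULL
  out
}

#' @export
print.mec_sweep <- function(x, ...) {
  cat(sprintf("E-I sweep table: %d rows (%d conditions, %d seeds)\n",
              nrow(x), length(unique(interaction(x$ei_gmax, x$ie_scale))),
              length(unique(x$seed))))
  err <- attr(x, "errors")
  if (length(err)) cat(sprintf("  %d failed runs recorded\n", length(err)))
  print(summary(x))
  invisible(x)
}

#' Per-seed Spearman correlation of frequency against conductance
#'
#' The monotonicity statistic behind the frequency-vs-E->I trend: for each
#' seed, the Spearman rank correlation between the per-condition median
#' QC-passing peak frequency and the E->I conductance.
#'
#' @param sweep an `mec_sweep`
#' @return Named numeric vector of Spearman rho, one per seed.
#' @export
sweep_spearman <- function(sweep) {
  vapply(split(as.data.frame(sweep), sweep$seed), function(d) {
    ok <- d[d$qc_pass, , drop = FALSE]
    med <- tapply(ok$peak_freq, ok$ei_gmax, median)
    g <- as.numeric(names(med))
    if (length(med) < 2) return(NA_real_)
    cor(g, as.numeric(med), method = "spearman")
  }, 1.0)
}

#' @export
plot.mec_sweep <- function(x, what = c("freq", "power"), ...) {
  what <- match.arg(what)
  col <- if (what == "freq") "peak_freq" else "peak_power"
  ok <- x[x$qc_pass, , drop = FALSE]
  boxplot(ok[[col]] ~ ok$ei_gmax, xlab = "E->I conductance (nS)",
          ylab = if (what == "freq") "peak frequency (Hz)"
                 else "peak power (pA^2)", ...)
  invisible(x)
}
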