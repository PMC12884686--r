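#' Connectivity specification for the E-I-I network
#'
#' Population sizes, connection probabilities and synaptic-weight statistics
#' of the mEC model network: 100 PV+ interneurons (I) and 400 stellate cells
#' (E); I->I connection probability 30%, I->E 40%, E->I 30%; gap-junction
#' probability 18% per unordered I pair; log-normal I->E weights with the
#' arithmetic mean scaled by 2.5; uniform 0.6-1 ms synaptic delays. The E
#' cells are not connected to each other.
#'
#' @param n_i,n_e population sizes
#' @param p_ii,p_ie,p_ei connection probabilities (I->I, I->E, E->I)
#' @param p_gap gap-junction probability per unordered I-cell pair
#' @param ii_g I->I chemical synaptic peak conductance (nS); not constrained
#'   in closed form, calibrated default
#' @param ie_base_mean base arithmetic mean of the log-normal I->E weight
#'   distribution before scaling (nS); calibrated default
#' @param ie_weight_mean_scale multiplier applied to the I->E mean (2.5)
#' @param ie_weight_cv coefficient of variation of the log-normal I->E
#'   weights (shape not constrained in closed form; default 1)
#' @param ei_gmax E->I synaptic conductance (nS) - the swept parameter. With
#'   `ei_total = TRUE` (default) this is the mean TOTAL E->I conductance per
#'   interneuron and each connection gets `ei_gmax / (p_ei * n_e)`; with
#'   `FALSE` it is the per-connection conductance.
#' @param ei_total interpretation switch for `ei_gmax` (see above)
#' @param delay_range synaptic delay range (ms), uniform
#' @param gap_g gap-junction conductance (nS); default gives a ~1-5% coupling
#'   coefficient between resting PV cells
#' @param n_readout voltage-clamped readout cells per population
#' @param seed integer seed for the connectivity RNG stream
#' @return Object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_i = 100, n_e = 400,
                              p_ii = 0.30, p_ie = 0.40, p_ei = 0.30,
                              p_gap = 0.18,
                              ii_g = 0.5, ie_base_mean = 0.3,
                              ie_weight_mean_scale = 2.5, ie_weight_cv = 1,
                              ei_gmax = 0, ei_total = TRUE,
                              delay_range = c(0.6, 1.0), gap_g = 0.3,
                              n_readout = 5, seed = 1) {
  p <- c(p_ii, p_ie, p_ei, p_gap)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (n_i <= 0 || n_e <= 0) stop("population sizes must be positive")
  if (length(delay_range) != 2L || delay_range[1] >= delay_range[2])
    stop("delay_range must be c(low, high) with low < high")
  if (ei_gmax < 0 || ii_g < 0 || gap_g < 0) stop("conductances must be >= 0")
  if (n_readout > min(n_i, n_e)) stop("too many readout cells")
  structure(
    list(n_i = n_i, n_e = n_e, p_ii = p_ii, p_ie = p_ie, p_ei = p_ei,
         p_gap = p_gap, ii_g = ii_g, ie_base_mean = ie_base_mean,
         ie_weight_mean_scale = ie_weight_mean_scale,
         ie_weight_cv = ie_weight_cv, ei_gmax = ei_gmax,
         ei_total = ei_total, delay_range = delay_range, gap_g = gap_g,
         n_readout = n_readout, seed = as.integer(seed)),
    class = "connectivity_spec")
}

#' Sample log-normal synaptic weights with a scaled arithmetic mean
#'
#' Weights are log-normal with arithmetic mean `scale * base_mean` and
#' coefficient of variation `cv`; `cv = 0` gives the degenerate distribution
#' at the scaled mean. All weights are strictly positive.
#'
#' @param n number of weights
#' @param base_mean base arithmetic mean (nS), `> 0`
#' @param scale multiplier on the mean
#' @param cv coefficient of variation
#' @return Numeric vector of `n` weights (nS).
#' @export
sample_lognormal_weights <- function(n, base_mean, scale = 2.5, cv = 1) {
  if (n == 0) return(numeric(0))
  if (base_mean <= 0) stop("base_mean must be positive")
  m <- base_mean * scale
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Sample ordered (pre, post) pairs with probability p, excluding self-edges
# when both index sets refer to the same population.
sample_edges <- function(n_pre, n_post, p, same_pop) {
  if (p == 0) return(data.frame(pre = integer(0), post = integer(0)))
  pre <- rep(seq_len(n_pre), each = n_post)
  post <- rep(seq_len(n_post), times = n_pre)
  if (same_pop) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  sel <- runif(length(pre)) < p
  data.frame(pre = pre[sel], post = post[sel])
}

#' Build a random E-I-I network from a connectivity specification
#'
#' Samples all chemical and electrical edges independently with their class
#' probabilities, draws weights and delays, and designates the voltage-clamped
#' readout cells. The same seed always produces the same graph (connectivity
#' uses its own RNG stream, independent of simulation length or runtime
#' noise). Cells are indexed per population: I cells `1..n_i`, E cells
#' `1..n_e`; the `class` column disambiguates. Readout cells keep their
#' sampled edges in the graph; the simulator ignores outgoing chemical edges
#' of clamped cells (they never spike) and detaches clamped cells from gap
#' junctions unless asked otherwise.
#'
#' @param spec a [connectivity_spec()]
#' @return Object of class `mec_network`: list with `spec`, `chemical`
#'   (data frame: `pre`, `post`, `class`, `weight` nS, `delay` ms), `gap`
#'   (data frame: `a`, `b`, `g` nS), `readout_i`, `readout_e` (cell indices).
#' @examples
#' net <- build_network(connectivity_spec(n_i = 20, n_e = 40, seed = 7))
#' net
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "connectivity_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  readout_i <- sort(sample.int(spec$n_i, spec$n_readout))
  readout_e <- sort(sample.int(spec$n_e, spec$n_readout))

  ii <- sample_edges(spec$n_i, spec$n_i, spec$p_ii, same_pop = TRUE)
  ie <- sample_edges(spec$n_i, spec$n_e, spec$p_ie, same_pop = FALSE)
  ei <- sample_edges(spec$n_e, spec$n_i, spec$p_ei, same_pop = FALSE)

  ii$weight <- rep(spec$ii_g, nrow(ii))
  ie$weight <- sample_lognormal_weights(nrow(ie), spec$ie_base_mean,
                                        spec$ie_weight_mean_scale,
                                        spec$ie_weight_cv)
  ei_w <- if (spec$ei_total) spec$ei_gmax / (spec$p_ei * spec$n_e)
          else spec$ei_gmax
  ei$weight <- rep(ei_w, nrow(ei))

  chem <- rbind(cbind(ii, class = rep("II", nrow(ii))),
                cbind(ie, class = rep("IE", nrow(ie))),
                cbind(ei, class = rep("EI", nrow(ei))))
  chem$delay <- runif(nrow(chem), spec$delay_range[1], spec$delay_range[2])
  chem <- chem[, c("pre", "post", "class", "weight", "delay")]
  rownames(chem) <- NULL

  pairs <- which(upper.tri(matrix(0, spec$n_i, spec$n_i)), arr.ind = TRUE)
  sel <- runif(nrow(pairs)) < spec$p_gap
  gap <- data.frame(a = pairs[sel, 1], b = pairs[sel, 2],
                    g = rep(spec$gap_g, sum(sel)))

  structure(list(spec = spec, chemical = chem, gap = gap,
                 readout_i = readout_i, readout_e = readout_e),
            class = "mec_network")
}

#' @export
print.mec_network <- function(x, ...) {
  tab <- table(factor(x$chemical$class, levels = c("II", "IE", "EI")))
  cat(sprintf("mEC E-I-I network: %d I cells, %d E cells (seed %d)\n",
              x$spec$n_i, x$spec$n_e, x$spec$seed))
  cat(sprintf("  chemical edges: II %d, IE %d, EI %d; gap junctions: %d\n",
              tab[["II"]], tab[["IE"]], tab[["EI"]], nrow(x$gap)))
  cat(sprintf("  E->I conductance: %g nS %s; readouts: %d I + %d E clamped\n",
              x$spec$ei_gmax,
              if (x$spec$ei_total) "(mean total per I cell)"
              else "(per connection)",
              length(x$readout_i), length(x$readout_e)))
  invisible(x)
}

#' @export
summary.mec_network <- function(object, ...) {
  ch <- object$chemical
  by_class <- split(ch, ch$class)
  out <- data.frame(
    class = names(by_class),
    n_edges = vapply(by_class, nrow, 1L),
    mean_weight = vapply(by_class, function(d) mean(d$weight), 1.0),
    mean_delay = vapply(by_class, function(d) mean(d$delay), 1.0))
  rownames(out) <- NULL
  out
}

#' Write / read a network as plain text
#'
#' The graph is stored as two TSV edge tables plus a JSON sidecar holding the
#' connectivity specification and readout indices; [read_network()] restores
#' an identical [build_network()] object (lossless round trip).
#'
#' @param net an `mec_network`
#' @param path directory to write into (created if needed)
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the restored `mec_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "mec_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(net$chemical, file.path(path, "chemical.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(net$gap, file.path(path, "gap.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  side <- unclass(net$spec)
  side$readout_i <- net$readout_i
  side$readout_e <- net$readout_e
  jsonlite::write_json(side, file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  chem <- read.delim(file.path(path, "chemical.tsv"))
  gap <- read.delim(file.path(path, "gap.tsv"))
  side <- jsonlite::read_json(file.path(path, "spec.json"),
                              simplifyVector = TRUE)
  readout_i <- side$readout_i; readout_e <- side$readout_e
  side$readout_i <- NULL; side$readout_e <- NULL
  spec <- do.call(connectivity_spec, side)
  chem$class <- as.character(chem$class)
  structure(list(spec = spec, chemical = chem, gap = gap,
                 readout_i = readout_i, readout_e = readout_e),
            class = "mec_network")
}
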