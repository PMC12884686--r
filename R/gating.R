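#' Gating-variable kinetics for the fast-spiking interneuron model
#'
#' Voltage-dependent opening/closing rates of a Hodgkin-Huxley gating variable
#' in the rate parameterization used by the PV+ interneuron model:
#' \deqn{\alpha(V) = k_1 (\theta - V) / (\exp((\theta - V)/\sigma_1) - 1)}
#' \deqn{\beta(V)  = k_2 \exp(V/\sigma_2)}
#' Activation variables (m, n, a) obey \eqn{dx/dt = \alpha(1-x) - \beta x};
#' the inactivation variable h swaps the roles of the two rates,
#' \eqn{dh/dt = \beta(1-h) - \alpha h}.
#'
#' @param theta half-activation voltage (mV)
#' @param sigma1 slope of the alpha term (mV); must be non-zero
#' @param sigma2 slope of the beta term (mV); must be non-zero
#' @param k1 alpha rate scale (1/ms); must be positive
#' @param k2 beta rate scale (1/ms); must be positive
#' @param is_inactivation logical; if `TRUE` the gate uses the swapped
#'   (inactivation) form of the first-order kinetics
#' @return An object of class `gating_kinetics`.
#' @examples
#' kin <- gating_kinetics(theta = -53, sigma1 = 4, sigma2 = -13,
#'                        k1 = 0.25, k2 = 0.1)
#' alpha_rate(kin, -70)
#' @export
gating_kinetics <- function(theta, sigma1, sigma2, k1, k2,
                            is_inactivation = FALSE) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (sigma1 == 0 || sigma2 == 0)
    stop("sigma1 and sigma2 must be non-zero")
  if (k1 <= 0 || k2 <= 0)
    stop("k1 and k2 must be positive")
  structure(
    list(theta = theta, sigma1 = sigma1, sigma2 = sigma2,
         k1 = k1, k2 = k2, is_inactivation = isTRUE(is_inactivation)),
    class = "gating_kinetics")
}

#' Gating parameters of the PV+ interneuron model
#'
#' The four gating variables of the fast-spiking interneuron: Na+ activation
#' `m`, Na+ inactivation `h`, Kv3 activation `n` and Kv1 activation `a`.
#'
#' The h row is reproduced verbatim, but note that it is dynamically
#' degenerate: `sigma1 = -20` mV makes the closed-form alpha rate negative at
#' every voltage, which under the swapped inactivation kinetics pins h at its
#' upper bound (no Na+ inactivation, hence no spike termination at any
#' drive); transposing the two slopes instead centres h-inactivation near
#' -16 mV, which parks the cell on a stable depolarized plateau after its
#' first spike. Because neither reading yields a working fast-spiking cell,
#' the default PV model replaces this one gate with a calibrated
#' Wang-Buzsaki-type h (see [pv_cell_params()] argument `h_form`); the
#' printed row is kept here for reference and for use via `h_form =
#' "table"`. The methods vignette walks through the full argument.
#'
#' @return Named list of [gating_kinetics()] objects (`m`, `h`, `n`, `a`).
#' @export
pv_kinetics <- function() {
  list(
    m = gating_kinetics(theta = -53,    sigma1 = 4,   sigma2 = -13,
                        k1 = 0.25,  k2 = 0.1),
    h = gating_kinetics(theta = -55.71, sigma1 = -20, sigma2 = 3.5,
                        k1 = 0.012, k2 = 0.2, is_inactivation = TRUE),
    n = gating_kinetics(theta = 5.9,    sigma1 = 12,  sigma2 = -8.5,
                        k1 = 1,     k2 = 0.001),
    a = gating_kinetics(theta = 51.36,  sigma1 = 12,  sigma2 = -80,
                        k1 = 1,     k2 = 0.02))
}

#' Opening (alpha) rate of a gating variable
#'
#' Evaluates \eqn{\alpha(V) = k_1(\theta - V)/(\exp((\theta - V)/\sigma_1)-1)}
#' with a series expansion near the removable singularity at \eqn{V = \theta},
#' where the limit is \eqn{k_1 \sigma_1}.
#'
#' @param kin a [gating_kinetics()] object
#' @param v membrane potential (mV); may be a vector
#' @return Rate in 1/ms, same length as `v`.
#' @export
alpha_rate <- function(kin, v) {
  stopifnot(inherits(kin, "gating_kinetics"))
  if (!all(is.finite(v))) stop("v must be finite")
  u <- (kin$theta - v) / kin$sigma1
  out <- numeric(length(v))
  small <- abs(u) < 1e-6
  # u/(exp(u)-1) = 1 - u/2 + u^2/12 + O(u^4)
  out[small] <- kin$k1 * kin$sigma1 * (1 - u[small] / 2 + u[small]^2 / 12)
  out[!small] <- kin$k1 * kin$sigma1 * u[!small] / expm1(u[!small])
  out
}

#' Closing (beta) rate of a gating variable
#'
#' Evaluates \eqn{\beta(V) = k_2 \exp(V/\sigma_2)}.
#'
#' @inheritParams alpha_rate
#' @return Rate in 1/ms, same length as `v`.
#' @export
beta_rate <- function(kin, v) {
  stopifnot(inherits(kin, "gating_kinetics"))
  if (!all(is.finite(v))) stop("v must be finite")
  kin$k2 * exp(v / kin$sigma2)
}

#' Time derivative of a gating variable
#'
#' First-order kinetics: activation variables use
#' \eqn{dx/dt = \alpha(1-x) - \beta x}; an inactivation variable uses
#' \eqn{dx/dt = \beta(1-x) - \alpha x}.
#'
#' @inheritParams alpha_rate
#' @param x gate value in \[0, 1\]
#' @return dx/dt in 1/ms.
#' @export
gate_derivative <- function(kin, x, v) {
  if (any(x < 0 | x > 1)) stop("gate value x must lie in [0, 1]")
  a <- alpha_rate(kin, v)
  b <- beta_rate(kin, v)
  if (kin$is_inactivation) b * (1 - x) - a * x else a * (1 - x) - b * x
}

#' Voltage-dependent steady state of a gating variable
#'
#' \eqn{x_\infty = \alpha/(\alpha+\beta)} for activation variables and
#' \eqn{\beta/(\alpha+\beta)} for inactivation variables. For the h gate of
#' [pv_kinetics()] the total rate can be negative (see that help page); the
#' steady state is then clipped to \[0, 1\], matching the bound the dynamics
#' converge to under gate clamping.
#'
#' @inheritParams alpha_rate
#' @return Steady-state gate value(s) in \[0, 1\].
#' @export
gate_steady_state <- function(kin, v) {
  a <- alpha_rate(kin, v)
  b <- beta_rate(kin, v)
  num <- if (kin$is_inactivation) b else a
  x <- num / (a + b)
  # negative total rate: unstable fixed point, dynamics run to a bound
  bad <- (a + b) <= 0
  if (any(bad)) {
    d1 <- gate_derivative(kin, rep(1, sum(bad)), v[bad])
    x[bad] <- ifelse(d1 >= 0, 1, 0)
  }
  pmin(1, pmax(0, x))
}

#' @export
print.gating_kinetics <- function(x, ...) {
  cat(sprintf(
    "Gating kinetics (%s): theta=%g mV, sigma1=%g, sigma2=%g, k1=%g, k2=%g /ms\n",
    if (x$is_inactivation) "inactivation" else "activation",
    x$theta, x$sigma1, x$sigma2, x$k1, x$k2))
  invisible(x)
}
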