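#' Parameter set of the normalized Jansen-Rit cortical-area model
#'
#' The model describes a cortical area by three interacting neural masses:
#' pyramidal cells (mass 3) with excitatory and inhibitory interneuron
#' feedback loops (masses 1 and 2, whose incoming postsynaptic potential is
#' carried by one combined state since both receive the same excitatory
#' kernel from the pyramidal cells). All quantities are dimensionless:
#' potentials are scaled by the sigmoid slope, time by the excitatory
#' dendritic time constant \code{tau}, so the normalized coupling gains are
#' \eqn{\alpha_{ba} = 2 e_0 r c_{ba} H \tau^2 / \tau_{e,i}} and the sigmoid
#' threshold-spread parameter is \eqn{\gamma = \exp(\upsilon_0 r)}.
#' \code{tau} is metadata only: it converts normalized frequency to Hz via
#' \eqn{f = \eta / \tau} at I/O boundaries and never enters the dynamics.
#'
#' Defaults are the canonical normalization of the Jansen-Rit constants:
#' \eqn{\alpha_{13} = 12.285}, \eqn{\alpha_{23} = \alpha_{13}/4},
#' \eqn{\alpha_{31} = 4\alpha_{13}/5}, \eqn{\alpha_{32} = -11\alpha_{13}/13},
#' \eqn{\beta = \tau_e/\tau_i = 0.5}, \eqn{\gamma = 28.7892}, constant
#' extrinsic inputs \eqn{x_{1T} = 0} (excitatory interneurons) and
#' \eqn{x_{3T} = 3.36} (pyramidal cells), \code{tau} = 0.010 s.
#'
#' @param alpha13,alpha23 coupling gains, pyramidal cells onto excitatory and
#'   inhibitory interneurons (both non-negative).
#' @param alpha31 coupling gain, excitatory interneurons onto pyramidal cells.
#' @param alpha32 coupling gain, inhibitory interneurons onto pyramidal cells
#'   (non-positive).
#' @param beta ratio of excitatory to inhibitory dendritic time constants.
#' @param gamma sigmoid threshold-spread parameter (> 0).
#' @param x1T,x3T constant normalized extrinsic inputs.
#' @param tau characteristic time constant in seconds (metadata only).
#' @return An object of class \code{jr_parameters}.
#' @export
jr_parameters <- function(alpha13 = 12.285,
                          alpha23 = alpha13 / 4,
                          alpha31 = 4 * alpha13 / 5,
                          alpha32 = -11 * alpha13 / 13,
                          beta = 0.5,
                          gamma = 28.7892,
                          x1T = 0,
                          x3T = 3.36,
                          tau = 0.010) {
  stopifnot(is.numeric(beta), length(beta) == 1L)
  if (beta <= 0) stop("beta must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (alpha32 > 0) stop("alpha32 is an inhibitory gain and must be <= 0")
  if (alpha13 < 0 || alpha23 < 0 || alpha31 < 0)
    stop("excitatory gains alpha13, alpha23, alpha31 must be >= 0")
  if (tau <= 0) stop("tau must be positive")
  structure(
    list(alpha13 = alpha13, alpha23 = alpha23, alpha31 = alpha31,
         alpha32 = alpha32, beta = beta, gamma = gamma,
         x1T = x1T, x3T = x3T, tau = tau),
    class = "jr_parameters")
}

#' Default normalized Jansen-Rit parameter set
#'
#' @return A \code{jr_parameters} object with the canonical values (see
#'   \code{\link{jr_parameters}}).
#' @export
default_parameters <- function() jr_parameters()

#' Periodic pulse stimulus specification
#'
#' The time-variant extrinsic input to the inhibitory interneurons is a
#' periodic train of brief pulses
#' \eqn{x_{2T}(\theta) = \zeta \exp(-2\delta \cos^2\theta)}, emulating the
#' sharpened thalamic feed-forward drive during flicker stimulation. The
#' phase advances as \eqn{d\theta/d\kappa = \pi\eta}, so the pulse train
#' repeats with normalized frequency \code{eta} (period \eqn{1/\eta} in
#' normalized time).
#'
#' @param zeta normalized stimulus amplitude (>= 0).
#' @param eta normalized stimulus frequency (>= 0, cycles per unit kappa).
#' @param delta pulse-shape parameter; larger values give narrower pulses.
#' @return An object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(zeta = 0, eta = 0.1, delta = 110) {
  if (zeta < 0) stop("zeta must be >= 0")
  if (eta < 0) stop("eta must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  structure(list(zeta = zeta, eta = eta, delta = delta),
            class = "stimulus_spec")
}

#' Sigmoid potential-to-rate transfer function
#'
#' Converts a normalized mean membrane potential to a normalized mean firing
#' rate in (0, 1): \eqn{O(x) = 1 / (1 + \gamma e^{-x})}.
#'
#' @param x normalized potential (vectorized).
#' @param gamma threshold-spread parameter (> 0).
#' @return Firing rate(s) in (0, 1).
#' @export
sigmoid_rate <- function(x, gamma = 28.7892) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  1 / (1 + gamma * exp(-x))
}

#' Stimulus pulse value at a given phase
#'
#' @param theta stimulus phase (vectorized); the pulse train is pi-periodic
#'   in theta with maxima where cos(theta) = 0.
#' @param spec a \code{\link{stimulus_spec}}.
#' @return Normalized input value(s) in \code{[zeta * exp(-2 delta), zeta]}.
#' @export
stimulus_value <- function(theta, spec) {
  spec$zeta * exp(-2 * spec$delta * cos(theta)^2)
}

#' Analytic variance of the deterministic pulse train
#'
#' Over one period the pulse train has variance
#' \eqn{\sigma^2 = \zeta^2 e^{-2\delta} (I_0(2\delta) - I_0(\delta)^2)},
#' where \eqn{I_0} is the modified Bessel function of the first kind. This is
#' the signal power used in stimulus signal-to-noise definitions.
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @return The variance (scalar, >= 0).
#' @export
stimulus_variance <- function(spec) {
  d <- spec$delta
  # expon.scaled besselI returns exp(-x) I0(x), avoiding overflow at large d
  spec$zeta^2 * (besselI(2 * d, 0, expon.scaled = TRUE) -
                   besselI(d, 0, expon.scaled = TRUE)^2)
}

# Pack parameters + stimulus into the fixed-order vector the C++ core expects.
pack_par <- function(params, spec) {
  c(params$alpha13, params$alpha23, params$alpha31, params$alpha32,
    params$beta, params$gamma, params$x1T, params$x3T,
    spec$zeta, spec$eta, spec$delta)
}

#' Right-hand side of the forced model
#'
#' The seven-dimensional augmented system: three second-order synaptic
#' equations written as first-order pairs (excitatory branches with unit
#' normalized kinetics, the inhibitory branch scaled by \code{beta}), plus
#' the stimulus phase equation. State order:
#' \code{(x03, x31, x32, y30, y31, y32, theta)}.
#'
#' @param state numeric length-7 augmented state.
#' @param params a \code{\link{jr_parameters}}.
#' @param spec a \code{\link{stimulus_spec}}.
#' @param stim_extra additive perturbation of the stimulus input (used for
#'   stimulus-noise probing).
#' @return Numeric length-7 derivative with respect to normalized time kappa.
#' @export
jr_rhs <- function(state, params, spec, stim_extra = 0) {
  if (length(state) != 7L) stop("state must have 7 components")
  if (any(!is.finite(state)))
    stop("non-finite state: integration failure signalled")
  cpp_rhs(as.numeric(state), pack_par(params, spec), stim_extra)
}

#' Unforced equilibrium of the neural subsystem
#'
#' With the stimulus off, the six neural equations have an equilibrium that
#' reduces to a scalar root problem in the combined interneuron state. The
#' equilibrium is unstable inside the intrinsic limit cycle and serves as a
#' deterministic, reproducible starting point for integrations.
#'
#' @param params a \code{\link{jr_parameters}}.
#' @return Numeric length-7 state (currents zero, theta = 0).
#' @export
jr_equilibrium <- function(params) {
  g <- params$gamma
  f <- function(x03) {
    x31 <- params$alpha31 * sigmoid_rate(params$alpha13 * x03 + params$x1T, g)
    x32 <- params$alpha32 *
      sigmoid_rate(params$alpha23 * x03 + 0, g) / params$beta^2
    sigmoid_rate(x31 + x32 + params$x3T, g) - x03
  }
  r <- stats::uniroot(f, c(-10, 10), tol = 1e-14)
  x03 <- r$root
  x31 <- params$alpha31 * sigmoid_rate(params$alpha13 * x03 + params$x1T, g)
  x32 <- params$alpha32 *
    sigmoid_rate(params$alpha23 * x03 + 0, g) / params$beta^2
  c(x03 = x03, x31 = x31, x32 = x32, y30 = 0, y31 = 0, y32 = 0, theta = 0)
}

#' Read a model/stimulus configuration file
#'
#' Flat key-value YAML (or JSON, a YAML subset) overriding any of the
#' defaults of \code{\link{jr_parameters}} and \code{\link{stimulus_spec}}.
#'
#' @param path file path.
#' @return \code{list(params = <jr_parameters>, spec = <stimulus_spec>)}.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  par_names <- c("alpha13", "alpha23", "alpha31", "alpha32", "beta", "gamma",
                 "x1T", "x3T", "tau")
  stim_names <- c("zeta", "eta", "delta")
  unknown <- setdiff(names(cfg), c(par_names, stim_names))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  params <- do.call(jr_parameters, cfg[intersect(names(cfg), par_names)])
  spec <- do.call(stimulus_spec, cfg[intersect(names(cfg), stim_names)])
  list(params = params, spec = spec)
}
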