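#' Analytic Jacobian of the neural subsystem
#'
#' 6x6 derivative matrix of the six neural equations with respect to the
#' neural states, the stimulus phase being treated as explicit time
#' dependence. Rows encoding the first-order reduction (PSP derivative =
#' current) carry constant unit couplings; the damping terms are the fixed
#' -2 (excitatory) and -2 beta (inhibitory) diagonals.
#'
#' @param state length-7 augmented state.
#' @param params a \code{\link{jr_parameters}}.
#' @param spec a \code{\link{stimulus_spec}}.
#' @return 6x6 numeric matrix.
#' @export
variational_jacobian <- function(state, params, spec) {
  if (length(state) != 7L) stop("state must have 7 components")
  cpp_jacobian(as.numeric(state), pack_par(params, spec))
}

#' Lyapunov spectrum by tangent-space QR reorthonormalization
#'
#' Integrates the forced system together with a set of tangent vectors using
#' a fixed-step classical fourth-order scheme, reorthonormalizing the tangent
#' set by modified Gram-Schmidt QR and accumulating the logarithms of the
#' diagonal growth factors. Exponents are per unit normalized time, ordered
#' descending. The stimulus phase contributes no exponent (explicit time
#' dependence), so the full spectrum has six exponents.
#'
#' Convergence is reported as the trailing-window drift: the maximum absolute
#' difference between exponents accumulated over the whole window and over
#' its second half. \code{converged} flags drift below \code{conv_tol}.
#'
#' @param params a \code{\link{jr_parameters}}.
#' @param spec a \code{\link{stimulus_spec}}.
#' @param span integration span in normalized time (after \code{discard}).
#' @param step fixed integration step.
#' @param renorm_every QR reorthonormalization interval in steps.
#' @param n_exponents number of exponents (1 to 6); 1 is cheaper for largest-
#'   exponent sweeps.
#' @param init optional initial state; default the perturbed equilibrium.
#' @param discard transient span excluded from accumulation.
#' @param conv_tol drift threshold for the convergence flag.
#' @return A \code{lyapunov_spectrum}: list with \code{exponents} (descending),
#'   \code{integration_span}, \code{drift}, \code{converged},
#'   \code{mean_trace} (time-averaged Jacobian trace along the same
#'   trajectory, for the dissipation cross-check) and \code{final_state}.
#' @export
lyapunov_spectrum <- function(params, spec, span = 3e4, step = 1e-3,
                              renorm_every = 1L, n_exponents = 6L,
                              init = NULL, discard = 500, conv_tol = 2e-3) {
  stopifnot(span > 0, step > 0, renorm_every >= 1L,
            n_exponents >= 1L, n_exponents <= 6L)
  if (is.null(init)) {
    init <- jr_equilibrium(params)
    init[1:3] <- init[1:3] + 1e-3
  }
  res <- cpp_lyapunov(as.numeric(init), pack_par(params, spec),
                      span + discard, step, as.integer(renorm_every),
                      as.integer(n_exponents), discard)
  lam <- sort(res$exponents, decreasing = TRUE)
  structure(list(exponents = lam, integration_span = span,
                 drift = res$drift, converged = res$drift < conv_tol,
                 mean_trace = res$mean_trace, final_state = res$final_state,
                 step = step, n_exponents = n_exponents,
                 forced = spec$zeta > 0),
            class = "lyapunov_spectrum")
}

#' Kaplan-Yorke dimension from an ordered Lyapunov spectrum
#'
#' \eqn{D_{KY} = k + (\sum_{i \le k} \lambda_i) / |\lambda_{k+1}|} with
#' \eqn{k} the largest index for which the partial sum is non-negative. By
#' convention the dimension is 0 when already \eqn{\lambda_1 < 0} (the
#' attractor is a fixed point).
#'
#' @param spectrum a \code{lyapunov_spectrum} or a numeric vector of
#'   exponents ordered descending.
#' @return Non-negative scalar dimension.
#' @export
kaplan_yorke <- function(spectrum) {
  lam <- if (inherits(spectrum, "lyapunov_spectrum")) {
    spectrum$exponents
  } else {
    as.numeric(spectrum)
  }
  if (is.unsorted(rev(lam))) stop("exponents must be ordered descending")
  if (lam[1] < 0) return(0)
  cs <- cumsum(lam)
  k <- max(which(cs >= 0))
  if (k >= length(lam)) return(length(lam))
  k + cs[k] / abs(lam[k + 1])
}

#' Classify the dynamic regime from a Lyapunov spectrum
#'
#' Sign-pattern classification under a zero tolerance, counting the
#' stimulus-phase direction: a periodically forced system always carries one
#' trivially zero exponent in the drive direction, which the reported fiber
#' spectrum excludes, so for forced spectra the zero count is the number of
#' near-zero fiber exponents plus one. The labels are then:
#' \code{hyperchaotic} (two or more positive exponents), \code{chaotic}
#' (exactly one positive), \code{quasi-periodic} (no positive, two zeros: a
#' two-torus), \code{periodic} (no positive, exactly one zero: a limit cycle,
#' which for a forced system means all fiber exponents negative, i.e. mode
#' locking), \code{fixed-point} (all exponents negative and no implicit
#' zero, unforced only).
#'
#' @param spectrum a \code{lyapunov_spectrum}, or a descending numeric vector
#'   (combined with \code{forced}).
#' @param zero_tol magnitude below which an exponent counts as zero.
#' @param forced whether the spectrum comes from a periodically driven
#'   configuration (ignored when \code{spectrum} carries the flag itself).
#' @return A \code{regime_label}: list with \code{label}, \code{zero_tol},
#'   and \code{warning_flag} (TRUE for an unconverged input spectrum).
#' @export
classify_regime <- function(spectrum, zero_tol = 1e-3, forced = FALSE) {
  warn <- FALSE
  if (inherits(spectrum, "lyapunov_spectrum")) {
    warn <- !isTRUE(spectrum$converged)
    forced <- isTRUE(spectrum$forced)
    lam <- spectrum$exponents
  } else {
    lam <- as.numeric(spectrum)
  }
  n_pos <- sum(lam > zero_tol)
  n_zero <- sum(abs(lam) <= zero_tol) + as.integer(forced)
  label <- if (n_pos >= 2) {
    "hyperchaotic"
  } else if (n_pos == 1) {
    "chaotic"
  } else if (n_zero >= 2) {
    "quasi-periodic"
  } else if (n_zero == 1) {
    "periodic"
  } else {
    "fixed-point"
  }
  structure(list(label = label, zero_tol = zero_tol, warning_flag = warn),
            class = "regime_label")
}

#' Direct two-trajectory estimate of the largest Lyapunov exponent
#'
#' Independent cross-check of the QR method: integrates a reference and a
#' nearby perturbed trajectory, renormalizing the separation back to the
#' initial perturbation norm at fixed intervals and averaging the logarithmic
#' growth. Intended for validation, not production sweeps.
#'
#' @param params,spec model and stimulus.
#' @param perturbation initial separation norm.
#' @param span accumulation span (normalized time).
#' @param renorm_interval separation renormalization interval.
#' @param discard transient span before accumulation starts; cells bordering
#'   chaotic windows can carry long chaotic transients, so this should be
#'   generous.
#' @param rel_tol integration tolerance.
#' @return Scalar estimate of the largest exponent (per unit kappa).
#' @export
two_trajectory_lambda1 <- function(params, spec, perturbation = 1e-6,
                                   span = 2000, renorm_interval = 2,
                                   discard = 1000, rel_tol = 1e-10) {
  init <- jr_equilibrium(params)
  init[1:3] <- init[1:3] + 1e-3
  pv <- pack_par(params, spec)
  # settle transient
  tr <- cpp_integrate(init, pv, c(0, discard), rel_tol, 1e-12, numeric(0))
  x <- tr[2, ]
  dx <- c(rep(perturbation / sqrt(3), 3), rep(0, 4))
  xp <- x + dx
  n_int <- ceiling(span / renorm_interval)
  sum_log <- 0
  for (i in seq_len(n_int)) {
    tt <- c(0, renorm_interval)
    x <- cpp_integrate(x, pv, tt, rel_tol, 1e-12, numeric(0))[2, ]
    xp <- cpp_integrate(xp, pv, tt, rel_tol, 1e-12, numeric(0))[2, ]
    sep <- xp[1:6] - x[1:6]
    d <- sqrt(sum(sep^2))
    sum_log <- sum_log + log(d / perturbation)
    xp <- x
    xp[1:6] <- x[1:6] + sep * (perturbation / d)
  }
  sum_log / (n_int * renorm_interval)
}
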