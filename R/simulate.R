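#' Integrate the forced model and resample uniformly
#'
#' Adaptive Dormand-Prince 4(5) integration over \code{kappa_total} units of
#' normalized time, linearly sampled at interval \code{dkappa} for analysis.
#' The default initial state is the unforced equilibrium perturbed by a small
#' fixed offset, giving a deterministic, reproducible transient. The analysis
#' window (used by downstream spectra/histograms) defaults to the final 20
#' percent of samples; \code{transient_frac} overrides it.
#'
#' @param params a \code{\link{jr_parameters}}.
#' @param spec a \code{\link{stimulus_spec}}.
#' @param kappa_total integration span in normalized time (>= 0).
#' @param dkappa output sampling interval.
#' @param rel_tol relative integration tolerance.
#' @param init optional length-7 initial state.
#' @param transient_frac fraction of samples treated as transient.
#' @param stim_noise optional noise generator from
#'   \code{\link{add_stimulus_noise}}; adds a piecewise-constant (one value
#'   per output interval) Gaussian perturbation to the stimulus input.
#' @return A \code{jr_trajectory}: list with \code{kappa}, \code{states}
#'   (matrix, columns \code{x03, x31, x32, y30, y31, y32, theta}),
#'   \code{dkappa}, \code{transient_cutoff} (index of the first retained
#'   sample), and the generating \code{params}/\code{spec}.
#' @export
simulate_model <- function(params, spec, kappa_total = 3e4, dkappa = 1e-2,
                           rel_tol = 1e-11, init = NULL,
                           transient_frac = 0.8, stim_noise = NULL) {
  stopifnot(kappa_total >= 0, dkappa > 0, rel_tol > 0)
  if (is.null(init)) {
    init <- jr_equilibrium(params)
    init[1:3] <- init[1:3] + 1e-3
  }
  if (length(init) != 7L) stop("init must have 7 components")
  kap <- seq(0, kappa_total, by = dkappa)
  if (length(kap) < 2L) {
    states <- matrix(numeric(0), ncol = 7,
                     dimnames = list(NULL, state_names()))
    return(structure(list(kappa = numeric(0), states = states,
                          dkappa = dkappa, transient_cutoff = 0L,
                          params = params, spec = spec),
                     class = "jr_trajectory"))
  }
  noise <- numeric(0)
  if (!is.null(stim_noise)) noise <- stim_noise$draw(length(kap) - 1L)
  states <- cpp_integrate(as.numeric(init), pack_par(params, spec), kap,
                          rel_tol, 1e-12, noise)
  colnames(states) <- state_names()
  cutoff <- as.integer(floor(transient_frac * length(kap))) + 1L
  cutoff <- min(max(cutoff, 1L), length(kap))
  structure(list(kappa = kap, states = states, dkappa = dkappa,
                 transient_cutoff = cutoff, params = params, spec = spec),
            class = "jr_trajectory")
}

state_names <- function() c("x03", "x31", "x32", "y30", "y31", "y32", "theta")

# Post-transient sample index range of a trajectory. smooth = TRUE trims the
# window from the front to the largest 5-smooth length (mixed-radix FFT cost
# degrades badly on lengths with large prime factors).
analysis_window <- function(traj, smooth = FALSE) {
  n <- length(traj$kappa)
  if (n == 0L) return(integer(0))
  w <- seq.int(traj$transient_cutoff, n)
  if (smooth && length(w) > 16L) {
    w <- w[seq.int(length(w) - fft_friendly_length(length(w)) + 1L,
                   length(w))]
  }
  w
}

# Largest integer <= n with no prime factor above 5.
fft_friendly_length <- function(n) {
  for (m in seq.int(n, 1L)) {
    k <- m
    for (f in c(2L, 3L, 5L)) while (k %% f == 0L) k <- k %/% f
    if (k == 1L) return(m)
  }
  1L
}

#' Linear M/EEG observer: summed pyramidal-cell PSP
#'
#' The measurable signal is modeled as a linear read-out of the normalized
#' postsynaptic potentials on the pyramidal cells, i.e. the sum
#' \code{x31 + x32} of the excitatory and inhibitory interneuron
#' contributions.
#'
#' @param traj a \code{jr_trajectory}, or a numeric matrix with columns
#'   \code{x31} and \code{x32}.
#' @return Numeric series, one value per sample.
#' @export
observer_pc_psp <- function(traj) {
  states <- if (inherits(traj, "jr_trajectory")) traj$states else traj
  if (nrow(states) == 0L) stop("empty trajectory")
  states[, "x31"] + states[, "x32"]
}

#' One-sided power spectrum of a uniformly sampled series
#'
#' Plain (untapered) periodogram scaled so that the sum of the spectral
#' ordinates equals the series variance (Parseval). The zero-frequency bin is
#' excluded from the dominant-peak search.
#'
#' @param series numeric series (>= 2 samples).
#' @param sample_interval sampling interval in normalized time.
#' @param taper optional taper function applied to the demeaned series (e.g.
#'   a window vector of the same length); default none.
#' @return A \code{spectrum_result}: list with \code{frequencies},
#'   \code{power}, \code{dominant_frequency}.
#' @export
power_spectrum <- function(series, sample_interval, taper = NULL) {
  n <- length(series)
  if (n < 2L) stop("need at least 2 samples")
  x <- series - mean(series)
  if (!is.null(taper)) {
    stopifnot(length(taper) == n)
    x <- x * taper
  }
  ft <- stats::fft(x)
  pow_full <- Mod(ft)^2 / n^2          # sums to var(x) * (n-1)/n ~ mean power
  nh <- floor(n / 2)
  idx <- seq_len(nh + 1L)              # 0 .. Nyquist
  pow <- pow_full[idx]
  # fold negative frequencies onto positive ones
  fold <- if (n %% 2 == 0) 2:nh else 2:(nh + 1L)
  pow[fold] <- pow[fold] + rev(pow_full)[fold - 1L]
  freq <- (idx - 1L) / (n * sample_interval)
  dom <- freq[which.max(pow[-1L]) + 1L]
  structure(list(frequencies = freq, power = pow, dominant_frequency = dom),
            class = "spectrum_result")
}

#' Characteristic mean frequency of a trajectory
#'
#' Mean rotation rate of the post-transient trajectory about the attractor
#' centroid, measured in the (x32, y32) projection plane: the time average of
#' the (unwrapped) polar-angle velocity, divided by 2 pi to give cycles per
#' unit normalized time. For a harmonic limit cycle this equals the dominant
#' spectral frequency. Degenerate (non-rotating) trajectories return zero
#' with \code{degenerate = TRUE}.
#'
#' @param traj a \code{jr_trajectory}.
#' @param plane character length-2: the two state columns spanning the
#'   projection plane.
#' @return List with \code{frequency} and \code{degenerate}.
#' @export
characteristic_mean_frequency <- function(traj, plane = c("x32", "y32")) {
  w <- analysis_window(traj)
  if (length(w) < 3L) stop("trajectory too short")
  u <- traj$states[w, plane[1]]
  v <- traj$states[w, plane[2]]
  u <- u - mean(u); v <- v - mean(v)
  r2 <- u^2 + v^2
  if (max(r2) < 1e-20)
    return(list(frequency = 0, degenerate = TRUE))
  ang <- atan2(v, u)
  dang <- diff(ang)
  dang <- dang - 2 * pi * round(dang / (2 * pi))  # unwrap increments
  total <- sum(dang)
  span <- (length(w) - 1L) * traj$dkappa
  freq <- abs(total) / (2 * pi * span)
  list(frequency = freq, degenerate = freq < .Machine$double.eps^0.5)
}

#' Per-state histograms of the post-transient trajectory
#'
#' One histogram per neural state over the analysis window, with the number
#' of bins chosen by the Freedman-Diaconis rule (an "optimal bin count"
#' stand-in; see the methods vignette). Counts sum to the number of samples.
#'
#' @param traj a \code{jr_trajectory}.
#' @return Named list of \code{hist} objects for the six neural states.
#' @export
state_histograms <- function(traj) {
  w <- analysis_window(traj)
  if (length(w) == 0L) stop("empty trajectory")
  cols <- state_names()[1:6]
  out <- lapply(cols, function(cn) {
    x <- traj$states[w, cn]
    if (diff(range(x)) < .Machine$double.eps) {
      graphics::hist(x, breaks = 1, plot = FALSE)
    } else {
      graphics::hist(x, breaks = "FD", plot = FALSE)
    }
  })
  names(out) <- cols
  out
}

#' Gaussian stimulus-noise generator at a requested SNR
#'
#' Returns a reproducible generator of additive Gaussian perturbations of the
#' stimulus input whose variance is
#' \code{stimulus_variance(spec) / 10^(snr_db/10)}, i.e. the signal-to-noise
#' ratio of the deterministic to the stochastic stimulus portion equals
#' \code{snr_db}. \code{snr_db = Inf} yields the deterministic stimulus.
#'
#' @param spec a \code{\link{stimulus_spec}} with \code{zeta > 0} (unless
#'   \code{snr_db} is infinite).
#' @param snr_db signal-to-noise ratio in dB.
#' @param seed integer seed; the stream is deterministic given the seed.
#' @return List with \code{sd} (noise standard deviation) and \code{draw(n)}
#'   (returns the next \code{n} noise values of the stream).
#' @export
add_stimulus_noise <- function(spec, snr_db, seed) {
  if (!is.finite(snr_db)) {
    return(list(sd = 0, draw = function(n) numeric(n)))
  }
  if (spec$zeta == 0)
    stop("zeta = 0 gives zero signal power; finite SNR undefined")
  sd <- sqrt(stimulus_variance(spec) / 10^(snr_db / 10))
  env <- new.env()
  env$rng <- local({
    set.seed(seed)
    .Random.seed
  })
  draw <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$rng, globalenv())
    x <- stats::rnorm(n, sd = sd)
    env$rng <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
  list(sd = sd, draw = draw)
}

#' Write / read a trajectory as columnar text
#'
#' @param traj a \code{jr_trajectory}.
#' @param path output file (TSV with a kappa column).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(kappa = traj$kappa, traj$states)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
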