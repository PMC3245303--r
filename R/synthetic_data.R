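#' Surrogate photic-driving experiment design
#'
#' Encodes the study conditions every surrogate subject is generated under:
#' 15 stimulus frequencies at ratios 0.4 to 1.6 of the subject's individual
#' alpha frequency, one occipital channel at 200 Hz for 62.5 s per condition
#' (12500 samples), individual alpha frequencies between 9.5 and 11.8 Hz, and
#' additive Gaussian measurement noise at a controllable signal-to-noise
#' ratio.
#'
#' @param n_ratios number of stimulus-to-alpha ratios.
#' @param ratio_range range of ratios.
#' @param sampling_rate recording rate in Hz.
#' @param duration analyzed duration per condition in seconds.
#' @param alpha_range admissible individual alpha frequencies in Hz.
#' @param snr_levels default SNR suite (dB) for robustness studies.
#' @param eta_int intrinsic normalized frequency of the unforced model.
#' @param rel_tol integration tolerance used when rendering records.
#' @return An \code{experiment_design}.
#' @export
experiment_design <- function(n_ratios = 15L, ratio_range = c(0.4, 1.6),
                              sampling_rate = 200, duration = 62.5,
                              alpha_range = c(9.5, 11.8),
                              snr_levels = c(Inf, 17, 13, 10, 7, 3, 0),
                              eta_int = 0.108, rel_tol = 1e-9) {
  stopifnot(n_ratios >= 2L, diff(ratio_range) > 0,
            abs(sampling_rate * duration - round(sampling_rate * duration))
            < 1e-9)
  structure(list(n_ratios = as.integer(n_ratios), ratio_range = ratio_range,
                 sampling_rate = sampling_rate, duration = duration,
                 alpha_range = alpha_range, snr_levels = snr_levels,
                 eta_int = eta_int, rel_tol = rel_tol),
            class = "experiment_design")
}

# Render the pyramidal-cell observer of one forced configuration to physical
# time: integrate in normalized time, discard the transient, and cubic-
# interpolate onto the target sampling grid (t = tau * kappa).
render_record <- function(params, zeta, eta, tau, sampling_rate, duration,
                          rel_tol, transient_kappa = 500) {
  spec <- stimulus_spec(zeta = zeta, eta = eta)
  span <- transient_kappa + duration / tau
  traj <- simulate_model(params, spec, kappa_total = span, dkappa = 1e-2,
                         rel_tol = rel_tol, transient_frac = 0)
  ser <- observer_pc_psp(traj)
  t_kappa <- traj$kappa
  n <- round(sampling_rate * duration)
  t_out <- transient_kappa + (seq_len(n) - 1L) / sampling_rate / tau
  stats::spline(t_kappa, ser, xout = t_out, method = "fmm")$y
}

#' Generate one surrogate photic-driving subject
#'
#' For each stimulus-to-alpha ratio, the forced model is simulated at
#' \code{eta = ratio * eta_int}, with the characteristic time constant chosen
#' so the intrinsic rhythm lands on the subject's alpha frequency
#' (\code{tau = eta_int / alpha_hz}); the pyramidal-cell observer is rendered
#' to physical time at the design's sampling rate and duration, and Gaussian
#' measurement noise is added at \code{snr_db} (signal power = variance of
#' the noise-free rendered series). Fully reproducible from the seed.
#'
#' @param design an \code{\link{experiment_design}}.
#' @param alpha_hz the subject's individual alpha frequency (within the
#'   design range).
#' @param zeta_true generating stimulus amplitude in [0, 4.1].
#' @param snr_db measurement SNR in dB (Inf = noise-free).
#' @param seed integer seed.
#' @param subject subject identifier.
#' @param params model parameters.
#' @return A \code{synthetic_subject}: list with \code{records} (one
#'   \code{eeg_record} per ratio), \code{clean} (noise-free series),
#'   \code{ratios}, and a provenance block of all generator settings.
#' @export
generate_subject <- function(design, alpha_hz, zeta_true, snr_db = Inf,
                             seed = 1L, subject = "S1",
                             params = default_parameters()) {
  if (alpha_hz < design$alpha_range[1] || alpha_hz > design$alpha_range[2])
    stop("alpha_hz outside the design range")
  if (zeta_true < 0 || zeta_true > 4.1)
    stop("zeta_true outside [0, 4.1]")
  ratios <- seq(design$ratio_range[1], design$ratio_range[2],
                length.out = design$n_ratios)
  tau <- design$eta_int / alpha_hz
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max, design$n_ratios)
  records <- vector("list", design$n_ratios)
  clean <- vector("list", design$n_ratios)
  for (i in seq_along(ratios)) {
    eta <- ratios[i] * design$eta_int
    ser <- render_record(params, zeta_true, eta, tau,
                         design$sampling_rate, design$duration,
                         design$rel_tol)
    clean[[i]] <- ser
    if (is.finite(snr_db)) {
      sd_n <- sqrt(stats::var(ser) / 10^(snr_db / 10))
      set.seed(rec_seeds[i])
      ser <- ser + stats::rnorm(length(ser), sd = sd_n)
    }
    records[[i]] <- eeg_record(ser, design$sampling_rate, subject = subject,
                               stimulus_ratio = ratios[i])
  }
  structure(list(records = records, clean = clean, ratios = ratios,
                 subject = subject,
                 provenance = list(alpha_hz = alpha_hz,
                                   zeta_true = zeta_true, snr_db = snr_db,
                                   seed = seed, design = design)),
            class = "synthetic_subject")
}

#' Wolf-exponent profile of a subject
#'
#' Runs the empirical largest-exponent estimator on every record of a
#' subject and returns a \code{\link{subject_data}} profile for fitting.
#'
#' @param subject a \code{synthetic_subject} (or list of \code{eeg_record}).
#' @param config an \code{\link{embedding_config}}.
#' @return A \code{subject_data}.
#' @export
subject_profile <- function(subject, config = embedding_config()) {
  recs <- subject$records
  lam <- vapply(recs, wolf_lambda1, numeric(1), config = config)
  subject_data(subject$ratios, lam, subject$subject)
}

#' Exponent-profile stability under measurement noise
#'
#' Re-estimates the Wolf exponent profile of a subject after adding Gaussian
#' measurement noise to the noise-free records at each SNR level, and
#' summarizes stability as the Pearson correlation of each noisy profile with
#' the noise-free profile, averaged over \code{n_realizations} independent
#' noise draws (a single-draw correlation of a 15-point profile is a noisy
#' statistic).
#'
#' @param subject a \code{synthetic_subject} (generated noise-free).
#' @param snr_levels SNR levels in dB.
#' @param seed base seed for the noise streams.
#' @param config an \code{\link{embedding_config}}.
#' @param n_realizations independent noise draws averaged per SNR level.
#' @return List with \code{table} (data.frame of exponents per ratio, SNR and
#'   realization) and \code{stability} (data.frame snr_db, mean correlation
#'   with the clean profile).
#' @export
robustness_suite <- function(subject, snr_levels = NULL, seed = 1L,
                             config = embedding_config(),
                             n_realizations = 3L) {
  if (is.null(snr_levels)) snr_levels <- subject$provenance$design$snr_levels
  if (length(snr_levels) == 0L) {
    return(list(table = data.frame(), stability = data.frame()))
  }
  fs <- subject$provenance$design$sampling_rate
  clean_lam <- vapply(subject$clean, function(s) {
    wolf_lambda1(eeg_record(s, fs), config = config)
  }, numeric(1))
  rows <- list()
  stab <- list()
  set.seed(seed)
  for (snr in snr_levels) {
    n_done <- if (is.finite(snr)) n_realizations else 1L  # noise-free: one
    rs <- numeric(n_done)
    for (rep in seq_len(n_done)) {
      lam <- vapply(seq_along(subject$clean), function(i) {
        s <- subject$clean[[i]]
        if (is.finite(snr)) {
          s <- s + stats::rnorm(length(s),
                                sd = sqrt(stats::var(s) / 10^(snr / 10)))
        }
        wolf_lambda1(eeg_record(s, fs), config = config)
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(ratio = subject$ratios, snr_db = snr,
                   realization = rep, lambda1 = lam)
      rs[rep] <- stats::cor(lam, clean_lam)
    }
    stab[[length(stab) + 1L]] <- data.frame(snr_db = snr, r = mean(rs))
  }
  list(table = do.call(rbind, rows), stability = do.call(rbind, stab))
}

#' Package a sweep as a model reference on the frequency-ratio axis
#'
#' @param sweep a \code{sweep_maps} from \code{\link{run_sweep}}.
#' @param eta_int intrinsic frequency used to form ratios.
#' @param bounds optional explicit normalization bounds.
#' @return A \code{\link{model_reference}}.
#' @export
make_reference <- function(sweep, eta_int = 0.108, bounds = NULL) {
  model_reference(sweep$amplitudes, sweep$frequencies / eta_int,
                  sweep$lambda1_map, bounds = bounds)
}

#' Write a surrogate subject as per-record text files plus a JSON manifest
#'
#' @param subject a \code{synthetic_subject}.
#' @param dir output directory.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(subject$records))
  for (i in seq_along(subject$records)) {
    files[i] <- file.path(dir, sprintf("%s_ratio%02d.tsv",
                                       subject$subject, i))
    write_eeg_text(subject$records[[i]], files[i])
  }
  manifest <- c(subject$provenance[c("alpha_hz", "zeta_true", "snr_db",
                                     "seed")],
                list(subject = subject$subject, ratios = subject$ratios,
                     files = basename(files),
                     design = unclass(subject$provenance$design)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
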