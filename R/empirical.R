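#' Single-channel EEG record container
#'
#' @param samples numeric series.
#' @param sampling_rate sampling rate in Hz.
#' @param subject subject identifier.
#' @param stimulus_ratio stimulus-to-alpha frequency ratio of the condition.
#' @param channel channel label (the study design records occipital O1).
#' @return An \code{eeg_record}.
#' @export
eeg_record <- function(samples, sampling_rate, subject = NA_character_,
                       stimulus_ratio = NA_real_, channel = "O1") {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate,
                 subject = subject, stimulus_ratio = stimulus_ratio,
                 channel = channel),
            class = "eeg_record")
}

#' Anti-alias filter, down-sample and validate an EEG record
#'
#' Low-pass filters at 80 percent of the target Nyquist frequency (4th-order
#' Butterworth, zero-phase via forward-backward filtering), decimates to the
#' target rate and truncates to the analysis length of
#' \code{target_rate * duration} samples (12500 at the default 200 Hz /
#' 62.5 s).
#'
#' @param raw an \code{eeg_record} with rate >= \code{target_rate}.
#' @param target_rate target sampling rate in Hz.
#' @param duration required analyzed duration in seconds.
#' @return A preprocessed \code{eeg_record}.
#' @export
preprocess <- function(raw, target_rate = 200, duration = 62.5) {
  stopifnot(inherits(raw, "eeg_record"))
  if (raw$sampling_rate < target_rate)
    stop("raw sampling rate below target rate")
  x <- raw$samples
  if (raw$sampling_rate > target_rate) {
    ratio <- raw$sampling_rate / target_rate
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("sampling-rate ratio must be an integer for decimation")
    ratio <- round(ratio)
    bf <- signal::butter(4, 0.8 / ratio, type = "low")
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1, length(x), by = ratio)]
  }
  n_req <- round(target_rate * duration)
  if (length(x) < n_req)
    stop(sprintf("record too short: %d samples after down-sampling, need %d",
                 length(x), n_req))
  eeg_record(x[seq_len(n_req)], target_rate, subject = raw$subject,
             stimulus_ratio = raw$stimulus_ratio, channel = raw$channel)
}

#' Wolf-estimator embedding configuration
#'
#' Defaults follow the photic-driving analysis settings at 200 Hz: embedding
#' dimension 16, delay 9 samples (about 50 ms) and evolution time 5 samples
#' (about 25 ms). Neighbor-distance bounds and the temporal exclusion window
#' default to data-driven values inside \code{\link{wolf_lambda1}}.
#'
#' @param dimension embedding dimension (>= 1).
#' @param delay embedding delay in samples (>= 1).
#' @param evolution fixed evolution time in samples (>= 1).
#' @param min_dist,max_dist admissible neighbor distance bounds (NULL =
#'   data-driven defaults).
#' @param exclusion temporal exclusion window in samples (NULL = one delay
#'   span).
#' @return An \code{embedding_config}.
#' @export
embedding_config <- function(dimension = 16L, delay = 9L, evolution = 5L,
                             min_dist = NULL, max_dist = NULL,
                             exclusion = NULL) {
  stopifnot(dimension >= 1L, delay >= 1L, evolution >= 1L)
  structure(list(dimension = as.integer(dimension),
                 delay = as.integer(delay),
                 evolution = as.integer(evolution),
                 min_dist = min_dist, max_dist = max_dist,
                 exclusion = exclusion),
            class = "embedding_config")
}

#' Takens delay embedding of a scalar series
#'
#' @param series numeric series.
#' @param config an \code{\link{embedding_config}} (or dimension/delay via
#'   \code{dimension}, \code{delay}).
#' @param dimension,delay used when \code{config} is NULL.
#' @return Matrix with \code{length(series) - (dimension-1)*delay} rows; row i
#'   is \code{series[i], series[i+delay], ...}.
#' @export
delay_embed <- function(series, config = NULL, dimension = 16L, delay = 9L) {
  if (!is.null(config)) {
    dimension <- config$dimension
    delay <- config$delay
  }
  n <- length(series)
  nvec <- n - (dimension - 1L) * delay
  if (nvec < 1L) stop("series too short for the requested embedding")
  idx <- outer(seq_len(nvec), (seq_len(dimension) - 1L) * delay, "+")
  matrix(series[idx], nrow = nvec, ncol = dimension)
}

#' Largest Lyapunov exponent by the Wolf fixed-evolution-time algorithm
#'
#' Tracks the separation between a fiducial trajectory in the delay embedding
#' and its nearest admissible neighbor, evolves both for a fixed number of
#' samples, accumulates the logarithmic separation growth and replaces the
#' neighbor after each evolution. Admissible neighbors lie outside a temporal
#' exclusion window and within distance bounds; the default lower bound is a
#' noise-floor estimate (median nearest-neighbor distance over a fiducial
#' subsample), the default upper bound 10 percent of the attractor extent.
#' When no neighbor satisfies the upper bound it is doubled; only total
#' exhaustion raises an error.
#'
#' @param record an \code{eeg_record} (or plain numeric series via
#'   \code{series}).
#' @param config an \code{\link{embedding_config}}.
#' @param per character: \code{"second"} converts via the record's sampling
#'   rate; \code{"sample"} returns natural log per sample.
#' @return Scalar estimate (natural-log units).
#' @export
wolf_lambda1 <- function(record, config = embedding_config(),
                         per = c("second", "sample")) {
  per <- match.arg(per)
  if (inherits(record, "eeg_record")) {
    s <- record$samples
    fs <- record$sampling_rate
  } else {
    s <- as.numeric(record)
    fs <- 1
    if (per == "second")
      stop("per-second units need an eeg_record with a sampling rate")
  }
  m <- config$dimension
  d <- config$delay
  ex <- config$exclusion
  if (is.null(ex)) ex <- d * (m - 1L)  # one delay-embedding window
  extent <- (max(s) - min(s)) * sqrt(m)
  dmax <- config$max_dist
  if (is.null(dmax)) dmax <- 0.1 * extent
  dmin <- config$min_dist
  if (is.null(dmin)) {
    # admissible neighbors must sit above the measurement-noise ball, or the
    # log growth measures noise decorrelation instead of deterministic
    # separation (and inverts the exponent-vs-frequency profile on noisy
    # records); the raw median nearest-neighbor distance estimates the noise
    # ball radius, so the lower bound is a small multiple of it, kept above
    # numerical roundoff for exactly periodic series
    dmin <- max(3 * noise_floor(s, m, d, ex), 1e-5 * extent)
  }
  res <- cpp_wolf(s, m, d, config$evolution, as.integer(ex), dmin, dmax)
  lam <- res$lambda_per_sample
  if (per == "second") lam * fs else lam
}

# Median nearest-neighbor distance over a subsample of fiducials: a cheap
# noise-floor scale for the Wolf lower distance bound.
noise_floor <- function(s, m, d, ex, n_probe = 200L) {
  emb <- delay_embed(s, dimension = m, delay = d)
  N <- nrow(emb)
  probes <- unique(round(seq(1, N, length.out = min(n_probe, N))))
  nn <- vapply(probes, function(i) {
    d2 <- rowSums((emb - matrix(emb[i, ], N, m, byrow = TRUE))^2)
    d2[max(1, i - ex):min(N, i + ex)] <- Inf
    sqrt(min(d2))
  }, numeric(1))
  stats::median(nn)
}

#' Read / write single-channel EEG as two-column text
#'
#' Plain whitespace-separated text with columns time (s) and value; the
#' sampling rate is inferred from the time column.
#'
#' @param path file path.
#' @param ... metadata passed to \code{\link{eeg_record}}.
#' @return An \code{eeg_record}.
#' @export
read_eeg_text <- function(path, ...) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("time", "value"))
  dt <- stats::median(diff(df$time))
  eeg_record(df$value, sampling_rate = 1 / dt, ...)
}

#' @rdname read_eeg_text
#' @param record an \code{eeg_record} to write.
#' @export
write_eeg_text <- function(record, path) {
  t <- (seq_along(record$samples) - 1L) / record$sampling_rate
  utils::write.table(data.frame(t, record$samples), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
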