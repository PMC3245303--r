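#' Stimulus-frequency grid with integer pulses per sampling interval
#'
#' Frequencies are chosen so that the pulse period is an exact multiple of
#' the analysis sampling interval, i.e. \eqn{1/(\eta \Delta\kappa)} is a
#' positive integer, keeping the pulses well sampled. The grid is
#' approximately uniform in eta over \code{(0, eta_max]}.
#'
#' @param n number of frequencies (>= 2).
#' @param eta_max upper end of the range.
#' @param dkappa reference sampling interval.
#' @param eta_min lower end (> 0); defaults to \code{eta_max / n}.
#' @return Sorted numeric vector of \code{n} distinct admissible frequencies.
#' @export
build_frequency_grid <- function(n, eta_max = 0.19, dkappa = 1e-2,
                                 eta_min = eta_max / n) {
  stopifnot(n >= 2L, eta_max > 0, dkappa > 0, eta_min > 0,
            eta_min < eta_max)
  m_lo <- ceiling(1 / (eta_max * dkappa))  # fewest sample points per period
  m_hi <- floor(1 / (eta_min * dkappa))
  if (m_hi - m_lo + 1 < n)
    stop("infeasible: fewer than n admissible frequencies in range")
  target <- seq(eta_min, eta_max, length.out = n)
  m <- unique(pmin(pmax(round(1 / (target * dkappa)), m_lo), m_hi))
  # rounding may collapse neighbors onto one integer period; fill the gaps
  extra <- setdiff(seq(m_lo, m_hi), m)
  if (length(m) < n) m <- c(m, extra[seq_len(n - length(m))])
  sort(1 / (m * dkappa))
}

#' Sweep the stimulus (amplitude, frequency) plane
#'
#' Computes a full Lyapunov spectrum per grid cell and derives the largest-
#' exponent map, the Kaplan-Yorke dimension map, the two-zero-exponent
#' (two-torus) indicator map and a regime-label map. Cells are independent;
#' a failure in one cell is recorded as missing, not fatal.
#'
#' @param amplitudes ordered zeta values.
#' @param frequencies ordered eta values (> 0).
#' @param params model parameters.
#' @param span,step,renorm_every,discard passed to
#'   \code{\link{lyapunov_spectrum}}.
#' @param zero_tol regime-classification zero tolerance.
#' @param progress print per-row progress.
#' @return A \code{sweep_maps}: list of matrices (rows = amplitudes, cols =
#'   frequencies) \code{lambda1_map}, \code{lambda2_map}, \code{kydim_map},
#'   \code{two_zero_map}, \code{regime_map} (character), \code{n_pos_map},
#'   plus the grid and settings.
#' @export
run_sweep <- function(amplitudes, frequencies, params = default_parameters(),
                      span = 5e3, step = 2e-3, renorm_every = 10L,
                      discard = 500, zero_tol = 1e-3, progress = FALSE) {
  na <- length(amplitudes); nf <- length(frequencies)
  dimn <- list(as.character(amplitudes), as.character(frequencies))
  l1 <- matrix(NA_real_, na, nf, dimnames = dimn)
  l2 <- l1; ky <- l1; npos <- l1
  tz <- matrix(NA, na, nf, dimnames = dimn)
  reg <- matrix(NA_character_, na, nf, dimnames = dimn)
  for (i in seq_len(na)) {
    for (j in seq_len(nf)) {
      sp <- stimulus_spec(zeta = amplitudes[i], eta = frequencies[j])
      ls <- tryCatch(
        lyapunov_spectrum(params, sp, span = span, step = step,
                          renorm_every = renorm_every, discard = discard),
        error = function(e) NULL)
      if (is.null(ls)) next
      lam <- ls$exponents
      l1[i, j] <- lam[1]
      l2[i, j] <- lam[2]
      ky[i, j] <- kaplan_yorke(lam)
      npos[i, j] <- sum(lam > zero_tol)
      n_zero <- sum(abs(lam) <= zero_tol) + as.integer(amplitudes[i] > 0)
      tz[i, j] <- n_zero >= 2 && all(lam <= zero_tol)
      reg[i, j] <- classify_regime(ls, zero_tol)$label
    }
    if (progress)
      message(sprintf("amplitude %g done (%d/%d)", amplitudes[i], i, na))
  }
  structure(list(amplitudes = amplitudes, frequencies = frequencies,
                 lambda1_map = l1, lambda2_map = l2, kydim_map = ky,
                 two_zero_map = tz, regime_map = reg, n_pos_map = npos,
                 settings = list(span = span, step = step,
                                 renorm_every = renorm_every,
                                 discard = discard, zero_tol = zero_tol)),
            class = "sweep_maps")
}

# Response frequency of the forced system at one configuration: dominant
# spectral peak (default) or characteristic mean frequency of the observer.
response_frequency <- function(zeta, eta, params = default_parameters(),
                               kappa_total = 6e3, rel_tol = 1e-9,
                               transient_frac = 0.8,
                               method = c("spectrum", "mean_frequency")) {
  method <- match.arg(method)
  sp <- stimulus_spec(zeta = zeta, eta = eta)
  traj <- simulate_model(params, sp, kappa_total = kappa_total,
                         rel_tol = rel_tol, transient_frac = transient_frac)
  w <- analysis_window(traj, smooth = TRUE)
  if (method == "spectrum") {
    ser <- observer_pc_psp(traj)[w]
    power_spectrum(ser, traj$dkappa)$dominant_frequency
  } else {
    characteristic_mean_frequency(traj)$frequency
  }
}

#' Frequency-detuning curve at fixed stimulus amplitude
#'
#' The ratio of stimulus to response frequency plotted against the ratio of
#' stimulus to intrinsic frequency; entrainment appears as plateaus where the
#' ordinate equals one.
#'
#' @param zeta stimulus amplitude.
#' @param frequencies stimulus frequencies (> 0).
#' @param eta_int intrinsic frequency of the unforced model.
#' @param params model parameters.
#' @param method response-frequency estimator: dominant spectral peak or
#'   characteristic mean frequency.
#' @param kappa_total,rel_tol per-cell integration settings.
#' @return A \code{detuning_curve}: data.frame with \code{eta},
#'   \code{eta_resp}, \code{eta_over_eta_int}, \code{eta_over_eta_resp} and
#'   attribute \code{eta_int}.
#' @export
detuning_curve <- function(zeta, frequencies, eta_int,
                           params = default_parameters(),
                           method = c("spectrum", "mean_frequency"),
                           kappa_total = 6e3, rel_tol = 1e-9) {
  stopifnot(eta_int > 0, all(frequencies > 0))
  method <- match.arg(method)
  resp <- vapply(frequencies, function(et) {
    tryCatch(response_frequency(zeta, et, params, kappa_total = kappa_total,
                                rel_tol = rel_tol, method = method),
             error = function(e) NA_real_)
  }, numeric(1))
  df <- data.frame(eta = frequencies, eta_resp = resp,
                   eta_over_eta_int = frequencies / eta_int,
                   eta_over_eta_resp = frequencies / resp)
  attr(df, "eta_int") <- eta_int
  class(df) <- c("detuning_curve", "data.frame")
  df
}

#' Mode-locked (entrainment) frequency intervals along a sweep row
#'
#' Maximal contiguous grid intervals where the largest Lyapunov exponent is
#' negative and the response frequency is locked to the stimulus frequency
#' (ratio within \code{lock_tol} of one). Interleaved chaotic islands
#' (positive exponents inside the enclosing locked span) are reported
#' separately.
#'
#' @param lambda1_row largest exponents along a frequency row.
#' @param frequencies the corresponding stimulus frequencies.
#' @param response_row response frequencies (same length); if NULL, locking is
#'   judged on the exponent sign only.
#' @param lock_tol absolute frequency tolerance for locking; a cell is locked
#'   when its largest exponent is negative and the response frequency lies
#'   within \code{lock_tol} of a rational multiple (k/q)*eta of the stimulus
#'   frequency with q <= \code{max_q} (p:q mode-locked orbits repeat with
#'   period q/eta, so their spectral peaks sit on multiples of eta/q).
#'   Default half a spectral bin of a 1200-kappa analysis window.
#' @param zero_tol exponent tolerance used for the chaotic-island report.
#' @param max_q largest locking denominator considered.
#' @return List with \code{intervals} (data.frame lower/upper) and
#'   \code{chaotic_islands} (data.frame of interior positive-exponent runs).
#' @export
entrainment_ranges <- function(lambda1_row, frequencies, response_row = NULL,
                               lock_tol = 1 / 2400, zero_tol = 5e-5,
                               max_q = 6L) {
  stopifnot(length(lambda1_row) == length(frequencies))
  # a clearly negative exponent marks a mode-locked cell on its own (deep
  # inside a tongue the locking order p:q may be high); at the tongue edge
  # the exponent approaches zero from below, so near-zero cells count as
  # locked only when the response sits on a low-order rational multiple of
  # the stimulus frequency
  locked <- lambda1_row < -zero_tol
  if (!is.null(response_row)) {
    stopifnot(length(response_row) == length(frequencies))
    rational_lock <- vapply(seq_along(frequencies), function(i) {
      r <- response_row[i]
      if (!is.finite(r)) return(FALSE)
      f0 <- frequencies[i] / seq_len(max_q)
      any(abs(r - pmax(round(r / f0), 1) * f0) < lock_tol)
    }, logical(1))
    locked <- locked |
      (abs(lambda1_row) <= zero_tol & rational_lock)
  }
  locked[is.na(locked)] <- FALSE
  chaotic <- lambda1_row > zero_tol & !locked
  chaotic[is.na(chaotic)] <- FALSE
  # an entrainment range is a maximal run of locked-or-chaotic cells that
  # starts and ends locked: interior chaotic runs are islands that interrupt
  # but do not terminate the range
  member <- locked | chaotic
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv_lo <- numeric(0); iv_hi <- numeric(0)
  is_lo <- numeric(0); is_hi <- numeric(0)
  for (b in which(r$values)) {
    idx <- starts[b]:ends[b]
    idx_locked <- idx[locked[idx]]
    if (length(idx_locked) == 0L) next
    lo <- min(idx_locked); hi <- max(idx_locked)
    iv_lo <- c(iv_lo, frequencies[lo])
    iv_hi <- c(iv_hi, frequencies[hi])
    inner <- idx[idx > lo & idx < hi]
    if (length(inner)) {
      rc <- rle(chaotic[inner])
      ec <- cumsum(rc$lengths); sc <- ec - rc$lengths + 1L
      for (bb in which(rc$values)) {
        is_lo <- c(is_lo, frequencies[inner[sc[bb]]])
        is_hi <- c(is_hi, frequencies[inner[ec[bb]]])
      }
    }
  }
  list(intervals = data.frame(lower = iv_lo, upper = iv_hi),
       chaotic_islands = data.frame(lower = is_lo, upper = is_hi))
}

#' Entrainment scan along stimulus frequency at fixed amplitude
#'
#' Computes the largest Lyapunov exponent and the spectral response frequency
#' on a frequency grid and extracts the mode-locked intervals via
#' \code{\link{entrainment_ranges}}. The exponent zero tolerance of the scan
#' (default 5e-5) is a few times the trailing-window drift of the estimator
#' at the default span, well below the converged magnitude of exponents
#' inside a locking tongue.
#'
#' @param zeta stimulus amplitude.
#' @param eta_from,eta_to,eta_step scan range and grid step.
#' @param params model parameters.
#' @param span,step Lyapunov integration settings per cell.
#' @param resp_kappa,resp_transient_frac response-frequency simulation span
#'   and transient fraction (the analysis window sets the spectral bin, and
#'   the locking tolerance is half a bin).
#' @param rel_tol trajectory integration tolerance.
#' @param zero_tol,max_q passed to \code{\link{entrainment_ranges}}.
#' @return List with \code{table} (eta, lambda1, response), \code{ranges}
#'   (from \code{\link{entrainment_ranges}}) and \code{first_upper} (upper
#'   endpoint of the lowest-frequency mode-locked interval).
#' @export
entrainment_scan <- function(zeta, eta_from, eta_to, eta_step = 0.002,
                             params = default_parameters(),
                             span = 2e4, step = 5e-3,
                             resp_kappa = 2.4e4, resp_transient_frac = 0.5,
                             rel_tol = 1e-8, zero_tol = 5e-5, max_q = 6L) {
  etas <- seq(eta_from, eta_to, by = eta_step)
  l1 <- vapply(etas, function(et) {
    lyapunov_spectrum(params, stimulus_spec(zeta, et), span = span,
                      step = step, renorm_every = 10L,
                      n_exponents = 1L)$exponents[1]
  }, numeric(1))
  resp <- vapply(etas, function(et) {
    tryCatch(response_frequency(zeta, et, params, kappa_total = resp_kappa,
                                rel_tol = rel_tol,
                                transient_frac = resp_transient_frac),
             error = function(e) NA_real_)
  }, numeric(1))
  window <- resp_kappa * (1 - resp_transient_frac)
  lock_tol <- 0.5 / (0.97 * window)  # half a spectral bin (+ trim slack)
  ranges <- entrainment_ranges(l1, etas, resp, lock_tol = lock_tol,
                               zero_tol = zero_tol, max_q = max_q)
  first_upper <- if (nrow(ranges$intervals)) {
    ranges$intervals$upper[1]
  } else {
    NA_real_
  }
  list(table = data.frame(eta = etas, lambda1 = l1, response = resp),
       ranges = ranges, first_upper = first_upper)
}

#' Poincare section of a trajectory
#'
#' Directional crossings of a hyperplane transverse to the unperturbed limit
#' cycle, located by linear interpolation between samples. By default the
#' plane fixes \code{x31} at its post-transient mean with positive-direction
#' crossings, and the \code{x32} coordinate of each crossing is recorded (the
#' bifurcation-diagram ordinate).
#'
#' @param traj a \code{jr_trajectory}.
#' @param coord state coordinate defining the plane.
#' @param level plane level; default the post-transient mean of \code{coord}.
#' @param direction +1 for upward crossings, -1 for downward.
#' @param record coordinate recorded at each crossing.
#' @return A \code{poincare_section}: list with \code{points} (recorded
#'   coordinate per crossing), \code{kappa} (interpolated crossing times),
#'   plane definition, and \code{empty} flag.
#' @export
poincare_section <- function(traj, coord = "x31", level = NULL,
                             direction = 1, record = "x32") {
  w <- analysis_window(traj)
  if (length(w) < 2L) stop("trajectory too short")
  u <- traj$states[w, coord]
  if (is.null(level)) level <- mean(u)
  g <- u - level
  s1 <- g[-length(g)]; s2 <- g[-1]
  if (direction >= 0) {
    hit <- which(s1 < 0 & s2 >= 0)
  } else {
    hit <- which(s1 > 0 & s2 <= 0)
  }
  if (length(hit) == 0L) {
    return(structure(list(points = numeric(0), kappa = numeric(0),
                          coord = coord, level = level,
                          direction = direction, record = record,
                          empty = TRUE),
                     class = "poincare_section"))
  }
  frac <- s1[hit] / (s1[hit] - s2[hit])
  v <- traj$states[w, record]
  pts <- v[hit] + frac * (v[hit + 1L] - v[hit])
  kap <- traj$kappa[w][hit] + frac * traj$dkappa
  structure(list(points = pts, kappa = kap, coord = coord, level = level,
                 direction = direction, record = record, empty = FALSE),
            class = "poincare_section")
}

#' Count distinct Poincare points (orbit period estimate)
#'
#' Clusters the recorded section coordinates with a tolerance and returns the
#' number of clusters: a period-n orbit gives n distinct points, chaos gives
#' many non-repeating ones.
#'
#' @param section a \code{poincare_section}.
#' @param tol absolute clustering tolerance.
#' @return Integer count of distinct points.
#' @export
distinct_section_points <- function(section, tol = 1e-4) {
  p <- sort(section$points)
  if (length(p) == 0L) return(0L)
  sum(c(TRUE, diff(p) > tol))
}

#' Bifurcation diagram over stimulus frequency at fixed amplitude
#'
#' For each frequency, integrates the forced system, discards transients and
#' records the Poincare-section \code{x32} values; the point pattern over
#' frequency exposes period-adding cascades, chaotic bands and tori.
#'
#' @param zeta stimulus amplitude.
#' @param frequencies stimulus frequencies.
#' @param params model parameters.
#' @param kappa_total,rel_tol per-cell integration settings.
#' @param ... passed to \code{\link{poincare_section}}.
#' @return data.frame with columns \code{eta}, \code{x32}; failures per cell
#'   are propagated as attributes.
#' @export
bifurcation_diagram <- function(zeta, frequencies,
                                params = default_parameters(),
                                kappa_total = 6e3, rel_tol = 1e-9, ...) {
  out <- vector("list", length(frequencies))
  fails <- character(0)
  for (i in seq_along(frequencies)) {
    et <- frequencies[i]
    res <- tryCatch({
      sp <- stimulus_spec(zeta = zeta, eta = et)
      traj <- simulate_model(params, sp, kappa_total = kappa_total,
                             rel_tol = rel_tol)
      sec <- poincare_section(traj, ...)
      if (sec$empty) NULL else data.frame(eta = et, x32 = sec$points)
    }, error = function(e) {
      fails <<- c(fails, sprintf("eta=%g: %s", et, conditionMessage(e)))
      NULL
    })
    out[[i]] <- res
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(eta = numeric(0), x32 = numeric(0))
  attr(df, "failures") <- fails
  df
}

#' Write sweep maps as CSV matrices with a JSON sidecar
#'
#' @param sweep a \code{sweep_maps}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_sweep <- function(sweep, dir, prefix = "sweep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("lambda1_map", "lambda2_map", "kydim_map", "two_zero_map",
               "regime_map")) {
    utils::write.csv(sweep[[nm]],
                     file.path(dir, paste0(prefix, "_", nm, ".csv")))
  }
  side <- list(amplitudes = sweep$amplitudes,
               frequencies = sweep$frequencies, settings = sweep$settings)
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_grid.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
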