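#' Model reference for the amplitude-fitting procedure
#'
#' Packages a largest-Lyapunov-exponent matrix over (amplitude, frequency
#' ratio) together with the normalization bounds used by the shift-scale
#' transformation. By default the bounds are the min/max over the
#' non-positive exponents of the matrix (chaotic cells have positive
#' exponents and are excluded from the bound definition).
#'
#' @param amplitudes ordered stimulus amplitudes.
#' @param ratios frequencies expressed as ratios to the intrinsic frequency.
#' @param lambda1 matrix (rows = amplitudes, cols = ratios) of largest
#'   exponents.
#' @param bounds optional length-2 c(lower, upper) normalization bounds.
#' @return A \code{model_reference}.
#' @export
model_reference <- function(amplitudes, ratios, lambda1, bounds = NULL) {
  stopifnot(nrow(lambda1) == length(amplitudes),
            ncol(lambda1) == length(ratios))
  if (is.null(bounds)) {
    nonpos <- lambda1[is.finite(lambda1) & lambda1 <= 0]
    if (length(nonpos) < 2L)
      stop("cannot derive normalization bounds: too few non-positive cells")
    bounds <- range(nonpos)
  }
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(amplitudes = amplitudes, ratios = ratios,
                 lambda1 = lambda1, bounds = bounds),
            class = "model_reference")
}

#' Per-subject empirical exponent profile
#'
#' @param ratios stimulus-to-alpha frequency ratios (strictly increasing).
#' @param lambda1 empirical largest-exponent estimates, one per ratio.
#' @param subject subject identifier.
#' @return A \code{subject_data}.
#' @export
subject_data <- function(ratios, lambda1, subject = NA_character_) {
  stopifnot(length(ratios) == length(lambda1),
            all(diff(ratios) > 0))
  structure(list(ratios = ratios, lambda1 = lambda1, subject = subject),
            class = "subject_data")
}

#' Shift-scale normalization of empirical exponents to the model range
#'
#' Transforms the subject's exponents by \eqn{u + v \lambda_1} so that their
#' minimum and maximum coincide exactly with the reference bounds; \eqn{v > 0}
#' preserves ordering.
#'
#' @param subject a \code{\link{subject_data}}.
#' @param ref a \code{\link{model_reference}}.
#' @param bounds optional explicit target bounds overriding \code{ref$bounds}
#'   (used for per-amplitude normalization).
#' @return List with \code{lambda_norm}, \code{u}, \code{v}.
#' @export
normalize_exponents <- function(subject, ref, bounds = NULL) {
  lam <- subject$lambda1
  rng <- range(lam)
  if (diff(rng) <= 0)
    stop("degenerate subject exponents: constant profile cannot be scaled")
  b <- if (is.null(bounds)) ref$bounds else bounds
  v <- (b[2] - b[1]) / (rng[2] - rng[1])
  u <- b[1] - v * rng[1]
  list(lambda_norm = u + v * lam, u = u, v = v)
}

#' Mean relative fit error between one model amplitude row and a subject
#'
#' The nearest-neighbor relative-error procedure: for each subject point, (i)
#' take the four nearest model frequencies, (ii) compute Euclidean distances
#' in the (frequency-ratio, normalized exponent) plane, (iii) compute each
#' neighbor's maximum possible distance by substituting the model exponent
#' bound farther from the query (lower bound when the query exponent exceeds
#' the midpoint of the bounds, upper bound otherwise), (iv) form relative
#' errors distance / maximum distance, (v) keep the minimum over the four
#' neighbors, and average these minima over the subject points.
#'
#' @param model_ratios model frequency ratios (>= 4).
#' @param model_lambda normalized model exponents along the row.
#' @param subject_ratios,subject_lambda subject points (exponents already
#'   normalized to the model bounds).
#' @param bounds the model normalization bounds c(lower, upper).
#' @return Mean relative error in [0, 1].
#' @export
fit_error <- function(model_ratios, model_lambda, subject_ratios,
                      subject_lambda, bounds) {
  if (length(model_ratios) < 4L) stop("need at least 4 model frequencies")
  stopifnot(length(model_ratios) == length(model_lambda),
            length(subject_ratios) == length(subject_lambda))
  mid <- mean(bounds)
  errs <- vapply(seq_along(subject_ratios), function(i) {
    q_r <- subject_ratios[i]
    q_l <- subject_lambda[i]
    nn <- order(abs(model_ratios - q_r))[1:4]
    d <- sqrt((model_ratios[nn] - q_r)^2 + (model_lambda[nn] - q_l)^2)
    far_bound <- if (q_l > mid) bounds[1] else bounds[2]
    dmax <- sqrt((model_ratios[nn] - q_r)^2 + (far_bound - q_l)^2)
    rel <- ifelse(dmax > 0, d / dmax, 0)
    min(rel)
  }, numeric(1))
  mean(pmin(errs, 1))
}

#' Best-fitting stimulus amplitude for a subject
#'
#' Evaluates the mean relative error for every model amplitude and returns
#' the minimizer (ties broken toward the smaller amplitude). By default the
#' subject is normalized per candidate amplitude, to the range of the
#' non-positive exponents of that amplitude's row: normalizing every
#' comparison to one global range structurally favors the rows with the
#' widest exponent span (see the methods vignette). \code{"global"} uses the
#' reference-wide bounds once.
#'
#' @param ref a \code{\link{model_reference}}.
#' @param subject a \code{\link{subject_data}}.
#' @param normalization bound policy, \code{"per_amplitude"} or
#'   \code{"global"}.
#' @return A \code{fit_result}: list with \code{best_amplitude},
#'   \code{errors} (per amplitude), \code{u}, \code{v} (shift/scale of the
#'   winning comparison), \code{lambda_norm}, \code{bounds}.
#' @export
best_amplitude <- function(ref, subject,
                           normalization = c("per_amplitude", "global")) {
  normalization <- match.arg(normalization)
  row_bounds <- function(i) {
    if (normalization == "global") return(ref$bounds)
    row <- ref$lambda1[i, ]
    np <- row[is.finite(row) & row <= 0]
    if (length(np) < 2L || diff(range(np)) == 0) ref$bounds else range(np)
  }
  fits <- lapply(seq_along(ref$amplitudes), function(i) {
    b <- row_bounds(i)
    nrm <- normalize_exponents(subject, ref, bounds = b)
    err <- fit_error(ref$ratios, ref$lambda1[i, ], subject$ratios,
                     nrm$lambda_norm, b)
    list(err = err, nrm = nrm, bounds = b)
  })
  errs <- vapply(fits, `[[`, numeric(1), "err")
  best <- which(errs == min(errs))[1]  # ties toward smaller amplitude
  structure(list(best_amplitude = ref$amplitudes[best],
                 best_index = best, errors = errs,
                 u = fits[[best]]$nrm$u, v = fits[[best]]$nrm$v,
                 lambda_norm = fits[[best]]$nrm$lambda_norm,
                 bounds = fits[[best]]$bounds,
                 subject = subject$subject),
            class = "fit_result")
}

#' Per-amplitude Pearson correlation with Bonferroni-corrected significance
#'
#' For each model amplitude, interpolates the model exponent profile onto the
#' subject's frequency ratios, computes Pearson's correlation with the
#' normalized subject exponents and a two-sided t-test, and compares against
#' the Bonferroni-corrected level \code{alpha_level / (4 * n_amplitudes)}
#' (four nearest neighbors times the amplitude count).
#'
#' @param ref a \code{\link{model_reference}}.
#' @param subject a \code{\link{subject_data}}.
#' @param alpha_level uncorrected significance level.
#' @return data.frame with \code{amplitude}, \code{r}, \code{p},
#'   \code{significant}; attribute \code{threshold} is the corrected level.
#' @export
correlation_significance <- function(ref, subject, alpha_level = 0.05) {
  if (length(subject$ratios) < 3L) stop("need at least 3 subject points")
  nrm <- normalize_exponents(subject, ref)
  thr <- alpha_level / (4 * length(ref$amplitudes))
  rows <- lapply(seq_along(ref$amplitudes), function(i) {
    mod <- stats::approx(ref$ratios, ref$lambda1[i, ],
                         xout = subject$ratios, rule = 2)$y
    if (stats::sd(mod) == 0 || stats::sd(nrm$lambda_norm) == 0) {
      return(data.frame(amplitude = ref$amplitudes[i], r = NA_real_,
                        p = NA_real_, significant = NA))
    }
    ct <- stats::cor.test(mod, nrm$lambda_norm, method = "pearson")
    data.frame(amplitude = ref$amplitudes[i], r = unname(ct$estimate),
               p = ct$p.value, significant = ct$p.value < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Bootstrap (permutation) significance of the amplitude fit
#'
#' Shuffles the subject's exponents across the frequency axis (destroying any
#' frequency dependence while preserving the distribution), refits, and
#' estimates the probability that a fit error as small as the observed one
#' arises by chance.
#'
#' @param ref a \code{\link{model_reference}}.
#' @param subject a \code{\link{subject_data}}.
#' @param n_reps number of shuffles.
#' @param seed RNG seed (reproducibility contract).
#' @return List with \code{p} (fraction of shuffled errors below the observed
#'   best error), \code{observed_error}, \code{null_errors}.
#' @export
bootstrap_test <- function(ref, subject, n_reps = 5000, seed = 1L) {
  stopifnot(n_reps >= 1)
  obs <- best_amplitude(ref, subject)
  obs_err <- min(obs$errors)
  null_err <- numeric(n_reps)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    shuf <- subject_data(subject$ratios, sample(subject$lambda1),
                         subject$subject)
    null_err[b] <- min(best_amplitude(ref, shuf)$errors)
  }
  list(p = mean(null_err < obs_err), observed_error = obs_err,
       null_errors = null_err)
}

#' Write / read a model reference as CSV plus JSON sidecar
#'
#' @param ref a \code{\link{model_reference}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_reference <- function(ref, dir, prefix = "reference") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ref$lambda1,
                   file.path(dir, paste0(prefix, "_lambda1.csv")),
                   row.names = FALSE)
  jsonlite::write_json(list(amplitudes = ref$amplitudes,
                            ratios = ref$ratios, bounds = ref$bounds),
                       file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir, prefix = "reference") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  lam <- as.matrix(utils::read.csv(
    file.path(dir, paste0(prefix, "_lambda1.csv")), check.names = FALSE))
  dimnames(lam) <- NULL
  model_reference(meta$amplitudes, meta$ratios, lam, bounds = meta$bounds)
}
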