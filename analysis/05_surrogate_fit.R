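#!/usr/bin/env Rscript
# Surrogate photic-driving experiment and model-to-data fitting: generate
# subjects driven at the study-like flash intensity (zeta = 3.6301) with
# individual alpha frequencies, estimate each record's largest Lyapunov
# exponent by the Wolf algorithm, fit the stimulus amplitude per subject by
# the shift-scale nearest-neighbor error, and assess significance by
# correlation (Bonferroni-corrected) and a permutation bootstrap. The output
# table mirrors the per-subject fit summary of a photic-driving study.
# Writes: results/fit_table.csv, results/fit_reference_*.csv/json,
#         results/robustness_stability.csv
# Runtime: ~25 min (10 subjects).

library(photicnmm)

dir.create("results", showWarnings = FALSE)
set.seed(7)

eta_int <- 0.108
zeta_true <- 3.6301
n_subjects <- 10

## Model reference: lambda1 over a desk-scale amplitude x ratio grid -------
amplitudes <- seq(0.5, 4.1, length.out = 10)
ratios <- seq(0.4, 1.6, length.out = 43)
l1 <- matrix(NA_real_, length(amplitudes), length(ratios))
for (i in seq_along(amplitudes)) {
  for (j in seq_along(ratios)) {
    l1[i, j] <- lyapunov_spectrum(
      default_parameters(),
      stimulus_spec(amplitudes[i], ratios[j] * eta_int),
      span = 1e4, step = 5e-3, renorm_every = 10L,
      n_exponents = 1L)$exponents[1]
  }
  message(sprintf("reference row %d/%d done", i, length(amplitudes)))
}
ref <- model_reference(amplitudes, ratios, l1)
write_reference(ref, "results", prefix = "fit_reference")
message(sprintf("Reference bounds (non-positive cells): [%.4g, %.4g]",
                ref$bounds[1], ref$bounds[2]))

## Subjects ---------------------------------------------------------------
des <- experiment_design()
alphas <- runif(n_subjects, des$alpha_range[1], des$alpha_range[2])
rows <- list()
for (k in seq_len(n_subjects)) {
  sub <- generate_subject(des, alphas[k], zeta_true, snr_db = 10,
                          seed = 1000 + k, subject = sprintf("S%02d", k))
  prof <- subject_profile(sub)
  fit <- best_amplitude(ref, prof)
  cs <- correlation_significance(ref, prof)
  bt <- bootstrap_test(ref, prof, n_reps = 500, seed = 2000 + k)
  rows[[k]] <- data.frame(
    subject = sub$subject, alpha_hz = alphas[k], zeta_true = zeta_true,
    zeta_fit = fit$best_amplitude,
    mean_error_pct = 100 * min(fit$errors),
    r_best = cs$r[fit$best_index],
    significant = isTRUE(cs$significant[fit$best_index]),
    bootstrap_p = bt$p)
  message(sprintf(
    "%s (alpha %.1f Hz): zeta* = %.2f, error %.0f%%, bootstrap p = %.3f",
    sub$subject, alphas[k], fit$best_amplitude, 100 * min(fit$errors), bt$p))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/fit_table.csv", row.names = FALSE)
message(sprintf("Median |zeta* - zeta_true| = %.3f (amplitude grid step %.3f)",
                median(abs(tab$zeta_fit - zeta_true)), diff(amplitudes)[1]))

## Noise robustness of the exponent profile -------------------------------
sub1 <- generate_subject(des, 10.8, zeta_true, snr_db = Inf, seed = 1)
rs <- robustness_suite(sub1, snr_levels = c(17, 13, 10, 7, 3, 0), seed = 3)
write.csv(rs$stability, "results/robustness_stability.csv", row.names = FALSE)
message("Correlation of noisy exponent profiles with the noise-free profile:")
print(rs$stability)
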