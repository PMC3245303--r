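# A small deterministic model reference used across the fitting tests: rows
# with distinct exponent-vs-ratio profiles (all non-positive, like the locked
# and weakly stable cells that define the normalization bounds).
toy_reference <- function() {
  ratios <- seq(0.4, 1.6, length.out = 13)
  amps <- c(1, 2, 3)
  lam <- rbind(-0.05 - 0.04 * sin(pi * ratios),
               -0.05 - 0.04 * cos(pi * ratios),
               -0.02 - 0.015 * ratios)
  model_reference(amps, ratios, lam)
}

test_that("reference bounds default to the non-positive exponent range", {
  ref <- toy_reference()
  expect_equal(ref$bounds, range(ref$lambda1))
  # positive (chaotic) cells are excluded from the bound definition
  lam <- ref$lambda1
  lam[1, 1] <- 0.05
  ref2 <- model_reference(ref$amplitudes, ref$ratios, lam)
  expect_equal(ref2$bounds, range(lam[lam <= 0]))
  expect_error(model_reference(1:2, 1:3, matrix(1, 2, 3)),
               "non-positive")
})

test_that("shift-scale normalization maps the subject range onto the bounds", {
  ref <- toy_reference()
  sub <- subject_data(seq(0.4, 1.6, length.out = 15),
                      c(15, 18, 13, 20, 17, 16, 19, 14, 15.5, 18.5, 17.2,
                        13.8, 16.6, 19.4, 14.9))
  nrm <- normalize_exponents(sub, ref)
  expect_equal(min(nrm$lambda_norm), ref$bounds[1])
  expect_equal(max(nrm$lambda_norm), ref$bounds[2])
  expect_gt(nrm$v, 0)
  # order preserved
  expect_equal(order(nrm$lambda_norm), order(sub$lambda1))
  # identity when the subject already spans the bounds
  sub_id <- subject_data(sub$ratios,
                         seq(ref$bounds[1], ref$bounds[2], length.out = 15))
  nrm_id <- normalize_exponents(sub_id, ref)
  expect_equal(nrm_id$u, 0, tolerance = 1e-12)
  expect_equal(nrm_id$v, 1, tolerance = 1e-12)
  # constant profiles cannot be scaled
  expect_error(normalize_exponents(subject_data(sub$ratios, rep(1, 15)), ref),
               "degenerate")
})

test_that("fit error vanishes when the subject lies on model cells", {
  ref <- toy_reference()
  idx <- seq(1, 13, by = 2)  # 7 of the model ratios
  err <- fit_error(ref$ratios, ref$lambda1[2, ], ref$ratios[idx],
                   ref$lambda1[2, idx], ref$bounds)
  expect_equal(err, 0)
})

test_that("fit error reproduces a hand-computed toy case", {
  # 4 model frequencies, one query point; worked through by hand
  mr <- c(0.8, 0.9, 1.1, 1.2)
  ml <- c(-0.08, -0.02, -0.06, -0.04)
  bounds <- c(-0.10, -0.01)
  q_r <- 1.0
  q_l <- -0.03  # above the midpoint -0.055 -> far bound is the lower one
  d <- sqrt((mr - q_r)^2 + (ml - q_l)^2)
  dmax <- sqrt((mr - q_r)^2 + (bounds[1] - q_l)^2)
  by_hand <- min(d / dmax)
  expect_equal(fit_error(mr, ml, q_r, q_l, bounds), by_hand)
  # below the midpoint the upper bound defines the maximum distance
  q_l2 <- -0.09
  d2 <- sqrt((mr - q_r)^2 + (ml - q_l2)^2)
  dmax2 <- sqrt((mr - q_r)^2 + (bounds[2] - q_l2)^2)
  expect_equal(fit_error(mr, ml, q_r, q_l2, bounds), min(d2 / dmax2))
  expect_error(fit_error(mr[1:3], ml[1:3], q_r, q_l, bounds), "at least 4")
})

test_that("the printed bound midpoint arithmetic is reproduced", {
  bounds <- c(-9.6972e-2, -9.4435e-5)
  expect_equal(mean(bounds), -4.8533e-2, tolerance = 1e-4)
})

test_that("fit errors always lie in the unit interval", {
  ref <- toy_reference()
  set.seed(7)
  for (i in 1:25) {
    sub <- subject_data(sort(runif(15, 0.4, 1.6)), rnorm(15, 10, 4))
    fit <- best_amplitude(ref, sub)
    expect_true(all(fit$errors >= 0 & fit$errors <= 1))
  }
})

test_that("best amplitude selects the error minimum with low-zeta ties", {
  ref <- toy_reference()
  # subject equal to row 2 at the model ratios: row 2 must win with zero error
  sub <- subject_data(ref$ratios, ref$lambda1[2, ] * 3 + 5)  # affine copy
  fit <- best_amplitude(ref, sub)
  expect_equal(fit$best_amplitude, 2)
  expect_equal(min(fit$errors), 0, tolerance = 1e-10)
  # single amplitude: returned directly
  ref1 <- model_reference(2, ref$ratios, ref$lambda1[2, , drop = FALSE])
  expect_equal(best_amplitude(ref1, sub)$best_amplitude, 2)
  # exact tie broken toward the smaller amplitude
  refT <- model_reference(c(1, 2), ref$ratios,
                          rbind(ref$lambda1[2, ], ref$lambda1[2, ]))
  expect_equal(best_amplitude(refT, sub)$best_amplitude, 1)
})

test_that("correlation significance applies the Bonferroni correction", {
  ref <- toy_reference()
  # collinear subject: r = 1 against its generating row
  sub <- subject_data(ref$ratios, 2 * ref$lambda1[3, ] + 1)
  cs <- correlation_significance(ref, sub)
  expect_equal(cs$r[cs$amplitude == 3], 1, tolerance = 1e-9)
  expect_equal(attr(cs, "threshold"), 0.05 / (4 * 3))
  # the study's amplitude count forces 0.05/424
  ref106 <- model_reference(seq(0, 4.1, length.out = 106), ref$ratios,
                            matrix(rep(ref$lambda1[1, ], 106), 106,
                                   byrow = TRUE))
  cs106 <- correlation_significance(ref106, sub)
  expect_equal(attr(cs106, "threshold"), 0.05 / 424)
  expect_error(correlation_significance(
    ref, subject_data(c(1, 1.2), c(1, 2))), "at least 3")
})

test_that("independent profiles are rarely significant at corrected level", {
  ref <- toy_reference()
  set.seed(31)
  n_sig <- 0
  for (i in 1:100) {
    sub <- subject_data(seq(0.4, 1.6, length.out = 15), rnorm(15))
    cs <- correlation_significance(ref, sub)
    if (any(cs$significant, na.rm = TRUE)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 5)
})

test_that("bootstrap p has resolution 1/n_reps and seed reproducibility", {
  ref <- toy_reference()
  sub <- subject_data(seq(0.4, 1.6, length.out = 15),
                      2 * approx(ref$ratios, ref$lambda1[1, ],
                                 seq(0.4, 1.6, length.out = 15),
                                 rule = 2)$y + 3)
  bt <- bootstrap_test(ref, sub, n_reps = 40, seed = 5)
  expect_true(abs(bt$p * 40 - round(bt$p * 40)) < 1e-9)
  bt2 <- bootstrap_test(ref, sub, n_reps = 40, seed = 5)
  expect_identical(bt$null_errors, bt2$null_errors)
  # a frequency-matched profile beats almost all shuffles
  expect_lt(bt$p, 0.2)
})

test_that("bootstrap p is roughly uniform for already-shuffled subjects", {
  ref <- toy_reference()
  base <- 2 * approx(ref$ratios, ref$lambda1[1, ],
                     seq(0.4, 1.6, length.out = 15), rule = 2)$y + 3
  set.seed(77)
  ps <- replicate(20, {
    sub <- subject_data(seq(0.4, 1.6, length.out = 15), sample(base))
    bootstrap_test(ref, sub, n_reps = 60,
                   seed = sample.int(1e6, 1))$p
  })
  # null p-values should spread over the unit interval
  expect_gt(mean(ps), 0.15)
  expect_lt(mean(ps), 0.85)
  expect_gt(stats::sd(ps), 0.1)
})

test_that("model references round-trip through CSV + JSON", {
  ref <- toy_reference()
  d <- tempfile()
  write_reference(ref, d)
  got <- read_reference(d)
  expect_equal(got$amplitudes, ref$amplitudes)
  expect_equal(got$ratios, ref$ratios)
  expect_equal(got$lambda1, ref$lambda1, tolerance = 1e-12)
  expect_equal(got$bounds, ref$bounds)
})
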