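test_that("zero-length integration yields an empty trajectory", {
  traj <- simulate_model(default_parameters(), default_spec_off(),
                         kappa_total = 0)
  expect_s3_class(traj, "jr_trajectory")
  expect_equal(nrow(traj$states), 0L)
  expect_equal(length(traj$kappa), 0L)
})

test_that("the unforced model settles on a bounded self-sustained cycle", {
  traj <- unforced_traj()
  ser <- observer_pc_psp(traj)
  w <- photicnmm:::analysis_window(traj)
  post <- ser[w]
  # bounded and non-decaying: oscillation amplitude persists to the end
  expect_true(all(is.finite(post)))
  first_half <- post[seq_len(length(post) %/% 2)]
  second_half <- post[-seq_len(length(post) %/% 2)]
  expect_gt(diff(range(second_half)), 0.9 * diff(range(first_half)))
  expect_gt(diff(range(second_half)), 0.5)
})

test_that("observer is the linear pyramidal-cell PSP read-out", {
  a <- matrix(rnorm(21), 3, 7,
              dimnames = list(NULL, photicnmm:::state_names()))
  b <- matrix(rnorm(21), 3, 7,
              dimnames = list(NULL, photicnmm:::state_names()))
  expect_equal(observer_pc_psp(a + b),
               observer_pc_psp(a) + observer_pc_psp(b))
  const <- matrix(rep(c(1, 2, 3, 0, 0, 0, 0), each = 4), 4, 7,
                  dimnames = list(NULL, photicnmm:::state_names()))
  expect_equal(observer_pc_psp(const), rep(5, 4))
  expect_error(observer_pc_psp(a[0, , drop = FALSE]), "empty")
})

test_that("power spectrum finds pure tones and conserves power", {
  dk <- 0.01
  n <- 6000
  kap <- (seq_len(n) - 1) * dk
  eta0 <- 0.12
  ser <- sin(2 * pi * eta0 * kap)
  ps <- power_spectrum(ser, dk)
  expect_lt(abs(ps$dominant_frequency - eta0), 1 / (n * dk))
  # Parseval: sum of one-sided spectral ordinates equals the mean power
  x <- ser - mean(ser)
  expect_lt(abs(sum(ps$power) - mean(x^2)) / mean(x^2), 1e-6)
  expect_true(all(ps$power >= 0))
  expect_true(ps$dominant_frequency %in% ps$frequencies)
  expect_error(power_spectrum(1, dk), "2 samples")
})

test_that("unforced rhythm sits at the intrinsic frequency near 0.108", {
  traj <- unforced_traj()
  w <- photicnmm:::analysis_window(traj, smooth = TRUE)
  ps <- power_spectrum(observer_pc_psp(traj)[w], traj$dkappa)
  bin <- 1 / (length(w) * traj$dkappa)
  expect_lt(abs(ps$dominant_frequency - 0.108), bin)
})

test_that("white noise yields an approximately flat spectrum", {
  set.seed(11)
  ser <- rnorm(20000)
  ps <- power_spectrum(ser, 0.01)
  pow <- ps$power[-1]
  # mean power in the lower half-band vs the upper half-band
  h <- length(pow) %/% 2
  ratio <- mean(pow[seq_len(h)]) / mean(pow[-seq_len(h)])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("characteristic mean frequency recovers a planar rotation rate", {
  omega <- 0.5
  # ten full turns, so the trajectory centroid coincides with the center
  traj <- circular_traj(omega = omega, n = round(40 * pi / 0.01) + 1)
  got <- characteristic_mean_frequency(traj)
  expect_false(got$degenerate)
  expect_lt(abs(got$frequency - omega / (2 * pi)) / (omega / (2 * pi)), 1e-3)
  # constant trajectory degenerates to zero with a flag
  const <- circular_traj(omega = 0)
  const$states[, c("x32", "y32")] <- 1
  got0 <- characteristic_mean_frequency(const)
  expect_true(got0$degenerate)
  expect_equal(got0$frequency, 0)
})

test_that("mean frequency and spectral peak agree on the unforced cycle", {
  traj <- unforced_traj()
  w <- photicnmm:::analysis_window(traj, smooth = TRUE)
  dom <- power_spectrum(observer_pc_psp(traj)[w], traj$dkappa)$dominant_frequency
  cmf <- characteristic_mean_frequency(traj)$frequency
  expect_lt(abs(cmf - dom) / dom, 0.02)
})

test_that("state histograms conserve sample counts", {
  traj <- unforced_traj()
  hh <- state_histograms(traj)
  n <- length(photicnmm:::analysis_window(traj))
  expect_named(hh, c("x03", "x31", "x32", "y30", "y31", "y32"))
  for (h in hh) expect_equal(sum(h$counts), n)
  # constant series occupy a single bin
  ctraj <- circular_traj(omega = 0)
  ctraj$states[, 1:6] <- 0.7
  hc <- state_histograms(ctraj)
  for (h in hc) expect_equal(sum(h$counts > 0), 1L)
})

test_that("uniform series give an approximately flat histogram", {
  traj <- circular_traj(n = 20000)
  set.seed(5)
  traj$states[, 1:6] <- runif(20000 * 6)
  hh <- state_histograms(traj)
  h <- hh$x03
  inner <- h$counts[-c(1, length(h$counts))]  # edge bins may be partial
  expect_lt(stats::sd(inner) / mean(inner), 0.2)
})

test_that("stimulus noise generator honors SNR and seed contracts", {
  sp <- stimulus_spec(zeta = 3.6301, eta = 0.1)
  gen_inf <- add_stimulus_noise(sp, Inf, seed = 1)
  expect_equal(gen_inf$sd, 0)
  expect_equal(gen_inf$draw(10), rep(0, 10))

  gen <- add_stimulus_noise(sp, 10, seed = 123)
  x <- gen$draw(2e5)
  realized_snr <- 10 * log10(stimulus_variance(sp) / stats::var(x))
  expect_lt(abs(realized_snr - 10), 0.2)

  gen_a <- add_stimulus_noise(sp, 10, seed = 99)
  gen_b <- add_stimulus_noise(sp, 10, seed = 99)
  expect_identical(gen_a$draw(1000), gen_b$draw(1000))
  # successive draws continue one stream
  gen_c <- add_stimulus_noise(sp, 10, seed = 99)
  gen_d <- add_stimulus_noise(sp, 10, seed = 99)
  expect_identical(c(gen_c$draw(400), gen_c$draw(600)), gen_d$draw(1000))

  expect_error(add_stimulus_noise(stimulus_spec(zeta = 0), 10, seed = 1),
               "zero signal power")
})

test_that("stimulus noise perturbs the forced simulation reproducibly", {
  p <- default_parameters()
  sp <- stimulus_spec(zeta = 2.4, eta = 0.12)
  t0 <- simulate_model(p, sp, kappa_total = 100, rel_tol = 1e-8)
  t1 <- simulate_model(p, sp, kappa_total = 100, rel_tol = 1e-8,
                       stim_noise = add_stimulus_noise(sp, 10, seed = 4))
  t2 <- simulate_model(p, sp, kappa_total = 100, rel_tol = 1e-8,
                       stim_noise = add_stimulus_noise(sp, 10, seed = 4))
  expect_false(identical(t0$states, t1$states))
  expect_identical(t1$states, t2$states)
  # the noise-free limit reproduces the deterministic run
  t3 <- simulate_model(p, sp, kappa_total = 100, rel_tol = 1e-8,
                       stim_noise = add_stimulus_noise(sp, Inf, seed = 4))
  expect_equal(t3$states, t0$states, tolerance = 1e-12)
})

test_that("identical configurations reproduce trajectories exactly", {
  p <- default_parameters()
  sp <- stimulus_spec(zeta = 1.5, eta = 0.0759)
  t1 <- simulate_model(p, sp, kappa_total = 200, rel_tol = 1e-9)
  t2 <- simulate_model(p, sp, kappa_total = 200, rel_tol = 1e-9)
  expect_identical(t1$states, t2$states)
})

test_that("trajectories round-trip through columnar text", {
  traj <- simulate_model(default_parameters(), default_spec_off(),
                         kappa_total = 10)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  got <- utils::read.table(f, header = TRUE)
  expect_equal(nrow(got), length(traj$kappa))
  expect_equal(got$x31, unname(traj$states[, "x31"]), tolerance = 1e-12)
})
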