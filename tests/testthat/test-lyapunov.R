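test_that("analytic Jacobian matches finite differences at random states", {
  p <- default_parameters()
  sp <- stimulus_spec(zeta = 3.6301, eta = 0.0933)
  set.seed(42)
  h <- 1e-6
  for (rep in 1:100) {
    st <- c(rnorm(6, sd = 2), runif(1, 0, 2 * pi))
    J <- variational_jacobian(st, p, sp)
    Jfd <- matrix(0, 6, 6)
    for (j in 1:6) {
      stp <- st; stm <- st
      stp[j] <- stp[j] + h
      stm[j] <- stm[j] - h
      Jfd[, j] <- (jr_rhs(stp, p, sp)[1:6] - jr_rhs(stm, p, sp)[1:6]) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("Jacobian has the fixed first-order-reduction structure", {
  p <- default_parameters()
  sp <- stimulus_spec(zeta = 1, eta = 0.1)
  J <- variational_jacobian(c(0.3, 1, -2, 0.1, 0, 0, 2), p, sp)
  expect_equal(J[1:3, 4:6], diag(3))
  expect_equal(J[1:3, 1:3], matrix(0, 3, 3))
  # constant damping diagonals: -2 on the excitatory currents, -2 beta on the
  # inhibitory one, so the trace is state-independent
  expect_equal(diag(J), c(0, 0, 0, -2, -2, -2 * p$beta))
  expect_equal(sum(diag(J)), -4 - 2 * p$beta)
})

test_that("the unforced cycle has one near-zero exponent, rest negative", {
  ls <- lyap_unforced_fix()
  expect_lt(abs(ls$exponents[1]), 1e-3)
  expect_true(all(ls$exponents[2:6] < -1e-3))
  expect_equal(classify_regime(ls)$label, "periodic")
})

test_that("exponent sum equals the time-averaged divergence", {
  ls <- lyap_unforced_fix()
  expect_lt(abs(sum(ls$exponents) - ls$mean_trace) / abs(ls$mean_trace), 0.01)
  ls2 <- lyap_chaotic_fix()
  expect_lt(abs(sum(ls2$exponents) - ls2$mean_trace) / abs(ls2$mean_trace),
            0.01)
})

test_that("the printed chaotic configuration has a positive exponent", {
  ls <- lyap_chaotic_fix()
  expect_gt(ls$exponents[1], 1e-3)
  expect_equal(classify_regime(ls)$label, "chaotic")
  # dissipative: exponent sum negative
  expect_lt(sum(ls$exponents), 0)
})

test_that("Kaplan-Yorke dimension follows the partial-sum formula", {
  expect_equal(kaplan_yorke(c(0.05, 0, -0.5, -1, -1, -1)), 2.1)
  expect_equal(kaplan_yorke(c(0, -0.1, -1, -1, -1, -1)), 1)
  expect_equal(kaplan_yorke(c(-0.01, -0.1, -1, -1, -1, -1)), 0)
  expect_equal(kaplan_yorke(c(0.2, 0.1, -0.1)), 3)  # sum never negative
  expect_error(kaplan_yorke(c(-1, 0, 1)), "descending")
})

test_that("regime labels follow the exponent sign pattern", {
  expect_equal(classify_regime(c(0.1, 0, -1, -1, -1, -1),
                               zero_tol = 1e-3)$label, "chaotic")
  expect_equal(classify_regime(c(0.1, 0.05, -1, -1, -1, -1))$label,
               "hyperchaotic")
  expect_equal(classify_regime(c(0, -0.5, -1, -1, -1, -1))$label, "periodic")
  expect_equal(classify_regime(c(0, 0, -1, -1, -1, -1))$label,
               "quasi-periodic")
  expect_equal(classify_regime(c(-0.2, -0.5, -1, -1, -1, -1))$label,
               "fixed-point")
  # forced systems carry the implicit drive-direction zero
  expect_equal(classify_regime(c(-0.2, -0.5, -1, -1, -1, -1),
                               forced = TRUE)$label, "periodic")
  expect_equal(classify_regime(c(0, -0.5, -1, -1, -1, -1),
                               forced = TRUE)$label, "quasi-periodic")
  # unconverged spectra carry a warning flag
  ls <- lyap_unforced_fix()
  ls$converged <- FALSE
  expect_true(classify_regime(ls)$warning_flag)
})

test_that("printed regime examples classify as in the frequency charts", {
  for (cfg in list(list(z = 3.6301, e = 0.0933, lab = "periodic"),
                   list(z = 1.5, e = 0.0759, lab = "quasi-periodic"),
                   list(z = 3.6301, e = 0.18, lab = "quasi-periodic"),
                   list(z = 3.6301, e = 0.03, lab = "periodic"))) {
    ls <- lyapunov_spectrum(default_parameters(),
                            stimulus_spec(cfg$z, cfg$e),
                            span = 5e3, step = 2e-3, renorm_every = 10L)
    expect_equal(classify_regime(ls)$label, cfg$lab,
                 label = sprintf("(%g, %g)", cfg$z, cfg$e))
  }
})

test_that("two-trajectory divergence agrees in sign with the QR method", {
  p <- default_parameters()
  cells <- list(c(3.6301, 0.0705),  # chaotic
                c(3.6301, 0.03),    # locked
                c(2.4, 0.12))       # locked
  for (cf in cells) {
    sp <- stimulus_spec(cf[1], cf[2])
    qr1 <- lyapunov_spectrum(p, sp, span = 4e3, step = 5e-3,
                             renorm_every = 10L,
                             n_exponents = 1L)$exponents[1]
    tt <- two_trajectory_lambda1(p, sp, span = 800, renorm_interval = 2,
                                 rel_tol = 1e-10)
    expect_equal(sign(qr1), sign(tt),
                 label = sprintf("(%g, %g): qr=%g two-traj=%g",
                                 cf[1], cf[2], qr1, tt))
  }
})
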