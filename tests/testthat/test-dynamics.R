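test_that("frequency grids satisfy the integer-period constraint", {
  fr <- build_frequency_grid(69, eta_max = 0.19, dkappa = 1e-2)
  expect_length(fr, 69)
  expect_true(all(fr > 0 & fr <= 0.19))
  periods <- 1 / (fr * 1e-2)
  expect_equal(periods, round(periods), tolerance = 1e-9)
  expect_true(all(diff(fr) > 0))

  fr2 <- build_frequency_grid(2, eta_max = 0.19, dkappa = 1e-2)
  expect_length(fr2, 2)
  p2 <- 1 / (fr2 * 1e-2)
  expect_lt(max(abs(p2 - round(p2))), 1e-6)
  expect_error(build_frequency_grid(5, eta_max = 0.19, dkappa = 1e-2,
                                    eta_min = 0.1895), "infeasible")
})

test_that("sweeps populate regime maps with the expected structure", {
  sw <- fixture("small_sweep", {
    run_sweep(amplitudes = c(0, 2.4, 3.6301),
              frequencies = c(0.03, 0.0705, 0.12, 0.18),
              span = 4e3, step = 5e-3, renorm_every = 10L)
  })
  expect_equal(dim(sw$lambda1_map), c(3L, 4L))
  # the unforced row has a near-zero largest exponent regardless of eta
  expect_true(all(abs(sw$lambda1_map[1, ]) < 1e-3))
  # dimensions non-negative and low
  expect_true(all(sw$kydim_map >= 0))
  expect_true(all(sw$kydim_map < 2))
  # at most one positive exponent per configuration
  expect_true(all(sw$n_pos_map <= 1))
  # two-torus indicator at the printed quasi-periodic cell
  expect_true(sw$two_zero_map["3.6301", "0.18"])
  expect_false(sw$two_zero_map["3.6301", "0.0705"])
  expect_equal(sw$regime_map["3.6301", "0.0705"], "chaotic")
})

test_that("sweep maps round-trip through the CSV + JSON sidecar", {
  sw <- fixture("small_sweep", stop("run sweep test first"))
  d <- tempfile()
  write_sweep(sw, d)
  side <- jsonlite::read_json(file.path(d, "sweep_grid.json"),
                              simplifyVector = TRUE)
  expect_equal(side$amplitudes, sw$amplitudes)
  expect_equal(side$frequencies, sw$frequencies)
  m <- utils::read.csv(file.path(d, "sweep_lambda1_map.csv"),
                       row.names = 1, check.names = FALSE)
  expect_equal(unname(as.matrix(m)), unname(sw$lambda1_map),
               tolerance = 1e-12)
})

test_that("detuning is flat at one when stimulating at the intrinsic rhythm", {
  dc <- detuning_curve(zeta = 2.4, frequencies = c(0.108, 0.12),
                       eta_int = 0.108, kappa_total = 4e3, rel_tol = 1e-8)
  expect_equal(nrow(dc), 2L)
  # inside the 1:1 entrainment range the response equals the stimulus
  expect_lt(abs(dc$eta_over_eta_resp[1] - 1), 0.01)
  expect_lt(abs(dc$eta_over_eta_resp[2] - 1), 0.01)
  expect_equal(dc$eta_over_eta_int[1], 1)
})

test_that("entrainment intervals merge interior chaotic islands", {
  freqs <- seq(0.01, 0.10, by = 0.01)
  l1 <- c(-0.02, -0.02, 0.03, -0.02, -0.01, 1e-6, 0.02, 0.02, 0.02, 0.02)
  er <- entrainment_ranges(l1, freqs)
  # island at 0.03 sits inside the locked run; trailing chaos is not merged
  expect_equal(er$intervals$lower, 0.01)
  expect_equal(er$intervals$upper, 0.05)
  expect_equal(er$chaotic_islands$lower, 0.03)
  # all-positive rows yield no interval
  er2 <- entrainment_ranges(rep(0.1, 5), freqs[1:5])
  expect_equal(nrow(er2$intervals), 0L)
  # near-zero cells extend a run only when the response is rationally locked
  l1b <- c(-0.02, -0.02, 1e-6, 1e-6)
  resp <- c(0.02, 0.04, 0.06, 0.0513)
  er3 <- entrainment_ranges(l1b, freqs[1:4], resp, lock_tol = 1e-3)
  expect_equal(er3$intervals$upper, 0.03)
})

test_that("Poincare sections count orbit periodicity", {
  p <- default_parameters()
  # 1:1 locked orbit: one distinct section point per crossing direction
  traj <- simulate_model(p, stimulus_spec(2.4, 0.12), kappa_total = 4e3,
                         rel_tol = 1e-8)
  sec <- poincare_section(traj)
  expect_false(sec$empty)
  expect_equal(distinct_section_points(sec, tol = 1e-3), 1L)
  # all recorded crossings lie on the plane (interpolated coordinate check)
  expect_true(all(abs(diff(sec$kappa) - mean(diff(sec$kappa))) < 0.5))

  # chaotic configuration: many non-repeating points
  trajc <- simulate_model(p, stimulus_spec(3.6301, 0.0705), kappa_total = 6e3,
                          rel_tol = 1e-8)
  secc <- poincare_section(trajc)
  expect_gt(distinct_section_points(secc, tol = 1e-3), 10L)

  # no crossings: flagged empty section
  flat <- circular_traj(omega = 0)
  flat$states[, "x31"] <- 1
  sec0 <- poincare_section(flat, coord = "x31", level = 5)
  expect_true(sec0$empty)
})

test_that("bifurcation diagrams expose the period-adding cascade", {
  # descending stimulus frequency in the low periodic branch: section point
  # count increases stepwise
  bd <- fixture("bifurcation_low", {
    bifurcation_diagram(3.6301, c(0.02, 0.04), kappa_total = 5e3,
                        rel_tol = 1e-8)
  })
  counts <- vapply(split(bd$x32, bd$eta), function(v) {
    distinct_section_points(list(points = v), tol = 1e-3)
  }, integer(1))
  expect_gt(counts[["0.02"]], counts[["0.04"]])
  expect_gte(counts[["0.04"]], 1L)
  # empty frequency list gives an empty diagram
  bd0 <- bifurcation_diagram(3.6301, numeric(0))
  expect_equal(nrow(bd0), 0L)
})
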