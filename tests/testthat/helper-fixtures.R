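# Shared fixtures, computed lazily and cached for the whole test session.
fixture_env <- new.env()

fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

default_spec_off <- function() stimulus_spec(zeta = 0, eta = 0.1)

# Unforced trajectory used by several spectral / histogram tests.
unforced_traj <- function() {
  fixture("unforced_traj", {
    simulate_model(default_parameters(), default_spec_off(),
                   kappa_total = 3e3, rel_tol = 1e-9)
  })
}

lyap_unforced_fix <- function() {
  fixture("lyap_unforced", {
    lyapunov_spectrum(default_parameters(), stimulus_spec(zeta = 0, eta = 0.1),
                      span = 5e3, step = 2e-3, renorm_every = 10L)
  })
}

lyap_chaotic_fix <- function() {
  fixture("lyap_chaotic", {
    lyapunov_spectrum(default_parameters(),
                      stimulus_spec(zeta = 3.6301, eta = 0.0705),
                      span = 5e3, step = 2e-3, renorm_every = 10L)
  })
}

# A small synthetic circular orbit in the (x32, y32) plane, angular velocity
# omega, for characteristic-mean-frequency oracles.
circular_traj <- function(omega = 0.5, n = 2000, dk = 0.01) {
  kap <- (seq_len(n) - 1) * dk
  states <- matrix(0, n, 7, dimnames = list(NULL, photicnmm:::state_names()))
  states[, "x32"] <- cos(omega * kap)
  states[, "y32"] <- sin(omega * kap)
  structure(list(kappa = kap, states = states, dkappa = dk,
                 transient_cutoff = 1L,
                 params = default_parameters(),
                 spec = default_spec_off()),
            class = "jr_trajectory")
}

# One surrogate subject at the design defaults (10 dB measurement noise).
synthetic_subject_fix <- function() {
  fixture("synthetic_subject", {
    generate_subject(experiment_design(), alpha_hz = 10.8, zeta_true = 2.4,
                     snr_db = 10, seed = 101)
  })
}

# Desk-scale model reference for the amplitude-fitting checks: largest
# exponents over 10 amplitudes x 43 frequency ratios (a 3x refinement of the
# 15 subject ratios, which it contains as grid cells). Deterministic.
acceptance_reference <- function() {
  fixture("acceptance_reference", {
    eta_int <- 0.108
    ratios <- seq(0.4, 1.6, length.out = 43)
    amps <- seq(0.5, 4.1, length.out = 10)
    l1 <- matrix(NA_real_, length(amps), length(ratios))
    for (i in seq_along(amps)) {
      for (j in seq_along(ratios)) {
        l1[i, j] <- lyapunov_spectrum(
          default_parameters(),
          stimulus_spec(amps[i], ratios[j] * eta_int),
          span = 1e4, step = 5e-3, renorm_every = 10L,
          n_exponents = 1L)$exponents[1]
      }
    }
    model_reference(amps, ratios, l1)
  })
}

# Noise-free surrogate at the study's best-fit flash intensity, for the
# noise-robustness suite (its profile has strong chaotic/locked contrast).
study_subject_fix <- function() {
  fixture("study_subject", {
    generate_subject(experiment_design(), alpha_hz = 10.8,
                     zeta_true = 3.6301, snr_db = 10, seed = 101,
                     subject = "S-study")
  })
}
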