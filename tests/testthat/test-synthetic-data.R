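# Generators: model knots, closed-form responses, determinism, validation.

test_that("reference isotherm model reproduces its knots and monotonicity", {
  p <- isotherm_params()
  expect_equal(isotherm_model_pressure(p, 0.77), 5.0)
  expect_equal(isotherm_model_pressure(p, 1.02), 0)
  expect_equal(isotherm_model_pressure(p, 0.55), 5.5)  # plateau end with tilt
  iso <- generate_isotherm(p, noise_sd = 0)
  expect_true(all(diff(iso$pressure) >= 0))   # compression order: pi rises
  expect_true(all(diff(iso$area) < 0))
  # continuity at the branch knots
  for (a in c(1.02, 0.77, 0.55)) {
    eps <- 1e-9
    expect_equal(isotherm_model_pressure(p, a - eps),
                 isotherm_model_pressure(p, a + eps), tolerance = 1e-6)
  }
})

test_that("LE-branch tangent at the plateau onset has the analytic slope and intercept", {
  p <- isotherm_params()
  # d pi / dA at A_C for the quadratic branch (one-sided: A_C is a knot):
  # -2 pi_C / (A_lift - A_C)
  eps <- 1e-7
  slope <- (isotherm_model_pressure(p, 0.77 + eps) -
              isotherm_model_pressure(p, 0.77)) / eps
  expect_equal(slope, -2 * 5 / (1.02 - 0.77), tolerance = 1e-5)
  # tangent crosses pi = 0 at A_C + pi_C / |slope|
  expect_equal(0.77 + 5 / abs(slope), 0.895, tolerance = 1e-5)
})

test_that("binary-film parameter tables encode the calibrated composition effects", {
  s <- binary_film_params("Fe3O4-S")
  as_ <- binary_film_params("Fe3O4-AS")
  expect_equal(s$le_shift, 0.19)
  expect_equal(s$plateau_onset_pressure, 12)
  expect_equal(s$lc_shift, -0.05)
  expect_equal(as_$le_shift, 0.14)
  expect_equal(as_$plateau_onset_pressure, 10)
  expect_equal(as_$lc_shift, 0.05)
  # scaling in X_W keeps pure DPPC at X_W = 0
  z <- binary_film_params("Fe3O4-S", X_W = 0)
  expect_equal(z$le_shift, 0)
  expect_equal(z$plateau_onset_pressure, 5)
})

test_that("isotherm generator is deterministic under a seed and validates inputs", {
  p <- isotherm_params()
  a <- generate_isotherm(p, noise_sd = 0.05, seed = 42)
  b <- generate_isotherm(p, noise_sd = 0.05, seed = 42)
  expect_identical(a, b)
  c <- generate_isotherm(p, noise_sd = 0.05, seed = 43)
  expect_false(identical(a$pressure, c$pressure))
  expect_error(isotherm_params(plateau_onset_area = 1.2), "outside the allowed range")
  expect_error(isotherm_params(collapse_pressure = 5), "outside the allowed range")
  expect_error(generate_isotherm(p, noise_sd = -1), "outside the allowed range")
  expect_error(generate_isotherm(p, n_points = 20), "outside the allowed range")
})

test_that("oscillation generator realises the closed-form viscoelastic response", {
  # purely elastic film: pi(t) = pi0 - u E' sin(2 pi f t) exactly
  p <- oscillation_params(E_prime = 60, E_dprime = 0, frequency = 0.1,
                          amplitude = 0.01, baseline_pressure = 30)
  tr <- generate_oscillation_trace(p)
  wt <- 2 * pi * 0.1 * tr$time
  expect_equal(tr$pressure, 30 - 0.6 * sin(wt), tolerance = 1e-12)
  expect_equal(tr$area, 273 * (1 + 0.01 * sin(wt)), tolerance = 1e-12)

  # null film: constant pressure
  p0 <- oscillation_params(E_prime = 0, E_dprime = 0)
  expect_equal(unique(generate_oscillation_trace(p0)$pressure), 30)

  # peak-to-peak excursion is 2 u |E|
  pv <- oscillation_params(E_prime = 60, E_dprime = 10)
  trv <- generate_oscillation_trace(pv)
  # sampled extrema miss the true peaks by O(1 - cos(pi/64)) relative
  expect_equal(diff(range(trv$pressure)), 2 * 0.01 * sqrt(60^2 + 10^2),
               tolerance = 2e-3)

  expect_error(oscillation_params(E_prime = 60, sampling_rate = 0.5,
                                  frequency = 0.1) |>
                 generate_oscillation_trace(), "under-samples")
  expect_error(oscillation_params(E_prime = -1), "outside the allowed range")
  expect_error(oscillation_params(E_prime = 10, amplitude = 0.2),
               "outside the allowed range")
})

test_that("penetration pair realises the exponential-saturation closed form", {
  pair <- generate_penetration_pair(
    penetration_params(delta_pi_max = 7.3, k_ads = 0.01, noise_sd = 0))
  dif <- pair$penetration$pressure - pair$reference$pressure
  i360 <- which(pair$penetration$time == 360)
  expect_equal(dif[i360], 7.3 * (1 - exp(-3.6)), tolerance = 1e-12)

  pair_s <- generate_penetration_pair(
    penetration_params(delta_pi_max = 4.32, k_ads = 0.01, noise_sd = 0))
  expect_equal((pair_s$penetration$pressure - pair_s$reference$pressure)[i360],
               4.2, tolerance = 0.005)

  # null injection: both traces identical
  null <- generate_penetration_pair(penetration_params(0, noise_sd = 0))
  expect_identical(null$penetration$pressure, null$reference$pressure)

  # shared drift enters both troughs equally
  drifted <- generate_penetration_pair(
    penetration_params(2, reference_drift = 0.01, noise_sd = 0))
  expect_equal(drifted$reference$pressure,
               30 + 0.01 * drifted$reference$time, tolerance = 1e-12)

  a <- generate_penetration_pair(penetration_params(2, noise_sd = 0.1, seed = 9))
  b <- generate_penetration_pair(penetration_params(2, noise_sd = 0.1, seed = 9))
  expect_identical(a, b)
})

test_that("contact-angle generator solves the inverse Owens-Wendt problem", {
  liquids <- default_probe_liquids()
  dim_row <- liquids[liquids$name == "diiodomethane", ]
  # starch on diiodomethane: closed-form Young angle
  expected <- acos((2 * sqrt(28.8 * 50.8) - 50.8) / 50.8) * 180 / pi
  set <- generate_contact_angles(starch_surface(), noise_deg = 0)
  expect_equal(unique(set$angles$diiodomethane), expected, tolerance = 1e-10)
  expect_equal(expected, 59.6, tolerance = 0.05)

  # dispersive-only limit: cos theta = 2 sqrt(gamma_d / gamma_L) - 1
  disp <- probe_liquids("apolar", 40, 40, 0)
  th <- young_angle(solid_surface(20, 0, "disp"), disp)
  expect_equal(cos(th * pi / 180), 2 * sqrt(20 / 40) - 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  # infeasible surface names the offending liquid
  expect_error(generate_contact_angles(solid_surface(80, 0, "super"), liquids),
               "diiodomethane")

  a <- generate_contact_angles(starch_surface(), noise_deg = 2, seed = 5)
  b <- generate_contact_angles(starch_surface(), noise_deg = 2, seed = 5)
  expect_identical(a, b)
  expect_true(all(unlist(a$angles) > 0 & unlist(a$angles) < 180))
})

test_that("every generator round-trips through its analysis stage noise-free", {
  # closed loop over a small parameter grid for each stage
  for (pi_c in c(4, 8)) {
    for (le in c(0, 0.1)) {
      p <- isotherm_params(plateau_onset_pressure = pi_c, plateau_tilt = 1,
                           le_shift = le, label = "grid")
      tr <- detect_transitions(generate_isotherm(p, noise_sd = 0))
      expect_rel_equal(tr$pi_C, pi_c, 0.01)
      expect_rel_equal(tr$A_C, 0.77 + le, 0.01)
    }
  }
  for (ep in c(20, 90)) {
    for (ev in c(0, 15)) {
      vm <- viscoelastic_moduli(generate_oscillation_trace(
        oscillation_params(E_prime = ep, E_dprime = ev)))
      expect_equal(vm$E_prime, ep, tolerance = 1e-8)
      expect_equal(vm$E_dprime, ev, tolerance = 1e-8)
    }
  }
  pair <- generate_penetration_pair(penetration_params(5, 0.02, noise_sd = 0))
  fit <- adsorption_summary(delta_pi(pair$penetration, pair$reference))
  expect_rel_equal(fit$delta_pi_max, 5, 1e-6)
  expect_rel_equal(fit$k_ads, 0.02, 1e-6)
  se <- surface_energy(generate_contact_angles(solid_surface(26.1, 18.0, "as"),
                                               noise_deg = 0), n_boot = 0)
  expect_equal(se$gamma_d, 26.1, tolerance = 1e-9)
  expect_equal(se$gamma_p, 18.0, tolerance = 1e-9)
})
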