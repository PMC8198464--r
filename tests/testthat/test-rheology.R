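# Harmonic regression and complex-modulus extraction.

test_that("harmonic fit is exact on noise-free harmonics and unbiased under noise", {
  t <- seq(0, 100, by = 0.25)
  f <- 0.1
  fit <- fit_harmonic(t, 5 + 2 * sin(2 * pi * f * t), f)
  expect_equal(fit$mean, 5, tolerance = 1e-10)
  expect_equal(fit$a_sin, 2, tolerance = 1e-10)
  expect_equal(fit$b_cos, 0, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  cfit <- fit_harmonic(t, rep(7, length(t)), f)
  expect_equal(c(cfit$mean, cfit$a_sin, cfit$b_cos), c(7, 0, 0),
               tolerance = 1e-10)

  # 10 cycles at 64 samples/cycle, noise sd 0.05: quadrature estimator
  # standard error is sd * sqrt(2/N) ~ 0.003, so 0.01 is a safe bound
  tt <- (0:639) / (64 * f)   # 10 cycles of period 10 s
  y <- withr::with_seed(21, 30 - 0.6 * sin(2 * pi * f * tt) +
                          rnorm(length(tt), sd = 0.05))
  nfit <- fit_harmonic(tt, y, f)
  expect_equal(nfit$a_sin, -0.6, tolerance = 0.01)
  expect_equal(nfit$residual_sd, 0.05, tolerance = 0.01)

  expect_error(fit_harmonic(t[t < 5], (t[t < 5]), f), "rank-deficient")
  expect_warning(fit_harmonic(t[t < 25], sin(2 * pi * f * t[t < 25]), f),
                 "fewer than 3")
})

test_that("viscoelastic moduli honour the sign convention for elastic and viscous films", {
  elastic <- viscoelastic_moduli(generate_oscillation_trace(
    oscillation_params(E_prime = 60, E_dprime = 0)))
  expect_equal(elastic$E_prime, 60, tolerance = 1e-8)
  expect_equal(elastic$E_dprime, 0, tolerance = 1e-8)
  expect_equal(elastic$phase, 0, tolerance = 1e-8)
  expect_equal(elastic$u, 0.01, tolerance = 1e-10)

  viscous <- viscoelastic_moduli(generate_oscillation_trace(
    oscillation_params(E_prime = 0, E_dprime = 25)))
  expect_equal(viscous$E_prime, 0, tolerance = 1e-8)
  expect_equal(viscous$E_dprime, 25, tolerance = 1e-8)
  expect_equal(viscous$phase, pi / 2, tolerance = 1e-8)

  noisy <- viscoelastic_moduli(generate_oscillation_trace(
    oscillation_params(E_prime = 60, E_dprime = 10, noise_sd = 0.05, seed = 8)))
  expect_rel_equal(noisy$E_prime, 60, 0.02)
  expect_rel_equal(noisy$E_dprime, 10, 0.02)
})

test_that("moduli are invariant to pressure offsets and area rescaling", {
  tr <- generate_oscillation_trace(oscillation_params(E_prime = 45, E_dprime = 12))
  base <- viscoelastic_moduli(tr)
  shifted <- tr; shifted$pressure <- tr$pressure + 7.5
  rescaled <- tr; rescaled$area <- tr$area * 3.2
  for (variant in list(shifted, rescaled)) {
    v <- viscoelastic_moduli(variant)
    expect_equal(v$E_modulus, base$E_modulus, tolerance = 1e-10)
    expect_equal(v$phase, base$phase, tolerance = 1e-10)
  }
})

test_that("closed-loop recovery is exact noise-free over the studied grid", {
  for (ep in c(10, 60, 120)) {
    for (ev in c(0, 15, 30)) {
      for (f in c(0.02, 0.08, 0.14)) {
        vm <- viscoelastic_moduli(generate_oscillation_trace(
          oscillation_params(E_prime = ep, E_dprime = ev, frequency = f)))
        expect_equal(vm$E_prime, ep, tolerance = max(ep, 1) * 1e-8)
        expect_equal(vm$E_dprime, ev, tolerance = max(ev, 1) * 1e-8)
      }
    }
  }
})

test_that("bursts separated by rest intervals are fitted separately and averaged", {
  # two 5-cycle bursts separated by a 60 s rest, as in the barrier protocol
  f <- 0.1
  p <- oscillation_params(E_prime = 50, E_dprime = 8, frequency = f,
                          n_cycles = 5)
  b1 <- generate_oscillation_trace(p)
  t2 <- b1$time + max(b1$time) + 60
  tr <- oscillation_trace(c(b1$time, t2), rep(b1$area, 2),
                          rep(b1$pressure, 2), frequency = f)
  vm <- viscoelastic_moduli(tr)
  expect_equal(vm$n_bursts, 2)
  expect_equal(vm$E_prime, 50, tolerance = 1e-6)
  expect_equal(vm$E_dprime, 8, tolerance = 1e-6)
})

test_that("frequency sweep collects per-frequency rows and keeps replicates", {
  freqs <- seq(0.02, 0.14, by = 0.02)
  traces <- lapply(freqs, function(f) generate_oscillation_trace(
    oscillation_params(E_prime = 70, E_dprime = 9, frequency = f),
    label = "DPPC", X_W = 0))
  sw <- frequency_sweep(traces)
  expect_equal(nrow(sw), 7)
  expect_equal(sw$frequency, freqs)
  # generator has no dispersion: E'(f) flat
  expect_lt(diff(range(sw$E_prime)), 1e-6)

  # dispersive loss modulus: E''(f) = c f gives perfect rank correlation
  disp <- lapply(freqs, function(f) generate_oscillation_trace(
    oscillation_params(E_prime = 70, E_dprime = 100 * f, frequency = f)))
  sw2 <- frequency_sweep(disp)
  expect_equal(cor(sw2$E_dprime, sw2$frequency, method = "spearman"), 1)

  # duplicates retained with a replicate index
  dup <- frequency_sweep(list(traces[[1]], traces[[1]]))
  expect_equal(dup$replicate, c(1L, 2L))
  expect_error(frequency_sweep(list()), "empty")
})

test_that("elastic modulus decreases along the calibrated composition series", {
  tab <- default_film_moduli()
  rec <- vapply(seq_len(nrow(tab)), function(i) {
    viscoelastic_moduli(generate_oscillation_trace(
      oscillation_params(E_prime = tab$E_prime[i], E_dprime = tab$E_dprime[i],
                         frequency = 0.08)))$E_prime
  }, numeric(1))
  for (coat in c("Fe3O4-S/DPPC", "Fe3O4-AS/DPPC")) {
    idx <- c(which(tab$label == "DPPC"), which(tab$label == coat))
    series <- rec[idx][order(tab$X_W[idx])]
    expect_true(all(diff(series) < 0))
  }
})
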