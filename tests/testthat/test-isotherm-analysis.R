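# Isotherm ingestion, normalisation, smoothing, compression modulus,
# phase classification, transition detection and shifts.

test_that("read_isotherm maps columns, reorders and averages duplicates", {
  df <- data.frame(area_nm2 = seq(1.2, 0.2, length.out = 12),
                   pi_mN_m = seq(0, 30, length.out = 12),
                   junk = "x")
  iso <- read_isotherm(write_iso_csv(df))
  expect_s3_class(iso, "isotherm")
  expect_equal(iso$area, df$area_nm2)
  expect_equal(iso$pressure, df$pi_mN_m)

  # increasing-area (expansion-order) file comes back reversed
  rev_df <- df[order(df$area_nm2), ]
  iso2 <- read_isotherm(write_iso_csv(rev_df))
  expect_equal(iso2$area, iso$area)

  # headerless two-column file: positional mapping
  iso3 <- read_isotherm(write_iso_csv(df[1:2], header = FALSE))
  expect_equal(iso3$pressure, iso$pressure)

  # duplicated area: pressures averaged, n - 1 points
  dup <- df[1:2]
  dup <- rbind(dup, data.frame(area_nm2 = dup$area_nm2[5],
                               pi_mN_m = dup$pi_mN_m[5] + 2))
  iso4 <- read_isotherm(write_iso_csv(dup))
  expect_length(iso4$area, 12)
  expect_equal(iso4$pressure[5], df$pi_mN_m[5] + 1)

  bad <- df[1:2]; bad$pi_mN_m <- as.character(bad$pi_mN_m)
  bad$pi_mN_m[7] <- "oops"
  expect_error(read_isotherm(write_iso_csv(bad)), "line 8")
  expect_error(read_isotherm(write_iso_csv(df[1:6, 1:2])), "at least 10")
})

test_that("mean molecular area counts only phospholipid molecules", {
  # 30 uL of 1 mM DPPC: 1.807e16 molecules
  A <- mean_molecular_area(273, 30, 1e-3 * 734.04, X_W = 0)
  expect_equal(273e14 / A, 30e-6 * 1e-3 * 6.02214076e23, tolerance = 1e-9)
  expect_equal(273e14 / A, 1.807e16, tolerance = 1e-3)
  # linear in trough area
  expect_equal(mean_molecular_area(136.5, 30, 0.734, 0),
               mean_molecular_area(273, 30, 0.734, 0) / 2)
  # only (1 - X_W) of the deposit counts
  expect_equal(mean_molecular_area(273, 30, 0.734, 0.5),
               2 * mean_molecular_area(273, 30, 0.734, 0))
  expect_error(mean_molecular_area(273, 30, 0.734, 1), "no phospholipid")
})

test_that("local-polynomial smoothing reproduces polynomials and reduces noise", {
  a <- seq(1.5, 0.5, length.out = 80)
  quad <- isotherm(a, 40 * (1.6 - a)^2, label = "quad")
  sm <- smooth_isotherm(quad, window = 11, polyorder = 2)
  expect_equal(sm$pressure, quad$pressure, tolerance = 1e-10)

  lin <- isotherm(a, 30 * (1.6 - a), label = "lin")
  expect_equal(smooth_isotherm(lin, window = 3, polyorder = 1)$pressure,
               lin$pressure, tolerance = 1e-10)

  noisy <- generate_isotherm(isotherm_params(), noise_sd = 0.05, seed = 11)
  clean <- generate_isotherm(isotherm_params(), noise_sd = 0)
  sm2 <- smooth_isotherm(noisy, window = 11, polyorder = 2)
  expect_lt(sd(sm2$pressure - clean$pressure),
            0.6 * sd(noisy$pressure - clean$pressure))

  expect_error(smooth_isotherm(quad, window = 10), "odd")
  expect_error(smooth_isotherm(quad, window = 3, polyorder = 2), "polyorder")
  expect_error(smooth_isotherm(quad, window = 81), "smaller than the series")
})

test_that("smoothing agrees with the classical Savitzky-Golay filter on a uniform grid", {
  noisy <- generate_isotherm(isotherm_params(), noise_sd = 0.05, seed = 3)
  mine <- smooth_isotherm(noisy, window = 11, polyorder = 2)$pressure
  ref <- signal::sgolayfilt(noisy$pressure, p = 2, n = 11)
  interior <- 6:(length(ref) - 5)
  expect_equal(mine[interior], ref[interior], tolerance = 1e-8)
})

test_that("compression modulus matches symbolic derivatives on analytic isotherms", {
  # linear: pi = 10 - 5 A  ->  Cs^-1 = 5 A
  a <- seq(1.8, 0.2, length.out = 50)
  mc <- compression_modulus(isotherm(a, 10 - 5 * a))
  expect_equal(mc$modulus, 5 * a, tolerance = 1e-10)
  i12 <- which.min(abs(a - 1.2))
  expect_equal(mc$modulus[i12], 5 * a[i12], tolerance = 1e-10)

  # two-dimensional ideal gas: pi = c/A  ->  Cs^-1 = pi, over a decade of c
  for (c0 in c(1, 3, 10)) {
    iso <- ideal_gas_isotherm(c = c0, n = 4001)
    mc <- compression_modulus(iso)
    interior <- 5:(length(iso$area) - 4)
    expect_rel_equal(mc$modulus[interior], iso$pressure[interior], 1e-6)
  }

  # quadratic: pi = 50 (1 - A)^2 on [0.4, 1]  ->  Cs^-1 = 100 A (1 - A)
  a <- seq(1, 0.4, length.out = 601)
  mc <- compression_modulus(isotherm(a, 50 * (1 - a)^2))
  interior <- 2:600
  expect_rel_equal(mc$modulus[interior], (100 * a * (1 - a))[interior], 1e-8)
  expect_equal(mc$modulus[which(a == 0.5)], 25, tolerance = 1e-8)

  # irregular grid: still exact for a quadratic (3-point Lagrange)
  a_irr <- sort(c(seq(1, 0.4, length.out = 101), 0.777, 0.513), decreasing = TRUE)
  mc_irr <- compression_modulus(isotherm(a_irr, 50 * (1 - a_irr)^2))
  expect_rel_equal(mc_irr$modulus[2:102], (100 * a_irr * (1 - a_irr))[2:102], 1e-8)
})

test_that("Davies-Rideal classification has fixed breakpoints and five labels", {
  expect_equal(classify_phase(30), "LE")
  expect_equal(classify_phase(150), "LC")
  expect_equal(classify_phase(c(250, 250.1)), c("LC", "S"))
  expect_equal(classify_phase(c(0, 12.4, 12.5, 49.9, 50, 99.9, 100)),
               c("G/LE-gas", "G/LE-gas", "LE", "LE", "L", "L", "LC"))
  expect_equal(classify_phase(-3), "unstable/artifact")
  expect_error(classify_phase(NaN), "finite")
  # total and piecewise constant: exactly five phase labels over a fine sweep
  sweep <- classify_phase(seq(0, 400, by = 0.5))
  expect_equal(sort(unique(sweep)), sort(c("G/LE-gas", "LE", "L", "LC", "S")))
})

test_that("tangent extrapolation recovers exact and synthetic lift-off areas", {
  # exactly linear branch: A_EXT = A0 for any window
  a <- seq(1.4, 0.4, length.out = 60)
  lin <- isotherm(a, 25 * (1.5 - a))
  for (w in list(c(2, 10), c(5, 20))) {
    expect_equal(extrapolated_area(lin, fit_window = w)$A_EXT, 1.5,
                 tolerance = 1e-9)
  }

  # synthetic DPPC, window anchored just below the plateau onset: the fit
  # approaches the analytic tangent through (A_C, pi_C), crossing zero at
  # 0.895 nm^2
  iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
  fit <- extrapolated_area(iso, fit_window = c(0.9, 1.0) * 5)
  expect_equal(fit$A_EXT, 0.895, tolerance = 0.895 * 0.01)
  expect_gt(fit$r_squared, 0.99)

  # A_EXT increase of the binary films over pure DPPC (default windows)
  s <- generate_isotherm(binary_film_params("Fe3O4-S"), noise_sd = 0)
  d_s <- extrapolated_area(s)$A_EXT - extrapolated_area(iso)$A_EXT
  expect_equal(d_s, 0.19, tolerance = 0.01)

  expect_error(extrapolated_area(lin, fit_window = c(5, 100)),
               "does not reach")
  rising <- isotherm(a, 5 + 10 * a)  # pressure rising with area: wrong branch
  expect_error(extrapolated_area(rising, fit_window = c(6, 12)),
               "non-negative slope")
  expect_warning(extrapolated_area(iso, fit_window = c(4.8, 4.95)),
                 "low-confidence")
})

test_that("transition detection recovers plateau parameters on calibrated films", {
  iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
  tr <- detect_transitions(iso)
  expect_true(tr$has_transition)
  expect_equal(tr$A_C, 0.77, tolerance = 0.77 * 0.01)
  expect_equal(tr$pi_C, 5.0, tolerance = 0.05)
  # branch maxima sit in the LE and LC Davies-Rideal ranges
  expect_equal(classify_phase(tr$max_modulus_LE), "LE")
  expect_equal(classify_phase(tr$max_modulus_LC), "LC")

  trs <- detect_transitions(generate_isotherm(binary_film_params("Fe3O4-S"),
                                              noise_sd = 0))
  expect_equal(trs$pi_C, 12, tolerance = 0.12)
  tras <- detect_transitions(generate_isotherm(binary_film_params("Fe3O4-AS"),
                                               noise_sd = 0))
  expect_equal(tras$pi_C, 10, tolerance = 0.10)
  # nanoparticles stiffen the LE branch and soften the condensed branch
  expect_gt(trs$max_modulus_LE, tr$max_modulus_LE)
  expect_lt(trs$max_modulus_LC, tr$max_modulus_LC)

  # strictly linear isotherm: no interior minimum, fields absent
  a <- seq(1.4, 0.4, length.out = 60)
  none <- detect_transitions(isotherm(a, 25 * (1.5 - a)))
  expect_false(none$has_transition)
  expect_true(is.na(none$A_C) && is.na(none$pi_C))

  # a clearly tilted plateau reports entry and exit pressures
  tilted <- detect_transitions(generate_isotherm(
    isotherm_params(plateau_tilt = 2), noise_sd = 0))
  expect_false(is.na(tilted$pi_prime_C))
  expect_lt(tilted$pi_prime_C, tilted$pi_dprime_C)

  expect_equal(phase_at(tr, 3), "LE")
  expect_equal(phase_at(tr, 30), "LC")
})

test_that("transition closed loop holds over a parameter grid, noise-free and noisy", {
  grid <- expand.grid(pi_c = c(4, 6, 9, 12), tilt = c(0.8, 1.5),
                      a_c = c(0.7, 0.85), le = c(0, 0.15))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- isotherm_params(plateau_onset_area = g$a_c,
                         plateau_onset_pressure = g$pi_c,
                         plateau_tilt = g$tilt, le_shift = g$le,
                         plateau_end_area = 0.5, label = "grid")
    tr <- detect_transitions(generate_isotherm(p, noise_sd = 0))
    expect_rel_equal(tr$pi_C, g$pi_c, 0.01)
    expect_rel_equal(tr$pi_prime_C, g$pi_c, 0.01)
    expect_rel_equal(tr$A_C, g$a_c + g$le, 0.01)
  }
  # with instrument-level noise, recovery within 5% after smoothing
  for (seed in 1:5) {
    noisy <- generate_isotherm(isotherm_params(plateau_tilt = 1),
                               noise_sd = 0.05, seed = seed)
    tr <- detect_transitions(smooth_isotherm(noisy, window = 41, polyorder = 3))
    expect_rel_equal(tr$pi_C, 5, 0.05)
    expect_rel_equal(tr$A_C, 0.77, 0.05)
  }
})

test_that("isotherm shifts are antisymmetric and recover the generator displacement", {
  dppc <- generate_isotherm(isotherm_params(), noise_sd = 0)
  expect_equal(isotherm_shift(dppc, dppc, 30), 0)

  s <- generate_isotherm(binary_film_params("Fe3O4-S"), noise_sd = 0)
  as_ <- generate_isotherm(binary_film_params("Fe3O4-AS"), noise_sd = 0)
  expect_equal(isotherm_shift(s, dppc, 30), -isotherm_shift(dppc, s, 30))
  # high-pressure displacement equals the generator's lc_shift by construction
  expect_equal(isotherm_shift(s, dppc, 30), -0.05, tolerance = 1e-6)
  expect_equal(isotherm_shift(as_, dppc, 30), +0.05, tolerance = 1e-6)
  # LE-branch displacement equals le_shift
  shifted_only <- generate_isotherm(isotherm_params(le_shift = 0.1, lc_shift = 0.1),
                                    noise_sd = 0)
  expect_equal(isotherm_shift(shifted_only, dppc, 2), 0.1, tolerance = 1e-3)

  # pressures on the coexistence plateau are rejected, naming its bounds
  expect_error(isotherm_shift(s, dppc, 5.2), "plateau of isotherm 'DPPC'")
  expect_error(isotherm_shift(dppc, dppc, 100), "outside the rising range")
})
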