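# Synthetic-data generators: every analysis stage in the package has a
# matching generator with known ground truth, so closed-loop tests can
# verify parameter recovery without laboratory data.

#' Evaluate the reference isotherm model
#'
#' Noise-free surface pressure of the piecewise model described in
#' [isotherm_params()] at arbitrary (shifted) areas: zero above lift-off, a
#' quadratic LE branch `pi(A) = pi_C ((A_lift - A)/(A_lift - A_C))^2`, a
#' linear tilted plateau, and a linear LC branch of slope `lc_slope` capped
#' at the collapse pressure.  The LE branch (and lift-off) is displaced by
#' `le_shift`, the LC branch by `lc_shift`, blended linearly in pressure
#' across the plateau.
#'
#' @param params An [isotherm_params] object.
#' @param area Areas (nm^2 per molecule) at which to evaluate.
#' @return Surface pressures, mN/m.
#' @export
#' @examples
#' isotherm_model_pressure(isotherm_params(), c(1.02, 0.895, 0.77, 0.55))
isotherm_model_pressure <- function(params, area) {
  stopifnot(inherits(params, "isotherm_params"))
  p <- params
  w <- p$lift_off_area - p$plateau_onset_area
  a_lift <- p$lift_off_area + p$le_shift
  a_on <- p$plateau_onset_area + p$le_shift
  a_end <- p$plateau_end_area + p$lc_shift
  pi_on <- p$plateau_onset_pressure
  pi_top <- pi_on + p$plateau_tilt
  vapply(area, function(a) {
    if (a >= a_lift) return(0)
    if (a >= a_on) {
      s <- (a_lift - a) / w
      return(pi_on * s^2)
    }
    if (a >= a_end && p$plateau_tilt > 0) {
      frac <- (a_on - a) / (a_on - a_end)
      return(pi_on + frac * p$plateau_tilt)
    }
    if (a >= a_end) return(pi_on)   # horizontal plateau
    min(pi_top + p$lc_slope * (a_end - a), p$collapse_pressure)
  }, numeric(1))
}

#' Generate a synthetic pi--A isotherm
#'
#' Samples the reference isotherm model on a strictly decreasing area grid
#' running from above the (shifted) lift-off area down to the collapse cut,
#' adding independent Gaussian noise to the pressure channel.
#'
#' @param params An [isotherm_params] object.
#' @param n_points Number of grid points (at least 50; default 400).
#' @param noise_sd Gaussian noise standard deviation on pressure, mN/m.
#' @param seed RNG seed (used only when `noise_sd > 0`); identical
#'   parameters and seed give bit-identical output.
#' @return An [isotherm] carrying the film label and weight fraction of
#'   `params`.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
#' max(iso$pressure)
generate_isotherm <- function(params, n_points = 400, noise_sd = 0.05,
                              seed = 1L) {
  stopifnot(inherits(params, "isotherm_params"))
  n_points <- check_count(n_points, "n_points", lower = 50L)
  check_number(noise_sd, "noise_sd", lower = 0)
  p <- params
  a_start <- (p$lift_off_area + p$le_shift) * 1.05
  a_collapse <- p$plateau_end_area + p$lc_shift -
    (p$collapse_pressure - p$plateau_onset_pressure - p$plateau_tilt) / p$lc_slope
  area <- seq(a_start, a_collapse, length.out = n_points)
  pressure <- isotherm_model_pressure(p, area)
  if (any(diff(pressure) < -1e-12)) {
    stop("internal error: model pressure not non-increasing in area",
         call. = FALSE)
  }
  if (noise_sd > 0) {
    pressure <- with_seed(seed, pressure + rnorm(n_points, sd = noise_sd))
    pressure <- pmax(pressure, -0.5)
  }
  isotherm(area, pressure, label = p$label, X_W = p$X_W, temperature = 20)
}

#' Generate a synthetic oscillating-barrier trace
#'
#' Forced sinusoidal area oscillation `A(t) = A_0 (1 + u sin(2 pi f t))`
#' with the linear viscoelastic pressure response
#' `pi(t) = pi_0 - u (E' sin(2 pi f t) + E'' cos(2 pi f t))` plus optional
#' Gaussian noise, sampled for `n_cycles` full cycles.
#'
#' @param params An [oscillation_params] object.
#' @param label,X_W Metadata attached to the trace.
#' @return An [oscillation_trace].
#' @export
#' @examples
#' tr <- generate_oscillation_trace(oscillation_params(E_prime = 60))
#' viscoelastic_moduli(tr)
generate_oscillation_trace <- function(params, label = "", X_W = NA_real_) {
  stopifnot(inherits(params, "oscillation_params"))
  p <- params
  if (p$sampling_rate < 8 * p$frequency) {
    stop(sprintf(
      "sampling_rate (%g Hz) under-samples the harmonic: need >= 8 x frequency (%g Hz)",
      p$sampling_rate, p$frequency), call. = FALSE)
  }
  n <- floor(p$n_cycles * p$sampling_rate / p$frequency)
  t <- (0:n) / p$sampling_rate
  wt <- 2 * pi * p$frequency * t
  area <- p$baseline_area * (1 + p$amplitude * sin(wt))
  pressure <- p$baseline_pressure -
    p$amplitude * (p$E_prime * sin(wt) + p$E_dprime * cos(wt))
  if (p$noise_sd > 0) {
    pressure <- with_seed(p$seed, pressure + rnorm(length(t), sd = p$noise_sd))
  }
  oscillation_trace(time = t, area = area, pressure = pressure,
                    frequency = p$frequency, label = label, X_W = X_W,
                    baseline_pressure = p$baseline_pressure)
}

#' Generate a synthetic penetration/reference trace pair
#'
#' The reference trough follows
#' `pi_R(t) = pi_0 + drift * t (+ noise)`; the penetration trough adds the
#' exponential-saturation adsorption signal
#' `dpi_max (1 - exp(-k_ads t))` on the same time grid, with independent
#' noise realisations for the two troughs.
#'
#' @param params A [penetration_params] object.
#' @param label Nanoparticle label attached to both traces.
#' @param concentration Subphase nanoparticle concentration, ug/mL
#'   (3.5 in the reference protocol).
#' @return A list with elements `penetration` and `reference`, both
#'   [kinetics_trace] objects.
#' @export
#' @examples
#' pair <- generate_penetration_pair(nanoparticle_penetration_params("Fe3O4-AS"))
#' dp <- delta_pi(pair$penetration, pair$reference)
#' tail(dp$delta_pi, 1)
generate_penetration_pair <- function(params, label = "", concentration = 3.5) {
  stopifnot(inherits(params, "penetration_params"))
  p <- params
  t <- seq(0, p$duration, by = p$sampling_interval)
  base <- p$baseline_pressure + p$reference_drift * t
  signal <- p$delta_pi_max * (1 - exp(-p$k_ads * t))
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, matrix(rnorm(2 * length(t), sd = p$noise_sd), ncol = 2))
    ref_pi <- base + noise[, 1]
    pe_pi <- base + signal + noise[, 2]
  } else {
    ref_pi <- base
    pe_pi <- base + signal
  }
  list(
    penetration = kinetics_trace(t, pe_pi, role = "penetration", label = label,
                                 concentration = concentration),
    reference = kinetics_trace(t, ref_pi, role = "reference", label = label,
                               concentration = 0)
  )
}

# Owens-Wendt forward relation: cosine of the Young angle of `liquid` on
# `solid`.  Returns a value possibly outside [-1, 1]; callers decide how to
# treat infeasible combinations.
owens_wendt_cosine <- function(solid, liquid) {
  (2 * (sqrt(solid$gamma_d * liquid$gamma_d) +
          sqrt(solid$gamma_p * liquid$gamma_p))) / liquid$gamma_total - 1
}

#' Young contact angle predicted by the Owens--Wendt relation
#'
#' @param solid A [solid_surface].
#' @param liquids A probe-liquid table (see [probe_liquids()]).
#' @return Named vector of contact angles in degrees.
#' @export
#' @examples
#' young_angle(starch_surface())
young_angle <- function(solid, liquids = default_probe_liquids()) {
  stopifnot(inherits(solid, "solid_surface"))
  cosv <- vapply(seq_len(nrow(liquids)), function(i)
    owens_wendt_cosine(solid, liquids[i, ]), numeric(1))
  bad <- which(cosv < -1 | cosv > 1)
  if (length(bad)) {
    stop(sprintf(
      "surface '%s' is infeasible for liquid '%s': Owens-Wendt cosine = %.3f outside [-1, 1]",
      solid$label, liquids$name[bad[1]], cosv[bad[1]]), call. = FALSE)
  }
  setNames(acos(cosv) * 180 / pi, liquids$name)
}

#' Generate synthetic contact-angle drop measurements
#'
#' Inverse Owens--Wendt problem: for each probe liquid the Young angle of
#' the prescribed solid is computed and `n_drops` noisy drop readings are
#' drawn around it (Gaussian, clipped to the open interval (0, 180)
#' degrees).
#'
#' @param solid A [solid_surface] with prescribed components.
#' @param liquids Probe-liquid table.
#' @param n_drops Drops per liquid (protocol: at least 10).
#' @param noise_deg Angular noise standard deviation, degrees.
#' @param seed RNG seed.
#' @return A [contact_angle_set].
#' @export
#' @examples
#' set <- generate_contact_angles(starch_surface(), noise_deg = 0)
#' aggregate_angles(set)
generate_contact_angles <- function(solid, liquids = default_probe_liquids(),
                                    n_drops = 10, noise_deg = 1, seed = 1L) {
  n_drops <- check_count(n_drops, "n_drops", lower = 1L)
  check_number(noise_deg, "noise_deg", lower = 0)
  theta <- young_angle(solid, liquids)
  angles <- with_seed(seed, lapply(theta, function(th) {
    x <- th + if (noise_deg > 0) rnorm(n_drops, sd = noise_deg) else numeric(n_drops)
    pmin(pmax(x, 1e-6), 180 - 1e-6)
  }))
  contact_angle_set(angles, label = solid$label)
}
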