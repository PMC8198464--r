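# Model parameter sets for the synthetic-data generators.

#' Parameters of the reference piecewise isotherm model
#'
#' Describes a synthetic surface pressure--mean molecular area (pi--A)
#' isotherm built from three analytic branches: a quadratic liquid-expanded
#' (LE) rise from the lift-off area down to the plateau onset, a linear
#' (optionally tilted) LE--LC coexistence plateau, and a linear
#' liquid-condensed (LC) branch up to the collapse pressure.  Binary
#' nanoparticle/phospholipid films are represented by two signed area
#' shifts: `le_shift` expands the whole low-pressure branch (nanoparticles
#' occupying interfacial area) and `lc_shift` displaces the high-pressure
#' branch (squeeze-out or retention), blended linearly across the plateau.
#'
#' The default values reproduce a pure DPPC monolayer at 20 degC with the
#' LE--LC plateau starting at A_C = 0.77 nm^2 and pi_C = 5 mN/m.
#'
#' @param lift_off_area Area (nm^2 per molecule) where the pressure lifts
#'   off zero.
#' @param plateau_onset_area A_C, plateau onset area (nm^2).
#' @param plateau_onset_pressure pi_C, plateau onset pressure (mN/m).
#' @param plateau_end_area Area at the end of the coexistence plateau (nm^2).
#' @param plateau_tilt Pressure rise across the plateau (mN/m); 0 gives a
#'   horizontal plateau.
#' @param lc_slope Slope of the LC branch, mN/m per nm^2 (positive; pressure
#'   rises as area shrinks).
#' @param collapse_pressure Pressure (mN/m) at which the generated isotherm
#'   is cut.
#' @param le_shift Uniform expansion of the LE branch (nm^2); 0 for pure DPPC.
#' @param lc_shift Signed shift of the high-pressure branch (nm^2).
#' @param label Film label.
#' @param X_W Nanoparticle weight fraction in the spread mixture, in [0, 1).
#' @return An object of class `isotherm_params`.
#' @seealso [generate_isotherm()], [isotherm_model_pressure()],
#'   [binary_film_params()]
#' @export
#' @examples
#' p <- isotherm_params()          # pure DPPC defaults
#' isotherm_model_pressure(p, c(1.02, 0.77))
isotherm_params <- function(lift_off_area = 1.02,
                            plateau_onset_area = 0.77,
                            plateau_onset_pressure = 5,
                            plateau_end_area = 0.55,
                            plateau_tilt = 0.5,
                            lc_slope = 250,
                            collapse_pressure = 55,
                            le_shift = 0,
                            lc_shift = 0,
                            label = "DPPC",
                            X_W = 0) {
  check_number(lift_off_area, "lift_off_area", lower = 0, closed_lower = FALSE)
  check_number(plateau_onset_area, "plateau_onset_area", lower = 0,
               upper = lift_off_area, closed_lower = FALSE, closed_upper = FALSE)
  check_number(plateau_end_area, "plateau_end_area", lower = 0,
               upper = plateau_onset_area, closed_lower = FALSE, closed_upper = FALSE)
  check_number(plateau_onset_pressure, "plateau_onset_pressure", lower = 0,
               closed_lower = FALSE)
  check_number(plateau_tilt, "plateau_tilt", lower = 0)
  check_number(lc_slope, "lc_slope", lower = 0, closed_lower = FALSE)
  check_number(collapse_pressure, "collapse_pressure",
               lower = plateau_onset_pressure + plateau_tilt,
               closed_lower = FALSE)
  check_number(le_shift, "le_shift")
  check_number(lc_shift, "lc_shift")
  check_number(X_W, "X_W", lower = 0, upper = 1, closed_upper = FALSE)
  # the shifted plateau must still move to smaller areas as pi grows
  if ((plateau_onset_area + le_shift) <= (plateau_end_area + lc_shift)) {
    stop("shifted plateau is non-decreasing in area: ",
         "(plateau_onset_area + le_shift) must exceed (plateau_end_area + lc_shift)",
         call. = FALSE)
  }
  structure(list(lift_off_area = lift_off_area,
                 plateau_onset_area = plateau_onset_area,
                 plateau_onset_pressure = plateau_onset_pressure,
                 plateau_end_area = plateau_end_area,
                 plateau_tilt = plateau_tilt,
                 lc_slope = lc_slope,
                 collapse_pressure = collapse_pressure,
                 le_shift = le_shift,
                 lc_shift = lc_shift,
                 label = as.character(label),
                 X_W = X_W),
            class = "isotherm_params")
}

#' @export
print.isotherm_params <- function(x, ...) {
  cat(sprintf("Isotherm model parameters: %s (X_W = %g)\n", x$label, x$X_W))
  cat(sprintf("  lift-off %.3f nm^2, plateau (%.3f nm^2, %.2f mN/m) -> (%.3f nm^2, %.2f mN/m)\n",
              x$lift_off_area, x$plateau_onset_area, x$plateau_onset_pressure,
              x$plateau_end_area, x$plateau_onset_pressure + x$plateau_tilt))
  cat(sprintf("  LC slope %g mN/m/nm^2, collapse %g mN/m, shifts LE %+.3f / LC %+.3f nm^2\n",
              x$lc_slope, x$collapse_pressure, x$le_shift, x$lc_shift))
  invisible(x)
}

#' Default parameter sets for nanoparticle/DPPC binary films
#'
#' Calibrated synthetic scenarios for DPPC monolayers doped with magnetite
#' nanoparticles coated with native starch (`"Fe3O4-S"`) or aminated starch
#' (`"Fe3O4-AS"`).  At the reference weight fraction X_W = 0.36 the native
#' starch film expands the LE branch by 0.19 nm^2, raises the transition
#' onset to 12 mN/m and shifts the condensed branch to smaller areas by
#' 0.05 nm^2 (squeeze-out); the aminated-starch film expands by 0.14 nm^2,
#' raises the onset to 10 mN/m and stays shifted to larger areas by
#' 0.05 nm^2.  For other weight fractions the deviations from pure DPPC are
#' scaled linearly in `X_W / 0.36`.
#'
#' The plateau end area is chosen so that, before the `lc_shift` is applied,
#' the condensed branch is colinear with the base DPPC branch; the
#' high-pressure displacement of the binary isotherm therefore equals
#' `lc_shift` exactly at any pressure on the LC branch.
#'
#' @param coating `"Fe3O4-S"` (native starch) or `"Fe3O4-AS"` (aminated
#'   starch).
#' @param X_W Nanoparticle weight fraction; defaults to the highest studied
#'   composition, 0.36.
#' @param base Pure-phospholipid parameter set the film is built from.
#' @return An `isotherm_params` object.
#' @export
#' @examples
#' binary_film_params("Fe3O4-S")
binary_film_params <- function(coating = c("Fe3O4-S", "Fe3O4-AS"),
                               X_W = 0.36,
                               base = isotherm_params()) {
  coating <- match.arg(coating)
  check_number(X_W, "X_W", lower = 0, upper = 1, closed_upper = FALSE)
  stopifnot(inherits(base, "isotherm_params"))
  s <- X_W / 0.36
  if (coating == "Fe3O4-S") {
    le_shift <- 0.19 * s
    onset_p <- base$plateau_onset_pressure + 7 * s
    lc_shift <- -0.05 * s
  } else {
    le_shift <- 0.14 * s
    onset_p <- base$plateau_onset_pressure + 5 * s
    lc_shift <- +0.05 * s
  }
  isotherm_params(
    lift_off_area = base$lift_off_area,
    plateau_onset_area = base$plateau_onset_area,
    plateau_onset_pressure = onset_p,
    plateau_end_area = base$plateau_end_area -
      (onset_p - base$plateau_onset_pressure) / base$lc_slope,
    plateau_tilt = base$plateau_tilt,
    lc_slope = base$lc_slope,
    collapse_pressure = base$collapse_pressure,
    le_shift = le_shift,
    lc_shift = lc_shift,
    label = paste0(coating, "/DPPC"),
    X_W = X_W
  )
}

#' Parameters for a synthetic oscillating-barrier trace
#'
#' Describes the forced small-amplitude area oscillation used to probe the
#' dilatational viscoelastic modulus E = E' + iE'' of a monolayer held at a
#' baseline surface pressure (30 mN/m by default, the lateral pressure of a
#' native membrane).
#'
#' @param E_prime Elastic (storage) modulus E', mN/m.
#' @param E_dprime Viscous (loss) modulus E'', mN/m.
#' @param frequency Barrier oscillation frequency, Hz (the protocol spans
#'   20--140 mHz).
#' @param amplitude Relative area amplitude u (peak, not peak-to-peak);
#'   1 percent by default, at most 5 percent to stay in the linear regime.
#' @param baseline_pressure Baseline surface pressure pi_0, mN/m.
#' @param baseline_area Baseline trough area A_0, cm^2 (default the 273 cm^2
#'   trough).
#' @param n_cycles Number of full oscillation cycles (protocol records at
#'   least 10).
#' @param sampling_rate Sampling rate, Hz; must be at least 8 times the
#'   oscillation frequency.
#' @param noise_sd Gaussian noise on the pressure channel, mN/m.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An object of class `oscillation_params`.
#' @export
oscillation_params <- function(E_prime, E_dprime = 0, frequency = 0.1,
                               amplitude = 0.01, baseline_pressure = 30,
                               baseline_area = 273, n_cycles = 10,
                               sampling_rate = 64 * frequency,
                               noise_sd = 0, seed = 1L) {
  check_number(E_prime, "E_prime", lower = 0)
  check_number(E_dprime, "E_dprime")
  check_number(frequency, "frequency", lower = 0, closed_lower = FALSE)
  check_number(amplitude, "amplitude", lower = 0, upper = 0.05,
               closed_lower = FALSE)
  check_number(baseline_pressure, "baseline_pressure")
  check_number(baseline_area, "baseline_area", lower = 0, closed_lower = FALSE)
  n_cycles <- check_count(n_cycles, "n_cycles", lower = 1L)
  check_number(sampling_rate, "sampling_rate", lower = 0, closed_lower = FALSE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(E_prime = E_prime, E_dprime = E_dprime,
                 frequency = frequency, amplitude = amplitude,
                 baseline_pressure = baseline_pressure,
                 baseline_area = baseline_area, n_cycles = n_cycles,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 seed = seed),
            class = "oscillation_params")
}

#' Parameters for a synthetic penetration/reference trace pair
#'
#' Emulates a penetration experiment: a DPPC monolayer compressed to
#' 30 mN/m at fixed barrier position, nanoparticles injected into the
#' subphase at time zero, and the surface pressure recorded alongside a
#' simultaneous reference trough with no injection.  Adsorption follows an
#' exponential saturation dpi(t) = dpi_max (1 - exp(-k_ads t)); both troughs
#' share a common linear drift (evaporation, ambient fluctuations) that the
#' differential measurement cancels.
#'
#' @param delta_pi_max Saturation pressure increase dpi_max, mN/m.
#' @param k_ads Adsorption rate constant, 1/min.
#' @param reference_drift Common baseline drift, mN/m per min.
#' @param duration Trace length, min (default 360 = the 6 h endpoint).
#' @param sampling_interval Sampling interval, min.
#' @param baseline_pressure Initial surface pressure of both troughs, mN/m.
#' @param noise_sd Gaussian noise per sample, mN/m (independent between the
#'   two troughs).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An object of class `penetration_params`.
#' @export
penetration_params <- function(delta_pi_max, k_ads = 0.01,
                               reference_drift = 0, duration = 360,
                               sampling_interval = 1, baseline_pressure = 30,
                               noise_sd = 0, seed = 1L) {
  check_number(delta_pi_max, "delta_pi_max", lower = 0)
  check_number(k_ads, "k_ads", lower = 0)
  check_number(reference_drift, "reference_drift")
  check_number(duration, "duration", lower = 0, closed_lower = FALSE)
  check_number(sampling_interval, "sampling_interval", lower = 0,
               closed_lower = FALSE, upper = duration)
  check_number(baseline_pressure, "baseline_pressure")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(delta_pi_max = delta_pi_max, k_ads = k_ads,
                 reference_drift = reference_drift, duration = duration,
                 sampling_interval = sampling_interval,
                 baseline_pressure = baseline_pressure,
                 noise_sd = noise_sd, seed = seed),
            class = "penetration_params")
}

#' Default penetration scenarios for the coated-nanoparticle study
#'
#' Calibrated so that the noise-free differential pressure reaches about
#' 7.1 mN/m (aminated starch coating, `"Fe3O4-AS"`) and about 4.2 mN/m
#' (native starch, `"Fe3O4-S"`) six hours after injection, with
#' k_ads = 0.01 per min.
#'
#' @param coating `"Fe3O4-S"` or `"Fe3O4-AS"`.
#' @param ... Overrides passed on to [penetration_params()].
#' @return A `penetration_params` object.
#' @export
nanoparticle_penetration_params <- function(coating = c("Fe3O4-S", "Fe3O4-AS"),
                                            ...) {
  coating <- match.arg(coating)
  dmax <- if (coating == "Fe3O4-S") 4.32 else 7.3
  penetration_params(delta_pi_max = dmax, k_ads = 0.01, ...)
}

#' Solid surface described by its Owens--Wendt components
#'
#' @param gamma_d Dispersive component, mJ/m^2.
#' @param gamma_p Polar component, mJ/m^2.
#' @param label Surface label.
#' @return An object of class `solid_surface`; `gamma_s` is the total
#'   surface free energy `gamma_d + gamma_p`.
#' @export
#' @examples
#' starch_surface()
solid_surface <- function(gamma_d, gamma_p, label = "") {
  check_number(gamma_d, "gamma_d", lower = 0)
  check_number(gamma_p, "gamma_p", lower = 0)
  structure(list(gamma_d = gamma_d, gamma_p = gamma_p,
                 gamma_s = gamma_d + gamma_p, label = as.character(label)),
            class = "solid_surface")
}

#' @export
print.solid_surface <- function(x, ...) {
  cat(sprintf("Solid surface '%s': gamma_s = %.1f (d %.1f + p %.1f) mJ/m^2\n",
              x$label, x$gamma_s, x$gamma_d, x$gamma_p))
  invisible(x)
}

#' @rdname solid_surface
#' @export
starch_surface <- function() solid_surface(28.8, 5.6, "starch")

#' @rdname solid_surface
#' @export
aminated_starch_surface <- function() solid_surface(26.1, 18.0, "aminated starch")

#' Probe liquid table for contact-angle work
#'
#' `probe_liquids()` validates a user-supplied liquid table;
#' `default_probe_liquids()` returns the two liquids of the goniometer
#' protocol with literature Owens--Wendt components (mJ/m^2): glycerin
#' (63.4 total = 37.0 dispersive + 26.4 polar) and diiodomethane (50.8,
#' purely dispersive).
#'
#' @param name Liquid names.
#' @param gamma_total Total surface tension of each liquid, mJ/m^2.
#' @param gamma_d Dispersive components, mJ/m^2.
#' @param gamma_p Polar components, mJ/m^2.
#' @return A data.frame with columns `name`, `gamma_total`, `gamma_d`,
#'   `gamma_p`.
#' @export
probe_liquids <- function(name, gamma_total, gamma_d, gamma_p) {
  stopifnot(length(name) == length(gamma_total),
            length(name) == length(gamma_d),
            length(name) == length(gamma_p))
  if (any(gamma_total < 0 | gamma_d < 0 | gamma_p < 0)) {
    stop("probe-liquid surface tension components must be non-negative",
         call. = FALSE)
  }
  bad <- abs(gamma_total - (gamma_d + gamma_p)) > 0.1
  if (any(bad)) {
    stop(sprintf("components of liquid '%s' do not sum to its total tension",
                 name[which(bad)[1]]), call. = FALSE)
  }
  data.frame(name = as.character(name), gamma_total = gamma_total,
             gamma_d = gamma_d, gamma_p = gamma_p,
             stringsAsFactors = FALSE)
}

#' @rdname probe_liquids
#' @export
default_probe_liquids <- function() {
  probe_liquids(name = c("glycerin", "diiodomethane"),
                gamma_total = c(63.4, 50.8),
                gamma_d = c(37.0, 50.8),
                gamma_p = c(26.4, 0.0))
}

#' Calibrated dilatational moduli for the synthetic composition series
#'
#' Ground-truth (E', E'') values, constant over frequency, used by the
#' synthetic rheology scenario.  The series mirrors the qualitative trends
#' of the study system: elastic films (E' well above E''), E' decreasing as
#' the nanoparticle weight fraction grows, E'' roughly constant for the
#' native-starch films and slightly decreasing for the aminated-starch
#' films.  The numbers themselves are free calibration choices.
#'
#' @return A data.frame with columns `label`, `X_W`, `E_prime`, `E_dprime`
#'   (mN/m).
#' @export
default_film_moduli <- function() {
  data.frame(
    label = c("DPPC",
              rep("Fe3O4-S/DPPC", 3), rep("Fe3O4-AS/DPPC", 3)),
    X_W = c(0, 0.02, 0.10, 0.36, 0.02, 0.10, 0.36),
    E_prime = c(85, 78, 66, 48, 80, 70, 55),
    E_dprime = c(12, 12, 12, 13, 11, 10, 8),
    stringsAsFactors = FALSE
  )
}
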