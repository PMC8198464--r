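# Compression modulus, Davies-Rideal phase classification, transition
# detection, tangent extrapolation and isotherm shifts.

#' Compression modulus of an isotherm
#'
#' Computes `Cs^-1(A) = -A dpi/dA`, the reciprocal of the in-plane
#' compressibility, by three-point Lagrange central differences on the
#' (possibly irregular) area grid, with one-sided two-point differences at
#' the two boundary points.  The input should be noise-free or smoothed
#' (see [smooth_isotherm()]): numerical differentiation amplifies raw
#' sensor noise.
#'
#' @param iso An [isotherm] with at least 3 points.
#' @return A `modulus_curve`: list with aligned `pressure`, `modulus` and
#'   `area` vectors.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
#' mc <- compression_modulus(iso)
#' range(mc$modulus)
compression_modulus <- function(iso) {
  stopifnot(inherits(iso, "isotherm"))
  x <- iso$area; y <- iso$pressure; n <- length(x)
  if (n < 3L) stop("need at least 3 points to differentiate", call. = FALSE)
  if (any(diff(x) >= 0)) {
    stop("area must be strictly decreasing in compression order", call. = FALSE)
  }
  d <- numeric(n)
  i <- 2:(n - 1)
  h1 <- x[i] - x[i - 1]
  h2 <- x[i + 1] - x[i]
  d[i] <- -h2 / (h1 * (h1 + h2)) * y[i - 1] +
    (h2 - h1) / (h1 * h2) * y[i] +
    h1 / (h2 * (h1 + h2)) * y[i + 1]
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  structure(list(pressure = y, modulus = -x * d, area = x,
                 label = iso$label, X_W = iso$X_W),
            class = "modulus_curve")
}

#' @export
print.modulus_curve <- function(x, ...) {
  cat(sprintf("Compression-modulus curve '%s' (%d points), Cs^-1 in [%.1f, %.1f] mN/m\n",
              x$label, length(x$modulus), min(x$modulus), max(x$modulus)))
  invisible(x)
}

#' @export
as.data.frame.modulus_curve <- function(x, ...) {
  data.frame(pressure_mN_m = x$pressure, modulus_mN_m = x$modulus,
             area_nm2 = x$area)
}

#' Davies--Rideal monolayer phase classification
#'
#' Maps compression-modulus values (mN/m) onto the classical monolayer
#' states: below 12.5 gaseous/LE-gas transition region, 12.5--50
#' liquid-expanded (LE), 50--100 liquid (L), 100--250 liquid-condensed
#' (LC), above 250 solid (S).  Lower bounds are inclusive and the solid
#' state is strictly above 250.  Negative moduli (unstable film or
#' differentiation artifact) are flagged rather than classified.
#'
#' @param modulus Compression modulus values, mN/m.
#' @return Character vector of labels among `"G/LE-gas"`, `"LE"`, `"L"`,
#'   `"LC"`, `"S"`, `"unstable/artifact"`.
#' @export
#' @examples
#' classify_phase(c(30, 150, 250, 250.1))
classify_phase <- function(modulus) {
  if (!is.numeric(modulus) || any(!is.finite(modulus))) {
    stop("'modulus' must be finite numeric", call. = FALSE)
  }
  vapply(modulus, function(m) {
    if (m < 0) "unstable/artifact"
    else if (m < 12.5) "G/LE-gas"
    else if (m < 50) "LE"
    else if (m < 100) "L"
    else if (m <= 250) "LC"
    else "S"
  }, character(1))
}

#' Extrapolated area of the first linear slope
#'
#' Fits a least-squares line `pi = a + b A` over the first (largest-area)
#' contiguous run of points whose pressure lies inside `fit_window` and
#' extrapolates it to zero pressure: `A_EXT = -a/b`.  By default the window
#' is `[0.3, 0.9]` times the plateau-onset pressure estimated by
#' [detect_transitions()]; for isotherms without a detectable transition
#' pass the window explicitly.
#'
#' @param iso An [isotherm] (noise-free or smoothed).
#' @param fit_window Numeric length-2 pressure interval (mN/m), or `NULL`
#'   for the default.
#' @param min_points Below this many in-window points a low-confidence flag
#'   is attached.
#' @param r2_warn R-squared below which the fit is flagged low-confidence.
#' @return An object of class `extrapolation_fit`: `A_EXT` (nm^2), `slope`,
#'   `intercept`, `r_squared`, `window`, `n_points`, `indices`,
#'   `low_confidence`.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
#' extrapolated_area(iso)$A_EXT
extrapolated_area <- function(iso, fit_window = NULL, min_points = 5,
                              r2_warn = 0.98) {
  stopifnot(inherits(iso, "isotherm"))
  if (is.null(fit_window)) {
    tr <- detect_transitions(iso)
    if (is.na(tr$pi_C)) {
      stop("no plateau-onset estimate available; supply 'fit_window' explicitly",
           call. = FALSE)
    }
    fit_window <- c(0.3, 0.9) * tr$pi_C
  }
  stopifnot(length(fit_window) == 2L, fit_window[1] < fit_window[2])
  if (max(iso$pressure) < fit_window[2]) {
    stop("isotherm does not reach the upper bound of 'fit_window'",
         call. = FALSE)
  }
  inw <- iso$pressure >= fit_window[1] & iso$pressure <= fit_window[2]
  if (!any(inw)) stop("no points inside 'fit_window'", call. = FALSE)
  # first contiguous run in compression order (largest areas first)
  r <- rle(inw)
  first <- which(r$values)[1]
  start <- if (first == 1L) 1L else sum(r$lengths[1:(first - 1L)]) + 1L
  idx <- start:(start + r$lengths[first] - 1L)
  if (length(idx) < 2L) stop("fewer than 2 points in 'fit_window'", call. = FALSE)
  fit <- lm(p ~ a, data = data.frame(a = iso$area[idx], p = iso$pressure[idx]))
  b <- coef(fit)[["a"]]; a0 <- coef(fit)[["(Intercept)"]]
  if (!is.finite(b) || b >= 0) {
    stop("non-negative slope in the fit window: not a compression branch",
         call. = FALSE)
  }
  ss_tot <- sum((iso$pressure[idx] - mean(iso$pressure[idx]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  low <- length(idx) < min_points || r2 < r2_warn
  if (low) {
    warning(sprintf("low-confidence A_EXT fit (n = %d, R^2 = %.4f)",
                    length(idx), r2), call. = FALSE)
  }
  structure(list(A_EXT = -a0 / b, slope = b, intercept = a0, r_squared = r2,
                 window = fit_window, n_points = length(idx), indices = idx,
                 low_confidence = low),
            class = "extrapolation_fit")
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf("A_EXT = %.4f nm^2 (slope %.1f mN/m/nm^2, R^2 = %.5f, n = %d%s)\n",
              x$A_EXT, x$slope, x$r_squared, x$n_points,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Detect the LE--LC transition from the compression-modulus curve
#'
#' Locates the two principal maxima of `Cs^-1(pi)` (the LE and LC branches)
#' and the coexistence minimum between them, then reads off the entry and
#' exit pressures of the low-modulus coexistence interval.  The interval is
#' bounded by the `coexistence_threshold` (50 mN/m, the upper Davies-Rideal
#' LE bound); when a branch maximum itself stays below the threshold the
#' effective bound falls back to the midpoint between the plateau floor and
#' that maximum, so the entry/exit points remain defined.  The reported
#' entry pressure is the plateau onset: `pi_C` (and `A_C`, the area there).
#' For a tilted plateau the entry and exit pressures are also reported as
#' `pi_prime_C` and `pi_dprime_C`; when the plateau is nearly horizontal
#' (exit - entry < `plateau_tol`) only the single `(A_C, pi_C)` pair is
#' reported.
#'
#' @param iso An [isotherm] (noise-free or smoothed).
#' @param curve Optional precomputed [compression_modulus()] curve.
#' @param coexistence_threshold Coexistence modulus bound, mN/m.
#' @param pressure_floor Minimum pressure (mN/m) for the coexistence
#'   minimum, excluding the trivial low-modulus region near lift-off.
#' @param prominence Minimum height (mN/m) of both branch maxima above the
#'   coexistence minimum.
#' @param plateau_tol Entry/exit separation (mN/m) below which the plateau
#'   is reported as a single point.
#' @return A `transition_report` with fields `A_C`, `pi_C`, `pi_prime_C`,
#'   `pi_dprime_C`, `pi_entry`, `pi_exit`, `max_modulus_LE`,
#'   `max_modulus_LC`, `has_transition`; transition fields are `NA` when no
#'   interior coexistence minimum exists.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
#' detect_transitions(iso)
detect_transitions <- function(iso, curve = NULL, coexistence_threshold = 50,
                               pressure_floor = 2, prominence = 5,
                               plateau_tol = 0.5) {
  stopifnot(inherits(iso, "isotherm"))
  if (is.null(curve)) curve <- compression_modulus(iso)
  stopifnot(inherits(curve, "modulus_curve"))
  C <- curve$modulus; p <- curve$pressure; A <- curve$area
  n <- length(C)
  empty <- structure(list(A_C = NA_real_, pi_C = NA_real_,
                          pi_prime_C = NA_real_, pi_dprime_C = NA_real_,
                          pi_entry = NA_real_, pi_exit = NA_real_,
                          max_modulus_LE = NA_real_, max_modulus_LC = NA_real_,
                          has_transition = FALSE, curve = curve,
                          label = curve$label),
                     class = "transition_report")
  if (n < 5L) return(empty)
  # interior local minima of C below the coexistence threshold
  interior <- 2:(n - 1)
  is_min <- C[interior] <= C[interior - 1] & C[interior] <= C[interior + 1]
  cand <- interior[is_min]
  cand <- cand[p[cand] > pressure_floor & C[cand] < coexistence_threshold]
  if (!length(cand)) return(empty)
  imin <- cand[which.min(C[cand])]
  iLE <- which.max(C[1:(imin - 1)])
  iLC <- imin + which.max(C[(imin + 1):n])
  if (C[iLE] - C[imin] < prominence || C[iLC] - C[imin] < prominence) {
    return(empty)
  }
  thr_left <- min(coexistence_threshold, (C[imin] + C[iLE]) / 2)
  thr_right <- min(coexistence_threshold, (C[imin] + C[iLC]) / 2)
  # walk outward from the coexistence minimum to the first sample at or
  # above the effective threshold; the sample just inside it bounds the
  # low-modulus interval
  j <- imin
  while (j > iLE && C[j - 1] < thr_left) j <- j - 1
  k <- imin
  while (k < iLC && C[k + 1] < thr_right) k <- k + 1
  pi_entry <- p[j]; pi_exit <- p[k]
  single <- (pi_exit - pi_entry) < plateau_tol
  structure(list(A_C = A[j], pi_C = pi_entry,
                 pi_prime_C = if (single) NA_real_ else pi_entry,
                 pi_dprime_C = if (single) NA_real_ else pi_exit,
                 pi_entry = pi_entry, pi_exit = pi_exit,
                 max_modulus_LE = C[iLE], max_modulus_LC = C[iLC],
                 has_transition = TRUE, curve = curve, label = curve$label),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("LE-LC transition report '%s'\n", x$label))
  if (!x$has_transition) {
    cat("  no coexistence region detected\n")
    return(invisible(x))
  }
  cat(sprintf("  plateau onset: A_C = %.3f nm^2 at pi_C = %.2f mN/m\n",
              x$A_C, x$pi_C))
  if (!is.na(x$pi_prime_C)) {
    cat(sprintf("  tilted plateau: pi'_C = %.2f, pi''_C = %.2f mN/m\n",
                x$pi_prime_C, x$pi_dprime_C))
  } else {
    cat(sprintf("  near-horizontal plateau (entry %.2f, exit %.2f mN/m)\n",
                x$pi_entry, x$pi_exit))
  }
  cat(sprintf("  branch maxima: Cs^-1(LE) = %.1f, Cs^-1(LC) = %.1f mN/m\n",
              x$max_modulus_LE, x$max_modulus_LC))
  invisible(x)
}

#' Monolayer phase at a given surface pressure
#'
#' Interpolates the compression modulus stored in a transition report at
#' the requested pressures and applies the Davies--Rideal classification.
#'
#' @param report A `transition_report` from [detect_transitions()].
#' @param pressure Surface pressures, mN/m.
#' @return Character vector of phase labels.
#' @export
phase_at <- function(report, pressure) {
  stopifnot(inherits(report, "transition_report"))
  cv <- report$curve
  m <- approx(cv$pressure, cv$modulus, xout = pressure, ties = mean)$y
  if (any(is.na(m))) {
    stop("pressure outside the range of the modulus curve", call. = FALSE)
  }
  classify_phase(m)
}

#' Area shift between two isotherms at a common pressure
#'
#' `isotherm_shift(a, b, pressure)` returns `A_a(pi) - A_b(pi)` by inverse
#' linear interpolation of each isotherm on its monotone rising branch.
#' Pressures falling on a coexistence plateau (where the inverse is
#' ill-conditioned) raise an error naming the plateau bounds.
#'
#' @param a,b [isotherm] objects.
#' @param pressure Surface pressure, mN/m.
#' @param max_inverse_slope Plateau guard: |dA/dpi| (nm^2 per mN/m) above
#'   which the local inverse is treated as multi-valued.
#' @return Area difference, nm^2.
#' @export
isotherm_shift <- function(a, b, pressure, max_inverse_slope = 0.1) {
  stopifnot(inherits(a, "isotherm"), inherits(b, "isotherm"))
  check_number(pressure, "pressure", lower = 0, closed_lower = FALSE)
  area_at(a, pressure, max_inverse_slope) - area_at(b, pressure, max_inverse_slope)
}

# inverse interpolation A(pi) on the compression branch, guarding against
# the multi-valued plateau region
area_at <- function(iso, target, max_inverse_slope = 0.1) {
  p <- iso$pressure; A <- iso$area; n <- length(p)
  if (target <= min(p) || target > max(p)) {
    stop(sprintf("pressure %g mN/m outside the rising range of isotherm '%s'",
                 target, iso$label), call. = FALSE)
  }
  j <- max(which(p <= target))
  if (j >= n) j <- n - 1L
  inv_slope <- function(i) {
    dp <- p[i + 1] - p[i]
    if (dp <= 0) Inf else (A[i] - A[i + 1]) / dp
  }
  if (inv_slope(j) > max_inverse_slope) {
    lo <- j; hi <- j
    while (lo > 1L && inv_slope(lo - 1L) > max_inverse_slope) lo <- lo - 1L
    while (hi < n - 1L && inv_slope(hi + 1L) > max_inverse_slope) hi <- hi + 1L
    stop(sprintf(
      "pressure %g mN/m falls on the coexistence plateau of isotherm '%s' (%.2f-%.2f mN/m)",
      target, iso$label, p[lo], p[hi + 1L]), call. = FALSE)
  }
  A[j] + (A[j + 1] - A[j]) * (target - p[j]) / (p[j + 1] - p[j])
}
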