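# Penetration kinetics: differential surface pressure between penetration
# and reference troughs, and adsorption summaries.

#' Surface pressure kinetics trace
#'
#' Time series of surface pressure at fixed barrier position, recorded
#' after injection of a penetrant into the subphase (`role =
#' "penetration"`) or on a simultaneous injection-free trough (`role =
#' "reference"`).  Time zero is the injection instant; samples before it
#' should be trimmed, and the trace must start within 1 min of it.
#'
#' @param time Time since injection, min; strictly increasing.
#' @param pressure Surface pressure, mN/m.
#' @param role `"penetration"` or `"reference"`.
#' @param label Nanoparticle (penetrant) label.
#' @param concentration Subphase penetrant concentration, ug/mL.
#' @return An object of class `kinetics_trace`.
#' @export
kinetics_trace <- function(time, pressure, role = c("penetration", "reference"),
                           label = "", concentration = NA_real_) {
  role <- match.arg(role)
  stopifnot(is.numeric(time), is.numeric(pressure))
  if (length(time) != length(pressure)) {
    stop("'time' and 'pressure' must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing", call. = FALSE)
  if (time[1] > 1) {
    stop("trace must start within 1 min of the injection time zero", call. = FALSE)
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 role = role, label = as.character(label),
                 concentration = concentration),
            class = "kinetics_trace")
}

#' @export
print.kinetics_trace <- function(x, ...) {
  cat(sprintf("Kinetics trace (%s) '%s': %d samples over %.0f min\n",
              x$role, x$label, length(x$time), max(x$time) - min(x$time)))
  invisible(x)
}

#' @export
as.data.frame.kinetics_trace <- function(x, ...) {
  data.frame(time_min = x$time, pressure_mN_m = x$pressure)
}

#' Write / read a kinetics trace (CSV + YAML sidecar)
#'
#' @param trace A [kinetics_trace].
#' @param path CSV path (columns `time_min`, `pressure_mN_m`); role, label
#'   and concentration go to the YAML sidecar.
#' @param params Optional generator parameters recorded as ground truth.
#' @return The CSV path (write) or a [kinetics_trace] (read).
#' @export
write_kinetics_trace <- function(trace, path, params = NULL) {
  stopifnot(inherits(trace, "kinetics_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  meta <- list(role = trace$role, label = trace$label,
               concentration = trace$concentration)
  if (!is.null(params)) meta$ground_truth <- unclass(params)
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_kinetics_trace
#' @param role Trace role; defaults to the sidecar value.
#' @export
read_kinetics_trace <- function(path, role = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  d <- utils::read.csv(path)
  r <- role %||% meta$role
  if (is.null(r)) stop("trace role not given and absent from the sidecar",
                       call. = FALSE)
  kinetics_trace(d$time_min, d$pressure_mN_m, role = r,
                 label = meta$label %||% "",
                 concentration = meta$concentration %||% NA_real_)
}

#' Differential surface pressure between penetration and reference troughs
#'
#' `dpi(t) = pi_PE(t) - pi_R(t)` on the intersection of the two time
#' spans: both traces are linearly interpolated onto the union of their
#' sample times inside the overlap (no extrapolation).  Because both
#' troughs run simultaneously, common drifts (evaporation, ambient
#' fluctuations) cancel in the difference.
#'
#' @param pe Penetration [kinetics_trace].
#' @param ref Reference [kinetics_trace].
#' @param min_overlap Required overlap, as a fraction of the shorter trace.
#' @return A `delta_pi_series`: data.frame with columns `time` (min) and
#'   `delta_pi` (mN/m), with the penetrant label and concentration as
#'   attributes.
#' @export
#' @examples
#' pair <- generate_penetration_pair(nanoparticle_penetration_params("Fe3O4-S"))
#' dp <- delta_pi(pair$penetration, pair$reference)
#' head(dp)
delta_pi <- function(pe, ref, min_overlap = 0.8) {
  stopifnot(inherits(pe, "kinetics_trace"), inherits(ref, "kinetics_trace"))
  if (pe$role != "penetration" || ref$role != "reference") {
    stop(sprintf("role mismatch: got (%s, %s), expected (penetration, reference)",
                 pe$role, ref$role), call. = FALSE)
  }
  lo <- max(min(pe$time), min(ref$time))
  hi <- min(max(pe$time), max(ref$time))
  shorter <- min(diff(range(pe$time)), diff(range(ref$time)))
  if (hi <= lo || (hi - lo) < min_overlap * shorter) {
    stop(sprintf(
      "time spans overlap over %.0f%% of the shorter trace; need at least %.0f%%",
      100 * max(0, hi - lo) / shorter, 100 * min_overlap), call. = FALSE)
  }
  grid <- sort(unique(c(pe$time, ref$time)))
  grid <- grid[grid >= lo & grid <= hi]
  pe_i <- approx(pe$time, pe$pressure, xout = grid)$y
  ref_i <- approx(ref$time, ref$pressure, xout = grid)$y
  structure(data.frame(time = grid, delta_pi = pe_i - ref_i),
            label = pe$label, concentration = pe$concentration,
            class = c("delta_pi_series", "data.frame"))
}

#' Summarise an adsorption kinetics series
#'
#' Reports the 6 h endpoint (linear interpolation at t = 360 min when
#' covered, otherwise the last sample with a short-span flag) and fits the
#' exponential-saturation model `dpi(t) = dpi_max (1 - exp(-k t))` by
#' bounded nonlinear least squares ([minpack.lm::nlsLM()]), initialised
#' from the final value and the time to half-final.  A positive endpoint
#' indicates adsorption of the penetrant into the monolayer; a series
#' trending below zero indicates extraction of phospholipid from the
#' interface and is summarised by its minimum instead of a saturation fit.
#' The saturation fit is a derived convenience summary: endpoint values are
#' the primary readout.
#'
#' @param dp A `delta_pi_series` from [delta_pi()] (or a data.frame with
#'   `time`/`delta_pi` columns) spanning at least 60 min.
#' @param t_end Endpoint time, min (default 360 = 6 h).
#' @return A `penetration_result`: `delta_pi_at_end`, `t_end`,
#'   `short_span`, `regime` (`"adsorption"`, `"extraction"` or
#'   `"degenerate"`), `delta_pi_max`, `k_ads`, `fit_residual_sd` (fit
#'   fields `NA` when not applicable or not converged, with a
#'   `fit_diagnostic` message), and for the extraction regime `min_value` /
#'   `min_time`.
#' @export
adsorption_summary <- function(dp, t_end = 360) {
  stopifnot(is.data.frame(dp), all(c("time", "delta_pi") %in% names(dp)))
  t <- dp$time; y <- dp$delta_pi
  if (diff(range(t)) < 60) {
    stop("kinetics series must span at least 60 min", call. = FALSE)
  }
  short <- max(t) < t_end
  end_val <- if (short) y[length(y)] else approx(t, y, xout = t_end)$y
  final <- mean(y[t >= quantile(t, 0.9)])
  res <- list(delta_pi_at_end = end_val, t_end = if (short) max(t) else t_end,
              short_span = short, delta_pi_max = NA_real_, k_ads = NA_real_,
              fit_residual_sd = NA_real_, fit_diagnostic = NA_character_,
              min_value = NA_real_, min_time = NA_real_,
              label = attr(dp, "label") %||% "")
  if (final < 0) {
    res$regime <- "extraction"
    res$min_value <- min(y)
    res$min_time <- t[which.min(y)]
    res$fit_diagnostic <- "negative trend: extraction regime, no saturation fit"
  } else if (sd(y) < 1e-12 || abs(final) < 1e-12) {
    res$regime <- "degenerate"
    res$fit_diagnostic <- "flat series: saturation fit degenerate"
  } else {
    res$regime <- "adsorption"
    t_half <- approx(cummax(y) + seq_along(y) * 1e-12, t, xout = final / 2)$y
    k0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1 / max(t)
    fit <- tryCatch(
      minpack.lm::nlsLM(delta_pi ~ dmax * (1 - exp(-k * time)),
                        data = data.frame(time = t, delta_pi = y),
                        start = list(dmax = max(final, 1e-6), k = k0),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      res$fit_diagnostic <- paste("saturation fit failed:", fit)
    } else {
      cf <- coef(fit)
      res$delta_pi_max <- unname(cf["dmax"])
      res$k_ads <- unname(cf["k"])
      res$fit_residual_sd <- sqrt(sum(stats::residuals(fit)^2) /
                                    max(length(y) - 2L, 1L))
    }
  }
  structure(res, class = "penetration_result")
}

#' @export
print.penetration_result <- function(x, ...) {
  cat(sprintf("Penetration summary '%s' (%s regime)\n", x$label, x$regime))
  cat(sprintf("  dpi at %g min = %.3f mN/m%s\n", x$t_end, x$delta_pi_at_end,
              if (x$short_span) " [short span: last sample]" else ""))
  if (!is.na(x$delta_pi_max)) {
    cat(sprintf("  saturation fit: dpi_max = %.3f mN/m, k_ads = %.4g /min (residual sd %.3g)\n",
                x$delta_pi_max, x$k_ads, x$fit_residual_sd))
  } else if (!is.na(x$fit_diagnostic)) {
    cat("  ", x$fit_diagnostic, "\n", sep = "")
  }
  if (x$regime == "extraction") {
    cat(sprintf("  minimum %.3f mN/m at %g min\n", x$min_value, x$min_time))
  }
  invisible(x)
}
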