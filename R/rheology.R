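# Dilatational viscoelasticity from oscillating-barrier traces:
# fixed-frequency harmonic regression and frequency sweeps.

#' Oscillating-barrier trace
#'
#' Time series of available area and surface pressure recorded while the
#' barriers oscillate sinusoidally at a known frequency.  Sampling must be
#' uniform (at least 8 samples per cycle) and cover at least 3 full cycles;
#' rest intervals between oscillation bursts appear as gaps in the time
#' grid and are handled by [viscoelastic_moduli()].
#'
#' @param time Time, s.
#' @param area Available area (absolute or relative units).
#' @param pressure Surface pressure, mN/m.
#' @param frequency Barrier frequency, Hz (from the instrument protocol).
#' @param label,X_W Film metadata.
#' @param baseline_pressure Baseline surface pressure, mN/m.
#' @return An object of class `oscillation_trace`.
#' @export
oscillation_trace <- function(time, area, pressure, frequency, label = "",
                              X_W = NA_real_, baseline_pressure = NA_real_) {
  stopifnot(is.numeric(time), is.numeric(area), is.numeric(pressure))
  n <- length(time)
  if (length(area) != n || length(pressure) != n) {
    stop("'time', 'area' and 'pressure' must have equal length", call. = FALSE)
  }
  check_number(frequency, "frequency", lower = 0, closed_lower = FALSE)
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing", call. = FALSE)
  dt <- diff(time)
  step <- median(dt)
  regular <- dt[dt < 5 * step]
  if (any(abs(regular - step) > 1e-6 * step + 1e-9)) {
    stop("non-uniform sampling within an oscillation burst", call. = FALSE)
  }
  if (1 / step < 8 * frequency) {
    stop("fewer than 8 samples per oscillation cycle", call. = FALSE)
  }
  if ((time[n] - time[1]) < 3 / frequency) {
    stop("trace must cover at least 3 full oscillation cycles", call. = FALSE)
  }
  structure(list(time = as.numeric(time), area = as.numeric(area),
                 pressure = as.numeric(pressure), frequency = frequency,
                 label = as.character(label), X_W = X_W,
                 baseline_pressure = baseline_pressure),
            class = "oscillation_trace")
}

#' @export
print.oscillation_trace <- function(x, ...) {
  cat(sprintf("Oscillation trace '%s': f = %g Hz, %d samples over %.1f s\n",
              x$label, x$frequency, length(x$time),
              x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

#' @export
as.data.frame.oscillation_trace <- function(x, ...) {
  data.frame(time_s = x$time, area = x$area, pressure_mN_m = x$pressure)
}

#' Write / read an oscillation trace (CSV + YAML sidecar)
#'
#' The CSV carries columns `time_s`, `area`, `pressure_mN_m`; the sidecar
#' records frequency, label, weight fraction and baseline pressure.
#'
#' @param trace An [oscillation_trace].
#' @param path CSV path.
#' @param params Optional generator parameters recorded as ground truth.
#' @return The CSV path (write) or an [oscillation_trace] (read).
#' @export
write_oscillation_trace <- function(trace, path, params = NULL) {
  stopifnot(inherits(trace, "oscillation_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  meta <- list(frequency = trace$frequency, label = trace$label,
               X_W = trace$X_W, baseline_pressure = trace$baseline_pressure)
  if (!is.null(params)) meta$ground_truth <- unclass(params)
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_oscillation_trace
#' @param frequency Barrier frequency (Hz); defaults to the sidecar value.
#' @export
read_oscillation_trace <- function(path, frequency = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  d <- utils::read.csv(path)
  freq <- frequency %||% meta$frequency
  if (is.null(freq)) {
    stop("oscillation frequency not given and absent from the sidecar",
         call. = FALSE)
  }
  oscillation_trace(d$time_s, d$area, d$pressure_mN_m, frequency = freq,
                    label = meta$label %||% "", X_W = meta$X_W %||% NA_real_,
                    baseline_pressure = meta$baseline_pressure %||% NA_real_)
}

#' Least-squares harmonic fit at a known frequency
#'
#' Fits `y(t) = m + a sin(2 pi f t) + b cos(2 pi f t)` by ordinary least
#' squares.  Demodulation at the known barrier frequency is robust to
#' non-integer cycle counts and short records, unlike an FFT bin readout.
#'
#' @param time Time, s.
#' @param y Signal samples.
#' @param frequency Frequency f, Hz.
#' @return List with `mean`, `a_sin`, `b_cos`, `residual_sd`.
#' @export
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' fit_harmonic(t, 5 + 2 * sin(2 * pi * 0.1 * t), 0.1)
fit_harmonic <- function(time, y, frequency) {
  stopifnot(is.numeric(time), is.numeric(y), length(time) == length(y))
  check_number(frequency, "frequency", lower = 0, closed_lower = FALSE)
  span <- max(time) - min(time)
  if (span < 1 / frequency) {
    stop("record spans less than one oscillation period: rank-deficient design",
         call. = FALSE)
  }
  if (span < 3 / frequency) {
    warning("record spans fewer than 3 oscillation cycles; estimates may be poor",
            call. = FALSE)
  }
  wt <- 2 * pi * frequency * time
  X <- cbind(1, sin(wt), cos(wt))
  fit <- lm.fit(X, y)
  dof <- max(length(y) - 3L, 1L)
  list(mean = unname(fit$coefficients[1]),
       a_sin = unname(fit$coefficients[2]),
       b_cos = unname(fit$coefficients[3]),
       residual_sd = sqrt(sum(fit$residuals^2) / dof))
}

#' Complex dilatational viscoelastic modulus from a trace
#'
#' Demodulates the relative area signal `x(t) = (A - mean(A)) / mean(A)` and
#' the pressure signal at the known barrier frequency and forms the complex
#' modulus from the defining relation `dpi = -E dA / A`: with harmonic
#' phasors `z = a_sin + i b_cos`, `E = -z_pi / z_x`, so an ideally elastic
#' film (pressure exactly in antiphase with area) has phase 0 and
#' `E'' = 0`, while a purely viscous film has phase pi/2.
#'
#' Rest intervals between oscillation bursts (gaps larger than
#' `burst_gap_factor` sampling steps) split the trace; each burst is fitted
#' separately and moduli are averaged across bursts (sd reported when more
#' than one).  The first cycle of each burst is discarded as a mechanical
#' transient whenever at least 3 full cycles remain.
#'
#' @param trace An [oscillation_trace].
#' @param discard_first_cycle Drop the first cycle of each burst.
#' @param burst_gap_factor Time-step multiple treated as a burst gap.
#' @param refine_frequency Refine the nominal frequency within +/- 5
#'   percent by minimising the residual sd (golden-section search via
#'   [stats::optimize()]).
#' @return A `viscoelastic_result`: `E_prime`, `E_dprime`, `E_modulus`,
#'   `phase` (radians, in (-pi, pi]), `u` (relative area amplitude),
#'   `frequency`, `residual_sd`, `n_bursts`, `E_sd` (across bursts, `NA`
#'   for a single burst).
#' @export
#' @examples
#' tr <- generate_oscillation_trace(oscillation_params(E_prime = 60, E_dprime = 10))
#' viscoelastic_moduli(tr)
viscoelastic_moduli <- function(trace, discard_first_cycle = TRUE,
                                burst_gap_factor = 5, refine_frequency = FALSE) {
  stopifnot(inherits(trace, "oscillation_trace"))
  f <- trace$frequency
  if (refine_frequency) {
    obj <- function(fr) {
      fit_harmonic(trace$time, trace$pressure, fr)$residual_sd
    }
    f <- optimize(obj, interval = f * c(0.95, 1.05))$minimum
  }
  dt <- diff(trace$time)
  gaps <- which(dt > burst_gap_factor * median(dt))
  bounds <- c(0L, gaps, length(trace$time))
  results <- list()
  for (bi in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[bi] + 1L):bounds[bi + 1L]
    t <- trace$time[idx]
    if (discard_first_cycle && (max(t) - min(t)) >= 4 / f) {
      keep <- t >= min(t) + 1 / f
      idx <- idx[keep]; t <- t[keep]
    }
    if ((max(t) - min(t)) < 3 / f) next
    abar <- mean(trace$area[idx])
    x <- trace$area[idx] / abar - 1
    fx <- fit_harmonic(t, x, f)
    fp <- fit_harmonic(t, trace$pressure[idx], f)
    u <- Mod(complex(real = fx$a_sin, imaginary = fx$b_cos))
    if (u < 1e-4) {
      stop("no resolvable area forcing (relative amplitude below 1e-4)",
           call. = FALSE)
    }
    E <- -complex(real = fp$a_sin, imaginary = fp$b_cos) /
      complex(real = fx$a_sin, imaginary = fx$b_cos)
    results[[length(results) + 1L]] <-
      list(E = E, u = u, residual_sd = fp$residual_sd)
  }
  if (!length(results)) {
    stop("no burst with at least 3 full cycles available for fitting",
         call. = FALSE)
  }
  Es <- vapply(results, `[[`, complex(1), "E")
  E <- mean(Es)
  phase <- wrap_angle(Arg(E))
  if (abs(phase) > pi / 2 + 1e-9) {
    warning("phase lag beyond pi/2: non-physical response, check the sign convention or frequency",
            call. = FALSE)
  }
  structure(list(E_prime = Re(E), E_dprime = Im(E), E_modulus = Mod(E),
                 phase = phase,
                 u = mean(vapply(results, `[[`, numeric(1), "u")),
                 frequency = f,
                 residual_sd = mean(vapply(results, `[[`, numeric(1), "residual_sd")),
                 n_bursts = length(results),
                 E_sd = if (length(results) > 1) sd(Mod(Es)) else NA_real_,
                 label = trace$label, X_W = trace$X_W),
            class = "viscoelastic_result")
}

#' @export
print.viscoelastic_result <- function(x, ...) {
  cat(sprintf(
    "Dilatational modulus at f = %g Hz: E' = %.2f, E'' = %.2f mN/m (|E| = %.2f, phase = %.3f rad)\n",
    x$frequency, x$E_prime, x$E_dprime, x$E_modulus, x$phase))
  cat(sprintf("  u = %.4f, residual sd = %.4f mN/m, %d burst(s)\n",
              x$u, x$residual_sd, x$n_bursts))
  invisible(x)
}

#' Assemble a frequency sweep table from oscillation traces
#'
#' Applies [viscoelastic_moduli()] to each trace and collects one row per
#' (composition, frequency); per-trace failures are recorded in the
#' `status` column rather than aborting the sweep.  Duplicate
#' (label, frequency) pairs are retained with a replicate index.
#'
#' @param traces List of [oscillation_trace] objects.
#' @param ... Passed on to [viscoelastic_moduli()].
#' @return A data.frame sorted by `X_W` then `frequency` with columns
#'   `label`, `X_W`, `frequency`, `E_prime`, `E_dprime`, `E_modulus`,
#'   `phase`, `u`, `residual_sd`, `replicate`, `status`.
#' @export
frequency_sweep <- function(traces, ...) {
  if (!length(traces)) stop("empty list of traces", call. = FALSE)
  stopifnot(all(vapply(traces, inherits, logical(1), "oscillation_trace")))
  rows <- lapply(traces, function(tr) {
    res <- tryCatch(viscoelastic_moduli(tr, ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(label = tr$label, X_W = tr$X_W, frequency = tr$frequency,
                 E_prime = NA_real_, E_dprime = NA_real_,
                 E_modulus = NA_real_, phase = NA_real_, u = NA_real_,
                 residual_sd = NA_real_, status = res,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = tr$label, X_W = tr$X_W, frequency = tr$frequency,
                 E_prime = res$E_prime, E_dprime = res$E_dprime,
                 E_modulus = res$E_modulus, phase = res$phase, u = res$u,
                 residual_sd = res$residual_sd, status = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$X_W, out$frequency, method = "radix"), , drop = FALSE]
  key <- paste(out$label, out$frequency)
  out$replicate <- as.integer(stats::ave(seq_along(key), key, FUN = seq_along))
  rownames(out) <- NULL
  out
}
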