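# Owens-Wendt surface free energy from contact-angle drop measurements.

#' Set of contact-angle drop measurements
#'
#' @param angles Named list: one numeric vector of drop angles (degrees,
#'   open interval (0, 180)) per probe liquid.
#' @param label Solid-surface label.
#' @return An object of class `contact_angle_set`.
#' @export
contact_angle_set <- function(angles, label = "") {
  if (!is.list(angles) || is.null(names(angles)) || any(names(angles) == "")) {
    stop("'angles' must be a named list with one vector per liquid",
         call. = FALSE)
  }
  for (nm in names(angles)) {
    a <- angles[[nm]]
    if (!is.numeric(a) || !length(a)) {
      stop(sprintf("empty or non-numeric angle group for liquid '%s'", nm),
           call. = FALSE)
    }
    if (any(!is.finite(a)) || any(a <= 0 | a >= 180)) {
      stop(sprintf("angles for liquid '%s' must lie in (0, 180) degrees", nm),
           call. = FALSE)
    }
  }
  structure(list(angles = lapply(angles, as.numeric),
                 label = as.character(label)),
            class = "contact_angle_set")
}

#' @export
print.contact_angle_set <- function(x, ...) {
  cat(sprintf("Contact angles on '%s':\n", x$label))
  for (nm in names(x$angles)) {
    a <- x$angles[[nm]]
    cat(sprintf("  %-15s n = %2d, mean %.1f deg (sd %.2f)\n", nm, length(a),
                mean(a), if (length(a) > 1) sd(a) else 0))
  }
  invisible(x)
}

#' Read contact angles from a CSV of drop measurements
#'
#' Expects columns `liquid` and `angle_deg` (one row per drop).
#'
#' @param path CSV path.
#' @param label Solid label; defaults to the YAML sidecar entry.
#' @return A [contact_angle_set].
#' @export
read_contact_angles <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("liquid", "angle_deg") %in% names(d))) {
    stop("expected columns 'liquid' and 'angle_deg' in ", path, call. = FALSE)
  }
  contact_angle_set(split(d$angle_deg, d$liquid),
                    label = label %||% meta$label %||% "")
}

#' Write contact angles as a CSV of drop measurements
#'
#' @param set A [contact_angle_set].
#' @param path CSV path; the solid label goes to the YAML sidecar.
#' @param params Optional generator ground truth for the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_contact_angles <- function(set, path, params = NULL) {
  stopifnot(inherits(set, "contact_angle_set"))
  d <- data.frame(
    liquid = rep(names(set$angles), lengths(set$angles)),
    angle_deg = unlist(set$angles, use.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- list(label = set$label)
  if (!is.null(params)) meta$ground_truth <- unclass(params)
  write_sidecar(path, meta)
  invisible(path)
}

#' Aggregate contact-angle drops per liquid
#'
#' Arithmetic mean and sample standard deviation per probe liquid.  Groups
#' with fewer than 10 drops are flagged as below the measurement protocol
#' (which averages at least 10) but are not rejected; fewer than 2 drops is
#' an error.
#'
#' @param set A [contact_angle_set].
#' @return A data.frame with columns `liquid`, `mean`, `sd`, `n`,
#'   `below_protocol`.
#' @export
#' @examples
#' aggregate_angles(generate_contact_angles(starch_surface(), seed = 7))
aggregate_angles <- function(set) {
  stopifnot(inherits(set, "contact_angle_set"))
  bad <- names(set$angles)[lengths(set$angles) < 2L]
  if (length(bad)) {
    stop(sprintf("need at least 2 drops per liquid (got %d for '%s')",
                 length(set$angles[[bad[1]]]), bad[1]), call. = FALSE)
  }
  data.frame(
    liquid = names(set$angles),
    mean = vapply(set$angles, mean, numeric(1)),
    sd = vapply(set$angles, sd, numeric(1)),
    n = lengths(set$angles),
    below_protocol = lengths(set$angles) < 10L,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Core linearised Owens-Wendt solve: gamma_L (1 + cos theta) / 2 =
# x sqrt(gamma_L^d) + y sqrt(gamma_L^p) with x = sqrt(gamma_d),
# y = sqrt(gamma_p).  Exact for two liquids, least squares for more.
ow_solve_core <- function(mean_angles_deg, liquids) {
  M <- cbind(sqrt(liquids$gamma_d), sqrt(liquids$gamma_p))
  rhs <- liquids$gamma_total * (1 + cos(mean_angles_deg * pi / 180)) / 2
  # purely dispersive (or purely polar) liquid sets: the corresponding solid
  # component is unidentifiable and fixed at zero, reducing the system
  nz <- colSums(M^2) > 0
  Msub <- M[, nz, drop = FALSE]
  qrM <- qr(Msub)
  if (qrM$rank < ncol(Msub)) {
    stop(sprintf(
      "singular Owens-Wendt system: liquids %s are dispersively proportional",
      paste(sQuote(liquids$name), collapse = ", ")), call. = FALSE)
  }
  xy <- numeric(2)
  xy[nz] <- qr.coef(qrM, rhs)
  # roots at numerical zero are not infeasibility, just an exactly apolar
  # (or exactly dispersion-free) surface
  clamped <- any(xy < -1e-6)
  xy <- pmax(xy, 0)
  list(gamma_d = xy[1]^2, gamma_p = xy[2]^2, infeasible = clamped)
}

#' Solve the Owens--Wendt system for the solid surface energy components
#'
#' Linearises the Owens--Wendt geometric-mean relation
#' `gamma_L (1 + cos theta) = 2 sqrt(gamma_d gamma_L^d) + 2 sqrt(gamma_p
#' gamma_L^p)` in the square roots of the solid components, solves exactly
#' for two probe liquids (least squares for more) and squares the roots.
#' Negative roots -- an infeasible geometry, usually from measurement noise
#' -- are clamped to zero and flagged rather than erroring, so batch runs
#' complete.  Total energy is `gamma_s = gamma_d + gamma_p` exactly.
#'
#' @param mean_angles Named numeric vector of per-liquid mean contact
#'   angles, degrees; names must match `liquids$name`.
#' @param liquids Probe-liquid table (at least two rows; see
#'   [probe_liquids()]).
#' @param label Solid label.
#' @return A `surface_energy_result` with `gamma_d`, `gamma_p`, `gamma_s`
#'   (mJ/m^2) and an `infeasible` flag; uncertainty fields are `NA` (use
#'   [surface_energy()] for bootstrap uncertainties).
#' @export
#' @examples
#' th <- young_angle(starch_surface())
#' owens_wendt_solve(th)
owens_wendt_solve <- function(mean_angles, liquids = default_probe_liquids(),
                              label = "") {
  if (is.null(names(mean_angles))) {
    stop("'mean_angles' must be a named vector (one entry per liquid)",
         call. = FALSE)
  }
  if (nrow(liquids) < 2L) {
    stop("need at least two probe liquids to separate the components",
         call. = FALSE)
  }
  missing <- setdiff(liquids$name, names(mean_angles))
  if (length(missing)) {
    stop("no mean angle supplied for liquid ", sQuote(missing[1]), call. = FALSE)
  }
  sol <- ow_solve_core(mean_angles[liquids$name], liquids)
  if (sol$infeasible) {
    warning("negative root clamped to zero: infeasible angle geometry",
            call. = FALSE)
  }
  structure(list(gamma_d = sol$gamma_d, gamma_p = sol$gamma_p,
                 gamma_s = sol$gamma_d + sol$gamma_p,
                 sd_d = NA_real_, sd_p = NA_real_, sd_s = NA_real_,
                 infeasible = sol$infeasible, label = label,
                 per_liquid = data.frame(liquid = liquids$name,
                                         mean = unname(mean_angles[liquids$name]),
                                         sd = NA_real_, n = NA_integer_)),
            class = "surface_energy_result")
}

#' Surface free energy with bootstrap uncertainties from raw drops
#'
#' Aggregates a drop-angle set, solves the Owens--Wendt system on the
#' per-liquid means and attaches uncertainties from a seeded parametric
#' bootstrap: drops are resampled with replacement within each liquid and
#' the solve repeated.  Bootstrapping is used instead of first-order error
#' propagation because the square of a near-zero root is non-Gaussian.
#'
#' @param set A [contact_angle_set].
#' @param liquids Probe-liquid table.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return A `surface_energy_result` with component standard deviations and
#'   the per-liquid angle summary.
#' @export
#' @examples
#' set <- generate_contact_angles(starch_surface(), noise_deg = 1, seed = 3)
#' surface_energy(set)
surface_energy <- function(set, liquids = default_probe_liquids(),
                           n_boot = 2000, seed = 1L) {
  stopifnot(inherits(set, "contact_angle_set"))
  n_boot <- check_count(n_boot, "n_boot", lower = 0L)
  agg <- aggregate_angles(set)
  means <- setNames(agg$mean, agg$liquid)
  res <- owens_wendt_solve(means, liquids, label = set$label)
  res$per_liquid <- agg
  if (n_boot > 0) {
    groups <- set$angles[liquids$name]
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        m <- vapply(groups, function(a) mean(sample(a, replace = TRUE)),
                    numeric(1))
        s <- ow_solve_core(m, liquids)
        c(s$gamma_d, s$gamma_p)
      }, numeric(2))
    })
    res$sd_d <- sd(boot[1, ])
    res$sd_p <- sd(boot[2, ])
    res$sd_s <- sd(boot[1, ] + boot[2, ])
  }
  res
}

#' @export
print.surface_energy_result <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.1f", v) else
    sprintf("%.1f +/- %.1f", v, s)
  cat(sprintf("Owens-Wendt surface energy '%s' (mJ/m^2)\n", x$label))
  cat(sprintf("  gamma_s = %s (dispersive %s, polar %s)%s\n",
              fmt(x$gamma_s, x$sd_s), fmt(x$gamma_d, x$sd_d),
              fmt(x$gamma_p, x$sd_p),
              if (x$infeasible) "  [clamped: infeasible root]" else ""))
  if (!all(is.na(x$per_liquid$n))) {
    for (i in seq_len(nrow(x$per_liquid))) {
      r <- x$per_liquid[i, ]
      cat(sprintf("  %-15s %.1f deg (sd %.2f, n = %d)\n",
                  r$liquid, r$mean, r$sd, r$n))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.surface_energy_result <- function(x, ...) {
  data.frame(label = x$label, gamma_s = x$gamma_s, gamma_d = x$gamma_d,
             gamma_p = x$gamma_p, sd_s = x$sd_s, sd_d = x$sd_d,
             sd_p = x$sd_p, infeasible = x$infeasible)
}
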