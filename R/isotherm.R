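# The isotherm container, trough-export I/O, per-molecule normalisation and
# smoothing.

#' Surface pressure--area isotherm
#'
#' Container for a compression isotherm: mean molecular area per
#' phospholipid molecule (nm^2) against surface pressure (mN/m).  Points
#' are stored in compression order (strictly decreasing area).  Small
#' negative pressures (>= -0.5 mN/m) are tolerated as Wilhelmy-plate sensor
#' noise.
#'
#' @param area Mean molecular area, nm^2 per molecule.
#' @param pressure Surface pressure, mN/m.
#' @param label Film label.
#' @param X_W Nanoparticle weight fraction of the spread mixture.
#' @param temperature Subphase temperature, degC.
#' @param average_duplicates Average pressures recorded at identical areas
#'   instead of erroring.
#' @return An object of class `isotherm`.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_params(), noise_sd = 0)
#' iso
isotherm <- function(area, pressure, label = "", X_W = NA_real_,
                     temperature = NA_real_, average_duplicates = FALSE) {
  if (!is.numeric(area) || !is.numeric(pressure)) {
    stop("'area' and 'pressure' must be numeric", call. = FALSE)
  }
  if (length(area) != length(pressure)) {
    stop("'area' and 'pressure' must have the same length", call. = FALSE)
  }
  keep <- is.finite(area) & is.finite(pressure)
  if (!all(keep)) stop("non-finite values in isotherm data", call. = FALSE)
  ord <- order(area, decreasing = TRUE)
  area <- area[ord]; pressure <- pressure[ord]
  if (anyDuplicated(area)) {
    if (!average_duplicates) {
      stop("duplicated area values; set average_duplicates = TRUE to average them",
           call. = FALSE)
    }
    ua <- sort(unique(area), decreasing = TRUE)
    pressure <- vapply(ua, function(a) mean(pressure[area == a]), numeric(1))
    area <- ua
  }
  if (length(area) < 10L) {
    stop("an isotherm needs at least 10 points", call. = FALSE)
  }
  if (any(pressure < -0.5)) {
    stop("surface pressure below -0.5 mN/m: not a valid isotherm", call. = FALSE)
  }
  structure(list(area = as.numeric(area), pressure = as.numeric(pressure),
                 label = as.character(label), X_W = X_W,
                 temperature = temperature),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("pi-A isotherm '%s' (%d points)\n", x$label, length(x$area)))
  if (!is.na(x$X_W)) cat(sprintf("  X_W = %g\n", x$X_W))
  cat(sprintf("  area %.3f -> %.3f nm^2, pressure %.2f -> %.2f mN/m\n",
              x$area[1], x$area[length(x$area)],
              x$pressure[1], x$pressure[length(x$pressure)]))
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_nm2 = x$area, pressure_mN_m = x$pressure)
}

#' @export
length.isotherm <- function(x) length(x$area)

#' Read an isotherm from a delimited trough export
#'
#' Reads a two-column delimited text file (area in nm^2 per molecule,
#' surface pressure in mN/m).  Columns are mapped by header name when a
#' header is present (any names containing "area" and "pi"/"press"),
#' otherwise the first two columns are used.  Rows are returned in
#' compression order (decreasing area); duplicated areas are averaged.
#'
#' @param path File path.
#' @param label,X_W,temperature Metadata attached to the isotherm; when a
#'   YAML sidecar `<path stem>.yaml` exists its `label`, `X_W` and
#'   `temperature` entries are used as defaults.
#' @param sep Field separator.
#' @return An [isotherm] object.
#' @export
read_isotherm <- function(path, label = NULL, X_W = NULL, temperature = NULL,
                          sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read_sidecar(path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  raw <- utils::read.csv(path, header = has_header, sep = sep,
                         stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  if (ncol(raw) < 2L) stop("expected at least two columns in ", path, call. = FALSE)
  nm <- tolower(names(raw))
  a_col <- grep("area", nm)[1]
  p_col <- grep("press|(^|_)pi($|_)", nm)[1]
  if (is.na(a_col) || is.na(p_col)) { a_col <- 1L; p_col <- 2L }
  area <- suppressWarnings(as.numeric(raw[[a_col]]))
  pressure <- suppressWarnings(as.numeric(raw[[p_col]]))
  bad <- which(is.na(area) | is.na(pressure))
  if (length(bad)) {
    stop(sprintf("non-numeric value at line %d of %s",
                 bad[1] + as.integer(has_header), path), call. = FALSE)
  }
  isotherm(area, pressure,
           label = label %||% meta$label %||% "",
           X_W = X_W %||% meta$X_W %||% NA_real_,
           temperature = temperature %||% meta$temperature %||% NA_real_,
           average_duplicates = TRUE)
}

#' Write an isotherm as CSV with a YAML metadata sidecar
#'
#' @param iso An [isotherm].
#' @param path Output CSV path; metadata (and generator ground truth, if
#'   supplied) go to `<path stem>.yaml`.
#' @param params Optional generator parameter set recorded in the sidecar.
#' @return The CSV path, invisibly.
#' @export
write_isotherm <- function(iso, path, params = NULL) {
  stopifnot(inherits(iso, "isotherm"))
  utils::write.csv(as.data.frame(iso), path, row.names = FALSE, quote = FALSE)
  meta <- list(label = iso$label, X_W = iso$X_W, temperature = iso$temperature)
  if (!is.null(params)) meta$ground_truth <- unclass(params)
  write_sidecar(path, meta)
  invisible(path)
}

#' Mean molecular area per phospholipid molecule
#'
#' Converts the available trough area into the area per spread
#' phospholipid molecule.  For nanoparticle/phospholipid mixtures only the
#' phospholipid mass `(1 - X_W)` of the deposit enters the molecule count;
#' the nanoparticle mass is excluded.
#'
#' @param trough_area_cm2 Available trough area, cm^2.
#' @param deposited_volume_uL Deposited mixture volume, microlitres.
#' @param concentration_mg_mL Total mixture concentration, mg/mL.
#' @param X_W Nanoparticle weight fraction of the mixture, in [0, 1).
#' @param molar_mass_g_mol Phospholipid molar mass, g/mol (default DPPC,
#'   734.04).
#' @return Mean molecular area in nm^2 per molecule.
#' @export
#' @examples
#' # 30 uL of a 1 mM DPPC solution on the 273 cm^2 trough
#' mean_molecular_area(273, 30, 0.73404, X_W = 0)
mean_molecular_area <- function(trough_area_cm2, deposited_volume_uL,
                                concentration_mg_mL, X_W = 0,
                                molar_mass_g_mol = 734.04) {
  check_number(trough_area_cm2, "trough_area_cm2", lower = 0, closed_lower = FALSE)
  check_number(deposited_volume_uL, "deposited_volume_uL", lower = 0,
               closed_lower = FALSE)
  check_number(concentration_mg_mL, "concentration_mg_mL", lower = 0,
               closed_lower = FALSE)
  check_number(molar_mass_g_mol, "molar_mass_g_mol", lower = 0,
               closed_lower = FALSE)
  if (!is.numeric(X_W) || length(X_W) != 1L || !is.finite(X_W) ||
      X_W < 0 || X_W >= 1) {
    stop("X_W must lie in [0, 1): X_W >= 1 leaves no phospholipid to count",
         call. = FALSE)
  }
  avogadro <- 6.02214076e23
  mass_g <- deposited_volume_uL * concentration_mg_mL * 1e-6 * (1 - X_W)
  n_molecules <- mass_g / molar_mass_g_mol * avogadro
  trough_area_cm2 * 1e14 / n_molecules   # 1 cm^2 = 1e14 nm^2
}

#' Savitzky--Golay-type smoothing of an isotherm
#'
#' Local polynomial least-squares smoothing of the pressure channel over
#' the area grid.  Unlike a classical convolution filter the fit uses the
#' actual abscissae, so irregular area grids are handled exactly; at the
#' endpoints the window is truncated by shifting it inward (the standard
#' Savitzky--Golay edge treatment).  The area grid is unchanged.
#'
#' @param iso An [isotherm].
#' @param window Odd window length in points; must be at least
#'   `polyorder + 2` and smaller than the series length.
#' @param polyorder Local polynomial order.
#' @return A smoothed [isotherm].
#' @export
smooth_isotherm <- function(iso, window = 11, polyorder = 2) {
  stopifnot(inherits(iso, "isotherm"))
  window <- check_count(window, "window", lower = 3L)
  polyorder <- check_count(polyorder, "polyorder", lower = 0L)
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  if (window < polyorder + 2L) {
    stop("'window' must be at least polyorder + 2", call. = FALSE)
  }
  n <- length(iso$area)
  if (window >= n) stop("'window' must be smaller than the series length",
                        call. = FALSE)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- i - h; hi <- i + h
    if (lo < 1L) { lo <- 1L; hi <- window }
    if (hi > n) { hi <- n; lo <- n - window + 1L }
    x <- iso$area[lo:hi] - iso$area[i]
    X <- outer(x, 0:polyorder, `^`)
    out[i] <- lm.fit(X, iso$pressure[lo:hi])$coefficients[1]
  }
  res <- iso
  res$pressure <- pmax(out, -0.5)   # keep the validity bound
  res
}
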