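# Workbench front end: configuration-driven pipeline runs and the
# calibrated synthetic reproduction scenario.

workbench_subcommands <- c("simulate", "isotherm", "rheology", "penetration",
                           "energy", "reproduce-paper")

#' Run a workbench pipeline stage
#'
#' Configuration-driven front end binding the pipeline stages into
#' reproducible runs.  Each run writes its artifacts (CSV tables with YAML
#' sidecars), the resolved configuration and a log file into `out_dir`, so
#' a run can be repeated exactly from its output directory; with fixed
#' seeds the CSV artifacts are byte-identical across re-runs.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{Generate the synthetic datasets of the calibrated
#'     scenario (isotherms for pure DPPC and the two binary films,
#'     oscillation traces, penetration pairs, contact angles).}
#'   \item{isotherm}{Smooth the configured isotherm files, compute
#'     compression-modulus curves, transition reports and extrapolated
#'     areas; write a per-film summary table.}
#'   \item{rheology}{Fit all configured oscillation traces and write the
#'     frequency-sweep table.}
#'   \item{penetration}{Difference the configured penetration/reference
#'     pair and write the dpi series plus the adsorption summary.}
#'   \item{energy}{Aggregate a drop-angle CSV and write the Owens-Wendt
#'     component table.}
#'   \item{reproduce-paper}{Run the full synthetic scenario and write the
#'     recovered-versus-target summary (see [reproduce_scenario()]).}
#' }
#'
#' @param subcommand One of `"simulate"`, `"isotherm"`, `"rheology"`,
#'   `"penetration"`, `"energy"`, `"reproduce-paper"`.
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.  Stage parameters live under a key named after the subcommand;
#'   `out_dir` and `seed` may also be given in the config.
#' @param out_dir Output directory (overrides the config; default
#'   `"workbench-out"`).
#' @param seed Integer seed for every stochastic step (overrides the
#'   config).
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' out <- run_workbench("simulate", out_dir = tempfile(), seed = 1)
#' }
run_workbench <- function(subcommand, config = NULL, out_dir = NULL,
                          seed = NULL) {
  if (length(subcommand) != 1L || !subcommand %in% workbench_subcommands) {
    stop("unknown subcommand ", sQuote(subcommand[1]), "; expected one of ",
         paste(sQuote(workbench_subcommands), collapse = ", "), call. = FALSE)
  }
  cfg_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) stop("empty configuration file", call. = FALSE)
  }
  config <- config %||% list()
  if (!is.list(config)) stop("invalid configuration: expected a mapping", call. = FALSE)
  out_dir <- out_dir %||% config$out_dir %||% "workbench-out"
  seed <- seed %||% config$seed %||% 1L
  check_number(seed, "seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_cfg <- config[[sub("-", "_", subcommand)]] %||% list()

  artifacts <- switch(
    subcommand,
    "simulate" = wb_simulate(stage_cfg, out_dir, seed),
    "isotherm" = wb_isotherm(stage_cfg, out_dir),
    "rheology" = wb_rheology(stage_cfg, out_dir),
    "penetration" = wb_penetration(stage_cfg, out_dir),
    "energy" = wb_energy(stage_cfg, out_dir, seed),
    "reproduce-paper" = {
      tab <- reproduce_scenario(seed = seed)
      path <- file.path(out_dir, "reproduction-summary.csv")
      utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
      list(summary = path)
    })

  resolved <- list(subcommand = subcommand, out_dir = out_dir, seed = seed,
                   config = config)
  yaml::write_yaml(resolved, file.path(out_dir, "run-config.yaml"))
  log_lines <- c(
    sprintf("langmuirkit %s", as.character(utils::packageVersion("langmuirkit"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("seed: %s", format(seed)),
    sprintf("config md5: %s", cfg_hash),
    sprintf("artifacts: %s", paste(basename(unlist(artifacts)), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(artifacts)
}

wb_simulate <- function(cfg, out_dir, seed) {
  noise <- cfg$isotherm_noise_sd %||% 0.05
  n_points <- cfg$n_points %||% 400
  params <- list(dppc = isotherm_params(),
                 fe3o4_s = binary_film_params("Fe3O4-S"),
                 fe3o4_as = binary_film_params("Fe3O4-AS"))
  arts <- list()
  for (nm in names(params)) {
    iso <- generate_isotherm(params[[nm]], n_points = n_points,
                             noise_sd = noise, seed = seed)
    path <- file.path(out_dir, paste0("isotherm-", nm, ".csv"))
    write_isotherm(iso, path, params = params[[nm]])
    arts[[paste0("isotherm_", nm)]] <- path
  }
  moduli <- default_film_moduli()
  freqs <- cfg$frequencies %||% c(0.02, 0.08, 0.14)
  k <- 0L
  for (i in seq_len(nrow(moduli))) {
    for (f in freqs) {
      k <- k + 1L
      op <- oscillation_params(E_prime = moduli$E_prime[i],
                               E_dprime = moduli$E_dprime[i], frequency = f,
                               noise_sd = cfg$oscillation_noise_sd %||% 0.05,
                               seed = seed + k)
      tr <- generate_oscillation_trace(op, label = moduli$label[i],
                                       X_W = moduli$X_W[i])
      path <- file.path(out_dir, sprintf("oscillation-%02d.csv", k))
      write_oscillation_trace(tr, path, params = op)
      arts[[sprintf("oscillation_%02d", k)]] <- path
    }
  }
  for (coating in c("Fe3O4-S", "Fe3O4-AS")) {
    pp <- nanoparticle_penetration_params(
      coating, noise_sd = cfg$penetration_noise_sd %||% 0.1, seed = seed)
    pair <- generate_penetration_pair(pp, label = coating)
    stem <- tolower(gsub("[^A-Za-z0-9]+", "_", coating))
    for (role in names(pair)) {
      path <- file.path(out_dir, sprintf("penetration-%s-%s.csv", stem, role))
      write_kinetics_trace(pair[[role]], path, params = pp)
      arts[[sprintf("penetration_%s_%s", stem, role)]] <- path
    }
  }
  solids <- list(starch_surface(), aminated_starch_surface())
  for (s in solids) {
    set <- generate_contact_angles(s, n_drops = cfg$n_drops %||% 10,
                                   noise_deg = cfg$angle_noise_deg %||% 1,
                                   seed = seed)
    stem <- gsub("[^A-Za-z0-9]+", "_", s$label)
    path <- file.path(out_dir, sprintf("contact-angles-%s.csv", stem))
    write_contact_angles(set, path, params = s)
    arts[[sprintf("angles_%s", stem)]] <- path
  }
  arts
}

wb_isotherm <- function(cfg, out_dir) {
  files <- cfg$files
  if (is.null(files)) stop("isotherm stage needs a 'files' list in the config",
                           call. = FALSE)
  missing <- files[!file.exists(unlist(files))]
  if (length(missing)) stop("input file not found: ", missing[[1]], call. = FALSE)
  rows <- list()
  for (f in files) {
    iso <- read_isotherm(f)
    sm <- smooth_isotherm(iso, window = cfg$smooth_window %||% 11,
                          polyorder = cfg$smooth_polyorder %||% 2)
    tr <- detect_transitions(sm)
    ext <- tryCatch(extrapolated_area(sm, fit_window = cfg$fit_window),
                    error = function(e) NULL, warning = function(w) {
                      suppressWarnings(extrapolated_area(sm, fit_window = cfg$fit_window))
                    })
    rows[[length(rows) + 1L]] <- data.frame(
      label = iso$label, X_W = iso$X_W,
      A_EXT = if (is.null(ext)) NA_real_ else ext$A_EXT,
      A_C = tr$A_C, pi_C = tr$pi_C,
      pi_prime_C = tr$pi_prime_C, pi_dprime_C = tr$pi_dprime_C,
      max_modulus_LE = tr$max_modulus_LE, max_modulus_LC = tr$max_modulus_LC)
  }
  tab <- do.call(rbind, rows)
  path <- file.path(out_dir, "isotherm-summary.csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  list(summary = path)
}

wb_rheology <- function(cfg, out_dir) {
  files <- cfg$files
  if (is.null(files)) stop("rheology stage needs a 'files' list in the config",
                           call. = FALSE)
  traces <- lapply(files, read_oscillation_trace)
  sweep <- frequency_sweep(traces)
  path <- file.path(out_dir, "frequency-sweep.csv")
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  list(sweep = path)
}

wb_penetration <- function(cfg, out_dir) {
  if (is.null(cfg$penetration_file) || is.null(cfg$reference_file)) {
    stop("penetration stage needs 'penetration_file' and 'reference_file'",
         call. = FALSE)
  }
  pe <- read_kinetics_trace(cfg$penetration_file)
  ref <- read_kinetics_trace(cfg$reference_file)
  dp <- delta_pi(pe, ref)
  summ <- adsorption_summary(dp, t_end = cfg$t_end %||% 360)
  dp_path <- file.path(out_dir, "delta-pi.csv")
  utils::write.csv(dp, dp_path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(summ)[c("delta_pi_at_end", "t_end", "regime",
                                   "delta_pi_max", "k_ads", "fit_residual_sd",
                                   "label")],
                   file.path(out_dir, "penetration-summary.yaml"))
  list(delta_pi = dp_path,
       summary = file.path(out_dir, "penetration-summary.yaml"))
}

wb_energy <- function(cfg, out_dir, seed) {
  if (is.null(cfg$angles_file)) {
    stop("energy stage needs an 'angles_file' entry", call. = FALSE)
  }
  set <- read_contact_angles(cfg$angles_file)
  liquids <- if (!is.null(cfg$liquids)) {
    do.call(probe_liquids, cfg$liquids)
  } else default_probe_liquids()
  res <- surface_energy(set, liquids, n_boot = cfg$n_boot %||% 2000,
                        seed = seed)
  path <- file.path(out_dir, "surface-energy.csv")
  utils::write.csv(as.data.frame(res), path, row.names = FALSE, quote = FALSE)
  list(energy = path)
}

#' Run the calibrated synthetic scenario and compare recovered values
#'
#' Exercises the full analysis chain on the calibrated noise-free
#' synthetic scenario and tabulates the recovered quantities against their
#' calibration targets: plateau-onset area and pressure of the pure DPPC
#' isotherm, transition-onset pressures and extrapolated-area increases of
#' the two binary films at X_W = 0.36, the 6 h differential-pressure
#' endpoints of the two penetration scenarios, and the Owens--Wendt
#' components recovered by a noise-free angle roundtrip for both polymer
#' coatings.
#'
#' @param seed Seed forwarded to every stochastic step (the scenario itself
#'   is noise-free; the seed only matters for optional noisy extensions).
#' @param n_points Isotherm grid size.
#' @return A data.frame with columns `quantity`, `unit`, `target`,
#'   `recovered`.
#' @export
#' @examples
#' \donttest{
#' reproduce_scenario()
#' }
reproduce_scenario <- function(seed = 1L, n_points = 400) {
  dppc <- generate_isotherm(isotherm_params(), n_points = n_points,
                            noise_sd = 0, seed = seed)
  iso_s <- generate_isotherm(binary_film_params("Fe3O4-S"), n_points = n_points,
                             noise_sd = 0, seed = seed)
  iso_as <- generate_isotherm(binary_film_params("Fe3O4-AS"), n_points = n_points,
                              noise_sd = 0, seed = seed)
  tr_dppc <- detect_transitions(dppc)
  tr_s <- detect_transitions(iso_s)
  tr_as <- detect_transitions(iso_as)
  aext <- function(iso, tr) extrapolated_area(iso, fit_window = c(0.3, 0.9) * tr$pi_C)$A_EXT
  d_aext_s <- aext(iso_s, tr_s) - aext(dppc, tr_dppc)
  d_aext_as <- aext(iso_as, tr_as) - aext(dppc, tr_dppc)

  dpi_end <- function(coating) {
    pair <- generate_penetration_pair(
      nanoparticle_penetration_params(coating, noise_sd = 0, seed = seed),
      label = coating)
    dp <- delta_pi(pair$penetration, pair$reference)
    approx(dp$time, dp$delta_pi, xout = 360)$y
  }

  ow <- function(solid) {
    set <- generate_contact_angles(solid, noise_deg = 0, seed = seed)
    surface_energy(set, n_boot = 0)
  }
  ow_s <- ow(starch_surface()); ow_as <- ow(aminated_starch_surface())

  data.frame(
    quantity = c("DPPC plateau onset area A_C",
                 "DPPC plateau onset pressure pi_C",
                 "Fe3O4-S/DPPC (X_W=0.36) transition onset pressure",
                 "Fe3O4-AS/DPPC (X_W=0.36) transition onset pressure",
                 "Fe3O4-S/DPPC A_EXT increase",
                 "Fe3O4-AS/DPPC A_EXT increase",
                 "Fe3O4-AS dpi after 6 h",
                 "Fe3O4-S dpi after 6 h",
                 "starch gamma_s", "starch gamma_d", "starch gamma_p",
                 "aminated starch gamma_s", "aminated starch gamma_d",
                 "aminated starch gamma_p"),
    unit = c("nm^2", "mN/m", "mN/m", "mN/m", "nm^2", "nm^2", "mN/m", "mN/m",
             rep("mJ/m^2", 6)),
    target = c(0.77, 5.0, 12, 10, 0.19, 0.14, 7.1, 4.2,
               34.4, 28.8, 5.6, 44.1, 26.1, 18.0),
    recovered = c(tr_dppc$A_C, tr_dppc$pi_C, tr_s$pi_C, tr_as$pi_C,
                  d_aext_s, d_aext_as,
                  dpi_end("Fe3O4-AS"), dpi_end("Fe3O4-S"),
                  ow_s$gamma_s, ow_s$gamma_d, ow_s$gamma_p,
                  ow_as$gamma_s, ow_as$gamma_d, ow_as$gamma_p))
}
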