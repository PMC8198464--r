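# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar numeric check with an interval constraint
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (closed_lower) "[" else "(", lower, upper,
                 if (closed_upper) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# Seeds are always explicit arguments; no function touches global RNG state
# without going through here.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(sidecar_path(path))
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) yaml::read_yaml(sc) else list()
}
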