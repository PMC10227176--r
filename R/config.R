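#' Simulation configuration
#'
#' Assembles, validates, and defaults every parameter of a sweep run. The
#' defaults are the published study conditions: for the deterministic model,
#' patches of 50 cells, 10,000 seeds per plant, `g = 0.3`, `c1 = 1e-4`, a
#' 5000-cell window, inter-patch distances swept 0 to 5000 by 1; for the
#' stochastic model, the same demography with `mu = 0.001`, 1000 generations
#' per level, founding size 20 mm, and inter-patch distances swept 5 to 1000
#' by 5. One cell corresponds to 1 m.
#'
#' Presets load the parameterizations of the headline figure panels:
#' `"fig3a"` (deterministic, `d05 = 60`, `d30 = 700`), `"fig3b"`
#' (deterministic, `d05 = 30`, `d30 = 300`), `"fig4a"` (stochastic,
#' `d05 = 120`, `d30 = 700`), `"fig4b"` (stochastic, `d05 = 90`,
#' `d30 = 300`). Named arguments override preset values.
#'
#' @param model `"deterministic"` or `"stochastic"`.
#' @param preset Optional preset name (see Details).
#' @param ... Named parameter overrides; valid keys are `d05`, `d30`,
#'   `s_min`, `s_max`, `x_h`, `x_ipd_min`, `x_max`, `ipd_step`, `d_max`,
#'   `n_tot`, `g`, `c1`, `s_init`, `step`, `mu`, `n_gens`, `mutation_step`,
#'   `n_patches`, `parent_offset`, `tol`, `refound`.
#' @param allow_out_of_range If `TRUE`, range violations become warnings
#'   instead of errors (for exploration outside the study's parameter table).
#' @return A validated list of class `run_config`.
#' @examples
#' cfg <- run_config("deterministic", d05 = 60, d30 = 700, x_max = 200,
#'                   ipd_step = 10, d_max = 500)
#' @export
run_config <- function(model = c("deterministic", "stochastic"),
                       preset = NULL, ..., allow_out_of_range = FALSE) {
  overrides <- rlang::list2(...)
  if (!is.null(preset)) {
    pr <- config_presets[[preset]]
    if (is.null(pr))
      abort(paste0("unknown preset; available: ",
                   paste(names(config_presets), collapse = ", ")))
    model <- pr$model
    overrides <- utils::modifyList(pr$values, overrides)
  } else {
    model <- match.arg(model)
  }
  cfg <- config_defaults(model)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  cfg$model <- model
  validate_config(cfg, allow_out_of_range)
}

config_defaults <- function(model) {
  common <- list(
    model = model, d05 = 60, d30 = 700, s_min = 0.5, s_max = 30,
    x_h = 50L, n_tot = 10000, g = 0.3, c1 = 1e-4,
    parent_offset = 0L, tol = NULL, allow_out_of_range = FALSE
  )
  if (model == "deterministic") {
    c(common, list(x_ipd_min = 0L, x_max = 5000L, ipd_step = 1L,
                   d_max = 5000L, s_init = 0.5, step = 0.01,
                   mu = NA_real_, n_gens = NA_integer_,
                   mutation_step = NA_real_, n_patches = NA_integer_,
                   refound = FALSE))
  } else {
    c(common, list(x_ipd_min = 5L, x_max = 1000L, ipd_step = 5L,
                   d_max = NA_integer_, s_init = 20, step = NA_real_,
                   mu = 0.001, n_gens = 1000L, mutation_step = 1,
                   n_patches = 10L, refound = FALSE))
  }
}

config_presets <- list(
  fig3a = list(model = "deterministic", values = list(d05 = 60, d30 = 700)),
  fig3b = list(model = "deterministic", values = list(d05 = 30, d30 = 300)),
  fig4a = list(model = "stochastic", values = list(d05 = 120, d30 = 700)),
  fig4b = list(model = "stochastic", values = list(d05 = 90, d30 = 300))
)

validate_config <- function(cfg, allow_out_of_range = FALSE) {
  fail <- function(msg) {
    if (allow_out_of_range) warn(paste0(msg, " (allowed by override)"))
    else abort(paste0(msg, "; set `allow_out_of_range = TRUE` to force."))
  }
  hard <- function(cond, msg) if (!cond) abort(msg)

  hard(cfg$d05 > 0 && cfg$d30 > 0, "`d05` and `d30` must be positive.")
  hard(cfg$g >= 0 && cfg$g <= 1, "`g` must lie in [0, 1].")
  hard(cfg$c1 >= 0, "`c1` must be non-negative.")
  hard(cfg$x_h >= 1, "`x_h` must be at least 1.")
  hard(cfg$x_ipd_min >= 0 && cfg$x_max >= cfg$x_ipd_min,
       "need 0 <= x_ipd_min <= x_max.")
  hard(cfg$ipd_step >= 1, "`ipd_step` must be at least 1.")
  hard(cfg$n_tot >= 1, "`n_tot` must be at least 1.")
  hard(cfg$s_init >= cfg$s_min && cfg$s_init <= cfg$s_max,
       "`s_init` must lie within the seed-size bounds.")
  hard(cfg$parent_offset >= 0 && cfg$parent_offset < cfg$x_h,
       "`parent_offset` must lie in [0, x_h).")
  hard(seed_cost(cfg$s_init, cfg$c1) < 1,
       "`s_init` has seed cost >= 1: no seeds could be produced.")

  # soft range checks against the study's parameter table
  if (cfg$d05 < 20 || cfg$d05 > 300)
    fail("`d05` outside the studied range [20, 300] cells")
  if (cfg$d30 < 50 || cfg$d30 > 750)
    fail("`d30` outside the studied range [50, 750] cells")
  if (cfg$d30 <= cfg$d05)
    fail("`d30` <= `d05`: larger seeds would not disperse farther")

  if (cfg$model == "deterministic") {
    hard(cfg$d_max >= 1, "`d_max` must be at least 1.")
    hard(cfg$step > 0, "`step` must be positive.")
  } else {
    hard(cfg$mu >= 0 && cfg$mu <= 1, "`mu` must lie in [0, 1].")
    hard(cfg$n_gens >= 1, "`n_gens` must be at least 1.")
    hard(cfg$n_patches >= 1, "`n_patches` must be at least 1.")
    hard(cfg$mutation_step > 0, "`mutation_step` must be positive.")
  }
  structure(cfg, class = "run_config")
}

#' Modify an existing configuration
#'
#' @param config A [run_config()].
#' @param ... Named overrides (same keys as [run_config()]).
#' @return A revalidated `run_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  overrides <- rlang::list2(...)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad))
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  cfg <- unclass(config)
  cfg[names(overrides)] <- overrides
  validate_config(cfg, isTRUE(cfg$allow_out_of_range))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("hydrodisp run config (%s model)\n", x$model))
  keys <- setdiff(names(x), "model")
  for (k in keys) {
    v <- x[[k]]
    if (length(v) == 0 || (length(v) == 1 && is.na(v)) || is.null(v)) next
    cat(sprintf("  %-14s %s\n", k, format(v)))
  }
  invisible(x)
}

#' Read / write a configuration file
#'
#' Configurations serialize to YAML and round-trip losslessly.
#'
#' @param path File path.
#' @return `read_run_config()` returns a validated [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model)) abort("config file lacks a `model` key.")
  cfg <- config_defaults(raw$model)
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    abort(paste0("unknown config key(s) in file: ", paste(bad, collapse = ", ")))
  for (k in names(raw)) if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  validate_config(cfg, isTRUE(cfg$allow_out_of_range))
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, function(v) is.null(v) || all(is.na(v)), logical(1))]
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Write sweep results to disk
#'
#' Writes tab-separated tables with a comment-prefixed provenance header
#' containing the full configuration (and RNG seed, if any), so any result
#' file can be regenerated from its own header. Files: `sweep.tsv` (one row
#' per level and direction) and, when a hysteresis summary is supplied,
#' `hysteresis.tsv`.
#'
#' @param curves A `disp_sweep` tibble.
#' @param dir Output directory (created if absent).
#' @param hysteresis Optional `hysteresis_summary`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(curves, dir, hysteresis = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  config <- attr(curves, "config")
  seed <- attr(curves, "seed")
  header <- c("# hydrodisp sweep results",
              paste0("# config.", config_header_lines(config)))
  if (!is.null(seed)) header <- c(header, paste0("# rng_seed: ", seed))
  paths <- file.path(dir, "sweep.tsv")
  writeLines(header, paths[1])
  readr::write_tsv(as_tibble(curves), paths[1], append = TRUE, col_names = TRUE)
  if (!is.null(hysteresis)) {
    hp <- file.path(dir, "hysteresis.tsv")
    writeLines(header, hp)
    readr::write_tsv(as_tibble(unclass_summary(hysteresis)), hp,
                     append = TRUE, col_names = TRUE)
    paths <- c(paths, hp)
  }
  invisible(paths)
}

config_header_lines <- function(config) {
  if (is.null(config)) return(character(0))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, function(v) is.null(v) || all(is.na(v)), logical(1))]
  paste0(names(vals), ": ", vapply(vals, function(v) format(v, digits = 15),
                                   character(1)))
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to a `.tsv` written by [write_results()].
#' @return A tibble (header comments are skipped).
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
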