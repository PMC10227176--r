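#' Up-then-down fragmentation sweep, deterministic model
#'
#' Runs the deterministic hill climb across an increasing sequence of
#' inter-patch distances (`x_ipd = x_ipd_min, ..., x_max` by `ipd_step`),
#' seeding each level with the seed size evolved at the previous level (the
#' first level uses `s_init`), then mirrors the sweep back down from `x_max`
#' seeded with the up sweep's final size. The curves differ wherever the
#' evolved strategy depends on fragmentation history (hysteresis). All runs
#' are deterministic, so no replication is needed.
#'
#' @param config A [run_config()] with `model = "deterministic"`.
#' @return A tibble of class `disp_sweep` with one row per level:
#'   `direction` (`"up"`/`"down"`), `x_ipd`, `seed_size`, `lambda`,
#'   `median_dispersal`, `fitness`. The config is attached as attribute
#'   `config`.
#' @export
sweep_deterministic <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$model != "deterministic")
    abort("`sweep_deterministic()` needs a deterministic config.")
  kernel <- dispersal_kernel(config$d05, config$d30, config$s_min, config$s_max)
  params <- det_params(config$n_tot, config$g, config$c1, config$d_max,
                       config$step)
  levels_up <- seq(config$x_ipd_min, config$x_max, by = config$ipd_step)

  run_direction <- function(levels, s_start, direction) {
    s <- s_start
    rows <- vector("list", length(levels))
    for (i in seq_along(levels)) {
      ls <- landscape(config$x_h, levels[i], mode = "bounded",
                      d_max = config$d_max, phase = config$parent_offset)
      opt <- optimize_seed_size(s, ls, kernel, params)
      s <- opt$s_star
      rows[[i]] <- tibble(direction = direction, x_ipd = levels[i],
                          seed_size = opt$s_star, lambda = opt$lambda,
                          median_dispersal = opt$median_dispersal,
                          fitness = opt$fitness)
    }
    list(rows = dplyr::bind_rows(rows), s_final = s)
  }

  up <- run_direction(levels_up, config$s_init, "up")
  down <- run_direction(rev(levels_up), up$s_final, "down")
  out <- dplyr::bind_rows(up$rows, down$rows)
  attr(out, "config") <- config
  class(out) <- c("disp_sweep", class(out))
  out
}

#' Up-then-down fragmentation sweep, stochastic individual-based model
#'
#' The sweep starts with every habitable cell occupied at `s_init` mm and the
#' smallest inter-patch distance; the population then runs `n_gens`
#' generations per level while `x_ipd` steps up to `x_max` and back down. The
#' population carries over across levels (occupants keep their
#' patch-relative position as the matrix widens or narrows); it is never
#' reseeded. If the population goes extinct, remaining levels are recorded as
#' extinct, unless `config$refound` is `TRUE`, in which case the next level
#' starts again from a full population at `s_init`.
#'
#' @param config A [run_config()] with `model = "stochastic"`.
#' @param seed Optional RNG seed (`set.seed()`) for a reproducible
#'   trajectory.
#' @return A tibble of class `disp_sweep`: `direction`, `x_ipd`,
#'   `generations_run`, `pop_size`, `seed_size` (population median, mm),
#'   `median_dispersal`, `extinct`. Attributes `config` and `seed`.
#' @export
sweep_stochastic <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$model != "stochastic")
    abort("`sweep_stochastic()` needs a stochastic config.")
  if (!is.null(seed)) set.seed(seed)
  kernel <- dispersal_kernel(config$d05, config$d30, config$s_min, config$s_max)
  params <- stoch_params(config$n_tot, config$g, config$c1, config$mu,
                         config$n_gens, config$s_init, config$mutation_step,
                         config$s_min, config$s_max)
  levels_up <- seq(config$x_ipd_min, config$x_max, by = config$ipd_step)
  levels <- c(levels_up, rev(levels_up))
  direction <- rep(c("up", "down"), each = length(levels_up))

  ls <- landscape(config$x_h, levels[1], mode = "periodic",
                  n_patches = config$n_patches)
  pop <- init_population(ls, params$s_init)
  prev_ls <- ls
  rows <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    ls <- landscape(config$x_h, levels[i], mode = "periodic",
                    n_patches = config$n_patches)
    if (length(pop$cells) == 0L && config$refound) {
      pop <- init_population(ls, params$s_init)
    } else if (length(pop$cells) > 0L && ls$x_ipd != prev_ls$x_ipd) {
      # carry occupants over by habitable-cell rank (patch-relative position)
      rank <- habitable_rank(prev_ls, pop$cells)
      pop <- population(habitable_cells(ls)[rank + 1L], pop$sizes,
                        pop$generation)
    }
    if (length(pop$cells) == 0L) {
      rows[[i]] <- tibble(direction = direction[i], x_ipd = levels[i],
                          generations_run = 0L, pop_size = 0L,
                          seed_size = NA_real_, median_dispersal = NA_real_,
                          extinct = TRUE)
    } else {
      res <- run_level(pop, ls, kernel, params)
      pop <- res$pop
      rows[[i]] <- tibble(direction = direction[i],
                          x_ipd = levels[i],
                          generations_run = res$summary$generations_run,
                          pop_size = res$summary$pop_size,
                          seed_size = res$summary$median_size,
                          median_dispersal = res$summary$median_dispersal,
                          extinct = res$summary$extinct)
    }
    prev_ls <- ls
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("disp_sweep", class(out))
  out
}

#' Detect a hysteresis zone from an up/down sweep pair
#'
#' Operationalizes the collapse/recovery transitions as 50% crossings of the
#' up sweep's running maximum: the collapse point (`up_transition`) is the
#' first `x_ipd`, in sweep order, at which the up curve's evolved median
#' dispersal distance falls to half (or less) of its running maximum; the
#' recovery point (`down_transition`) is the first `x_ipd`, in down-sweep
#' order, at which the down curve climbs back above half of the up curve's
#' pre-collapse maximum. The hysteresis zone is the inter-patch-distance
#' range between recovery and collapse; if the down sweep never recovers the
#' zone extends to the grid minimum. Whenever the two curves agree within
#' `tol` everywhere there is no hysteresis and the zone size is 0. Extinct
#' levels (stochastic sweeps) are treated as zero dispersal capacity.
#'
#' @param curves A `disp_sweep` tibble containing both directions on the same
#'   `x_ipd` grid.
#' @param tol Tolerance (cells of median dispersal distance) below which the
#'   curves are considered equal; defaults to one `x_ipd` grid step.
#' @return A one-row tibble of class `hysteresis_summary`: `up_transition`,
#'   `down_transition` (cells; `NA` if absent), `zone_size` (cells, >= 0),
#'   `max_gap` (largest |up - down| in median-distance cells).
#' @export
detect_hysteresis <- function(curves, tol = NULL) {
  up <- dplyr::arrange(dplyr::filter(curves, .data$direction == "up"), .data$x_ipd)
  down <- dplyr::arrange(dplyr::filter(curves, .data$direction == "down"), .data$x_ipd)
  if (nrow(up) == 0L || nrow(down) == 0L)
    abort("`curves` must contain both an up and a down sweep.")
  if (nrow(up) != nrow(down) || any(up$x_ipd != down$x_ipd))
    abort("up and down sweeps must share the same `x_ipd` grid.")
  if (is.null(tol)) {
    steps <- diff(up$x_ipd)
    tol <- if (length(steps)) min(steps) else 1
  }
  grid_min <- min(up$x_ipd)

  up_val <- ifelse(is.na(up$median_dispersal), 0, up$median_dispersal)
  down_val <- ifelse(is.na(down$median_dispersal), 0, down$median_dispersal)
  max_gap <- max(abs(up_val - down_val))

  out <- function(up_tr, down_tr, zone) {
    res <- tibble(up_transition = up_tr, down_transition = down_tr,
                  zone_size = zone, max_gap = max_gap, tol = tol)
    class(res) <- c("hysteresis_summary", class(res))
    res
  }
  if (max_gap <= tol) return(out(NA_real_, NA_real_, 0))

  # collapse on the up sweep: first drop to <= 50% of the running maximum
  runmax <- cummax(up_val)
  collapse_idx <- which(up_val <= 0.5 * dplyr::lag(runmax, default = -Inf))
  if (length(collapse_idx) == 0L) return(out(NA_real_, NA_real_, 0))
  ci <- collapse_idx[1L]
  up_tr <- up$x_ipd[ci]
  pre_max <- runmax[ci - 1L]

  # recovery on the down sweep (traversed in sweep order: x_ipd decreasing)
  rec_idx <- which(rev(down_val) > 0.5 * pre_max)
  down_tr <- if (length(rec_idx)) rev(down$x_ipd)[rec_idx[1L]] else NA_real_
  zone <- if (is.na(down_tr)) up_tr - grid_min else max(0, up_tr - down_tr)
  out(up_tr, down_tr, zone)
}

#' @describeIn detect_hysteresis `glance()` method (the summary is already
#'   one tidy row).
#' @param x A `hysteresis_summary`.
#' @param ... Unused.
#' @export
glance.hysteresis_summary <- function(x, ...) {
  tibble::as_tibble(unclass_summary(x))
}

unclass_summary <- function(x) {
  class(x) <- setdiff(class(x), "hysteresis_summary")
  x
}

#' Sensitivity analysis over a parameter grid
#'
#' Runs one full up/down sweep plus hysteresis detection for every
#' combination of the supplied parameter values (Cartesian product), varying
#' a base configuration. Mirrors the published sensitivity protocol over
#' patch size, seed number, survival, cost, generations per level, and
#' mutation rate.
#'
#' @param config A base [run_config()].
#' @param axes Named list of parameter value vectors; names must be
#'   [run_config()] keys.
#' @param seed Optional base RNG seed for stochastic sweeps (each combination
#'   gets `seed + i - 1`).
#' @return A long-format tibble: one row per combination with the axis
#'   columns followed by `up_transition`, `down_transition`, `zone_size`,
#'   `max_gap`.
#' @export
sensitivity_grid <- function(config, axes, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(names(axes), names(config))
  if (length(bad))
    abort(paste0("unknown config key(s) in `axes`: ", paste(bad, collapse = ", ")))
  if (is.null(names(axes)) || any(names(axes) == ""))
    abort("`axes` must be a fully named list.")
  grid <- tidyr::expand_grid(!!!axes)
  res <- purrr::imap(purrr::transpose(as.list(grid)), function(row, i) {
    cfg <- update_config(config, !!!row)
    curves <- if (cfg$model == "deterministic") {
      sweep_deterministic(cfg)
    } else {
      sweep_stochastic(cfg, seed = if (is.null(seed)) NULL else seed + as.integer(i) - 1L)
    }
    unclass_summary(detect_hysteresis(curves, tol = cfg$tol))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Plot an up/down sweep pair
#'
#' Evolved median dispersal distance against inter-patch distance, one line
#' per sweep direction. The vertical gap between the two lines marks the
#' hysteresis zone.
#'
#' @param object A `disp_sweep` tibble.
#' @param ... Unused.
#' @export
autoplot.disp_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x_ipd, y = .data$median_dispersal,
                               colour = .data$direction,
                               linetype = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Inter-patch distance (cells)",
                  y = "Evolved median dispersal distance (cells)",
                  colour = "Sweep", linetype = "Sweep")
}
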