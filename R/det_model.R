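#' Parameters of the deterministic single-plant model
#'
#' Demographic constants for the deterministic fitness model: a lone parent
#' at the upstream edge of a patch releases `n_tot` seeds, pays a
#' volume-proportional production cost, and its expected colonization success
#' over a downstream window of `d_max` cells is the fitness that seed size
#' evolves to maximize by +/- `step` mm hill climbing.
#'
#' @param n_tot Total seeds to disperse (default 10,000).
#' @param g Germination-and-survival probability in habitat cells (default
#'   0.3; always 0 in the matrix).
#' @param c1 Cost per unit seed volume (default 1e-4).
#' @param d_max Window length in cells (default 5000).
#' @param step Hill-climbing mutation step in mm (default 0.01).
#' @return An object of class `det_params`.
#' @export
det_params <- function(n_tot = 10000, g = 0.3, c1 = 1e-4, d_max = 5000,
                       step = 0.01) {
  if (n_tot < 1) abort("`n_tot` must be at least 1.")
  if (g < 0 || g > 1) abort("`g` must lie in [0, 1].")
  if (c1 < 0) abort("`c1` must be non-negative.")
  if (d_max < 1) abort("`d_max` must be at least 1.")
  structure(list(n_tot = n_tot, g = g, c1 = c1, d_max = as.integer(d_max),
                 step = step),
            class = "det_params")
}

#' Seed production cost
#'
#' Cost fraction of producing seeds of size `S`, linearly proportional to
#' seed volume (round seeds): \eqn{c = c_1 \pi S^3 / 6}. The fraction of the
#' seed budget left for dispersal is `1 - c`; contexts that multiply seed
#' numbers by `1 - c` require `c < 1` and raise otherwise.
#'
#' @param size Seed size(s) in mm (> 0).
#' @param c1 Cost per unit seed volume (>= 0).
#' @return Cost fraction(s) `c`.
#' @examples
#' seed_cost(30, 1e-4)  # 1.414; such a seed cannot be produced at this c1
#' @export
seed_cost <- function(size, c1) {
  if (any(size <= 0)) abort("`size` must be positive.")
  if (c1 < 0) abort("`c1` must be non-negative.")
  c1 * pi * size^3 / 6
}

#' Expected seeds deposited per cell
#'
#' Expected number of seeds a single parent deposits in each downstream cell
#' `d = 0, ..., d_max - 1`:
#' `n_tot * deposition_pmf(lambda(S), d_max)[d] * (1 - c)`. Counts are
#' real-valued expectations, deliberately not rounded, so that occupancy
#' probabilities vary smoothly with seed size.
#'
#' @param size Seed size in mm.
#' @param kernel A [dispersal_kernel()].
#' @param params A [det_params()].
#' @return Numeric vector of length `d_max`.
#' @export
seeds_per_cell <- function(size, kernel, params) {
  cost <- seed_cost(size, params$c1)
  if (cost >= 1)
    abort(sprintf(
      "seed cost %.4g >= 1 at size %.3g mm: seed production would be non-positive.",
      cost, size))
  lam <- lambda_of_size(kernel, size)
  params$n_tot * (1 - cost) * deposition_pmf(lam, params$d_max)
}

#' Probability that a cell becomes occupied
#'
#' With `n_d` seeds arriving in a cell and each germinating and surviving
#' independently with probability `g`, the cell ends up occupied (by exactly
#' one plant; all later seeds are outcompeted) with probability
#' \eqn{P^+ = 1 - (1 - g)^{n_d}}. Valid for real-valued expected counts.
#'
#' @param n_d Seed count(s), real-valued allowed (>= 0).
#' @param g Germination-and-survival probability in \[0, 1\].
#' @return Occupancy probability(ies).
#' @export
occupancy_prob <- function(n_d, g) {
  if (any(n_d < 0)) abort("`n_d` must be non-negative.")
  if (g < 0 || g > 1) abort("`g` must lie in [0, 1].")
  if (g == 1) return(as.numeric(n_d > 0))
  -expm1(n_d * log1p(-g))
}

#' Fitness of a seed size: expected number of colonized cells
#'
#' Sums the occupancy probability over every habitable cell of a bounded
#' window (matrix cells have zero germination and contribute nothing). The
#' parent sits at cell 0; the sum runs over the deposition support
#' `d = 0, ..., d_max - 1`, so self-replacement in the natal cell counts as
#' one colonized cell.
#'
#' @param size Seed size in mm.
#' @param landscape A bounded [landscape()] with the same `d_max` as `params`.
#' @param kernel A [dispersal_kernel()].
#' @param params A [det_params()].
#' @return Expected number of colonized cells (scalar).
#' @export
det_fitness <- function(size, landscape, kernel, params) {
  stopifnot(inherits(landscape, "landscape1d"))
  if (landscape$mode != "bounded")
    abort("`det_fitness()` needs a bounded landscape.")
  if (landscape$d_max != params$d_max)
    abort("landscape and params disagree on `d_max`.")
  hab <- habitable_mask(landscape, params$d_max)
  det_fitness_masked(size, hab, kernel, params)
}

# logical mask over deposition support 0 ... d_max - 1
habitable_mask <- function(landscape, d_max) {
  is_habitable(landscape, 0:(d_max - 1L))
}

det_fitness_masked <- function(size, hab, kernel, params) {
  n_d <- seeds_per_cell(size, kernel, params)
  sum(occupancy_prob(n_d[hab], params$g))
}

#' Evolve seed size by hill climbing on the fitness landscape
#'
#' Iterated local search on the 0.01-mm seed-size grid: at each step the
#' fitness of `S` is compared with that of its neighbors `S - step` and
#' `S + step` (candidates outside the size bounds, or whose production cost
#' reaches 1, are excluded); the walk moves to the strictly better neighbor
#' (to the smaller seed on an exact tie) and stops when `S` beats or ties
#' both neighbors. Deterministic for fixed inputs; the returned size is the
#' local optimum reachable from `s_init`. Because mutations are small, the
#' walk cannot cross fitness valleys — the mechanism behind evolutionary
#' hysteresis.
#'
#' @param s_init Starting seed size in mm, on the `step` grid (snapped with a
#'   warning otherwise).
#' @inheritParams det_fitness
#' @return A list of class `seed_size_opt`: `s_star` (evolved size, mm),
#'   `fitness`, `lambda`, `median_dispersal`, `n_steps`, and the visited
#'   `trajectory` of sizes.
#' @export
optimize_seed_size <- function(s_init, landscape, kernel, params) {
  step <- params$step
  grid_max <- as.integer(round((kernel$s_max - kernel$s_min) / step))
  k0 <- round((s_init - kernel$s_min) / step)
  if (abs(kernel$s_min + k0 * step - s_init) > 1e-9) {
    warn(sprintf("`s_init` = %g is not on the %g-mm grid; snapped.", s_init, step))
  }
  k0 <- min(max(k0, 0L), grid_max)
  hab <- habitable_mask(landscape, params$d_max)

  cache <- new.env(parent = emptyenv())
  fit_at <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    size <- kernel$s_min + k * step
    f <- if (seed_cost(size, params$c1) >= 1) -Inf
         else det_fitness_masked(size, hab, kernel, params)
    cache[[key]] <- f
    f
  }

  k <- k0
  trajectory <- kernel$s_min + k * step
  f0 <- fit_at(k)
  repeat {
    f_lo <- if (k > 0L) fit_at(k - 1L) else -Inf
    f_hi <- if (k < grid_max) fit_at(k + 1L) else -Inf
    if (f_lo <= f0 && f_hi <= f0) break
    k <- if (f_lo >= f_hi) k - 1L else k + 1L  # tie -> cheaper (smaller) seed
    f0 <- max(f_lo, f_hi)
    trajectory <- c(trajectory, kernel$s_min + k * step)
    if (length(trajectory) > grid_max + 2L)
      abort("hill climb exceeded the size grid; this should be impossible.")
  }
  s_star <- kernel$s_min + k * step
  lam <- lambda_of_size(kernel, s_star)
  structure(
    list(s_star = s_star, fitness = f0, lambda = lam,
         median_dispersal = median_distance(lam),
         n_steps = length(trajectory) - 1L, trajectory = trajectory),
    class = "seed_size_opt"
  )
}

#' @export
print.seed_size_opt <- function(x, ...) {
  cat(sprintf(
    "Evolved seed size %.2f mm (fitness %.4g cells, median dispersal %.4g cells, %d steps)\n",
    x$s_star, x$fitness, x$median_dispersal, x$n_steps))
  invisible(x)
}

#' @describeIn optimize_seed_size One-row tibble summary of the evolved optimum.
#' @param x A `seed_size_opt`.
#' @param ... Unused.
#' @export
tidy.seed_size_opt <- function(x, ...) {
  tibble(s_star = x$s_star, fitness = x$fitness, lambda = x$lambda,
         median_dispersal = x$median_dispersal, n_steps = x$n_steps)
}
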