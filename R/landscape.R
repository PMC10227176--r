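#' One-dimensional fragmented landscape
#'
#' A linear (river-like) lattice of habitat patches of `x_h` cells separated
#' by uninhabitable matrix runs of `x_ipd` cells. The pattern starts with a
#' habitable run at cell 0. Two variants:
#'
#' * `"bounded"`: a downstream window of cells `0 ... d_max`, used by the
#'   deterministic single-plant model (the focal parent sits at cell 0, the
#'   most upstream cell of a patch; only downstream cells matter because flow
#'   is unidirectional).
#' * `"periodic"`: a ring of `n_patches` patch + matrix units
#'   (`L = n_patches * (x_h + x_ipd)` cells, indices modulo `L`), used by the
#'   stochastic individual-based model, where continuous boundaries conserve
#'   seed mass.
#'
#' @param x_h Habitat patch length in cells (>= 1).
#' @param x_ipd Inter-patch distance in cells (>= 0); the fragmentation axis.
#' @param mode `"bounded"` or `"periodic"`.
#' @param d_max Window length in cells (bounded mode).
#' @param n_patches Number of patches on the ring (periodic mode).
#' @param phase Offset of cell 0 within its patch (bounded mode only;
#'   default 0 = cell 0 is the most upstream cell of a patch). Places the
#'   deterministic model's focal parent `phase` cells into its patch.
#' @return An object of class `landscape1d`.
#' @examples
#' ls <- landscape(x_h = 50, x_ipd = 10, mode = "bounded", d_max = 5000)
#' is_habitable(ls, c(49, 50, 60))
#' @export
landscape <- function(x_h, x_ipd, mode = c("bounded", "periodic"),
                      d_max = NULL, n_patches = NULL, phase = 0L) {
  mode <- match.arg(mode)
  if (x_h < 1) abort("`x_h` must be at least 1 cell.")
  if (x_ipd < 0) abort("`x_ipd` must be non-negative.")
  x_h <- as.integer(x_h); x_ipd <- as.integer(x_ipd)
  if (phase != 0L && mode == "periodic")
    abort("`phase` is only meaningful for bounded landscapes.")
  if (phase < 0L || phase >= x_h)
    abort("`phase` must lie in [0, x_h).")
  phase <- as.integer(phase)
  if (mode == "bounded") {
    if (is.null(d_max) || d_max < 1) abort("bounded mode needs `d_max` >= 1.")
    d_max <- as.integer(d_max)
    n_patches <- NA_integer_
    length_total <- d_max + 1L
  } else {
    if (is.null(n_patches) || n_patches < 1)
      abort("periodic mode needs `n_patches` >= 1.")
    n_patches <- as.integer(n_patches)
    d_max <- NA_integer_
    length_total <- n_patches * (x_h + x_ipd)
  }
  structure(
    list(x_h = x_h, x_ipd = x_ipd, mode = mode, d_max = d_max,
         n_patches = n_patches, length_total = length_total, phase = phase),
    class = "landscape1d"
  )
}

#' @export
print.landscape1d <- function(x, ...) {
  cat(sprintf("1-D %s landscape: patches of %d cells, inter-patch distance %d cells\n",
              x$mode, x$x_h, x$x_ipd))
  if (x$mode == "bounded") {
    cat(sprintf("  window: cells 0 ... %d\n", x$d_max))
  } else {
    cat(sprintf("  ring of %d patches, %d cells total (%d habitable)\n",
                x$n_patches, x$length_total, x$n_patches * x$x_h))
  }
  invisible(x)
}

#' Is a cell habitable?
#'
#' A cell is habitable iff its position within the repeating
#' patch-plus-matrix unit falls inside the leading habitable run:
#' `(cell %% (x_h + x_ipd)) < x_h`. Periodic landscapes wrap indices modulo
#' the ring length first; bounded landscapes reject out-of-window indices.
#'
#' @param landscape A [landscape()].
#' @param cells Integer cell indices.
#' @return Logical vector, one element per cell.
#' @export
is_habitable <- function(landscape, cells) {
  stopifnot(inherits(landscape, "landscape1d"))
  if (landscape$mode == "bounded") {
    if (any(cells < 0 | cells > landscape$d_max))
      abort("cell index outside the bounded window.")
  } else {
    cells <- cells %% landscape$length_total
  }
  ((cells + landscape$phase) %% (landscape$x_h + landscape$x_ipd)) < landscape$x_h
}

#' All habitable cell indices, in ascending order
#'
#' @inheritParams is_habitable
#' @return Integer vector of habitable cell indices: within `0 ... d_max`
#'   (bounded) or `0 ... L - 1` (periodic; exactly `n_patches * x_h` cells).
#' @export
habitable_cells <- function(landscape) {
  stopifnot(inherits(landscape, "landscape1d"))
  period <- landscape$x_h + landscape$x_ipd
  if (landscape$mode == "periodic") {
    starts <- (seq_len(landscape$n_patches) - 1L) * period
    as.integer(outer(0:(landscape$x_h - 1L), starts, `+`))
  } else {
    cells <- 0:landscape$d_max
    cells[is_habitable(landscape, cells)]
  }
}

# Position of a habitable cell in the habitable_cells() ordering (0-based
# rank). Used to carry populations across landscapes with the same patch
# structure but different inter-patch distance.
habitable_rank <- function(landscape, cells) {
  period <- landscape$x_h + landscape$x_ipd
  unit <- cells %/% period
  offset <- cells %% period
  if (any(offset >= landscape$x_h)) abort("cell is not habitable.")
  unit * landscape$x_h + offset
}
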