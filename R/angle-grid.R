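#' Angle grid for a tomographic acquisition
#'
#' Defines the set of projection angles available to an instrument:
#' `n_proj` angles equally spaced on the half-open interval
#' `[a_min, a_max)`. The j-th angle (j = 0, ..., n_proj - 1) is
#' `a_min + j / n_proj * (a_max - a_min)`, so the upper end of the range is
#' never generated (for a full circle, 360 deg is the same view as 0 deg).
#'
#' @param a_min,a_max Angular range in degrees; `a_max` must exceed `a_min`.
#' @param n_proj Number of projections (positive integer).
#'
#' @return An `mtr_angle_grid` object.
#' @examples
#' grid <- angle_grid(0, 360, 8)
#' grid_angles(grid)
#' @export
angle_grid <- function(a_min, a_max, n_proj) {
  if (!is.numeric(a_min) || !is.numeric(a_max) || a_max <= a_min) {
    stop_invalid("`a_max` must be greater than `a_min`.")
  }
  if (!is.numeric(n_proj) || length(n_proj) != 1 || n_proj < 1 ||
      n_proj != round(n_proj)) {
    stop_invalid("`n_proj` must be a positive integer.")
  }
  structure(
    list(a_min = as.numeric(a_min), a_max = as.numeric(a_max),
         n_proj = as.integer(n_proj)),
    class = "mtr_angle_grid"
  )
}

#' Angles of a grid
#'
#' @param grid An [angle_grid()].
#' @param index Zero-based angle indices; defaults to the whole grid.
#' @return Numeric vector of angles in degrees.
#' @export
grid_angles <- function(grid, index = seq_len(grid$n_proj) - 1L) {
  stopifnot(inherits(grid, "mtr_angle_grid"))
  grid$a_min + index / grid$n_proj * (grid$a_max - grid$a_min)
}

#' @export
print.mtr_angle_grid <- function(x, ...) {
  cat(sprintf("<angle grid: %d projections on [%g, %g) deg, spacing %g deg>\n",
              x$n_proj, x$a_min, x$a_max,
              (x$a_max - x$a_min) / x$n_proj))
  invisible(x)
}

grid_spacing <- function(grid) (grid$a_max - grid$a_min) / grid$n_proj
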