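new_order <- function(grid, order, kind, n_prescan = NA_integer_,
                      seed = NA_integer_) {
  structure(
    list(grid = grid, order = as.integer(order), kind = kind,
         n_prescan = as.integer(n_prescan), seed = as.integer(seed)),
    class = "mtr_order"
  )
}

#' Consecutive acquisition order
#'
#' The classical protocol: projections are acquired in increasing angle,
#' `order(i) = i`. Total angular travel over a full-circle grid is one
#' rotation (~360 deg) regardless of the number of projections.
#'
#' @param grid An [angle_grid()].
#' @return An `mtr_order` object.
#' @export
acq_order_consecutive <- function(grid) {
  stopifnot(inherits(grid, "mtr_angle_grid"))
  new_order(grid, seq_len(grid$n_proj) - 1L, "consecutive")
}

#' Random acquisition order
#'
#' A uniformly random permutation of the angle indices, reproducible from
#' `seed`. Random orders give well-spread partial data at any stopping point
#' but cost ~90 deg of rotation per projection on average (180 deg if the
#' stage can only rotate one way), which slows most instruments drastically.
#'
#' @param grid An [angle_grid()].
#' @param seed Integer seed recorded in the result.
#' @return An `mtr_order` object.
#' @export
acq_order_random <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "mtr_angle_grid"))
  perm <- withr_seed(seed, sample.int(grid$n_proj)) - 1L
  new_order(grid, perm, "random", seed = seed)
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Logarithmic acquisition order
#'
#' A prescan rotation acquires `n_prescan` equidistant angles; every further
#' rotation doubles the angular sampling by visiting the midpoints of the
#' already-acquired set (in ascending angle within a rotation). After each
#' completed rotation the acquired angles are again equidistant, so fast
#' analytic reconstruction stays artifact-free at every rotation boundary,
#' while total travel grows only logarithmically:
#' `d_total = 360 * (1 + log2(n_proj / n_prescan))` degrees.
#'
#' `n_proj / n_prescan` must be a power of two.
#'
#' @param grid An [angle_grid()].
#' @param n_prescan Number of projections in the prescan rotation.
#' @return An `mtr_order` object.
#' @examples
#' acq_order_logarithmic(angle_grid(0, 360, 16), 4)$order
#' @export
acq_order_logarithmic <- function(grid, n_prescan) {
  stopifnot(inherits(grid, "mtr_angle_grid"))
  n <- grid$n_proj
  if (!is.numeric(n_prescan) || n_prescan < 1 ||
      n_prescan != round(n_prescan)) {
    stop_invalid("`n_prescan` must be a positive integer.")
  }
  ratio <- n / n_prescan
  if (ratio != round(ratio) || bitwAnd(as.integer(ratio), as.integer(ratio) - 1L) != 0L) {
    stop_invalid(paste0(
      "`n_proj / n_prescan` must be a power of two (got ", n, " / ",
      n_prescan, "); the midpoint-refinement rotations require it."))
  }
  step <- as.integer(ratio)
  idx <- seq.int(0L, n - 1L, by = step)       # prescan rotation
  while (step > 1L) {
    half <- step %/% 2L
    idx <- c(idx, seq.int(half, n - 1L, by = step))  # midpoints, ascending
    step <- half
  }
  new_order(grid, idx, "logarithmic", n_prescan = n_prescan)
}

#' @export
print.mtr_order <- function(x, ...) {
  extra <- switch(x$kind,
    random = sprintf(" (seed %d)", x$seed),
    logarithmic = sprintf(" (n_prescan %d)", x$n_prescan),
    "")
  cat(sprintf("<%s acquisition order%s: %d projections on [%g, %g) deg>\n",
              x$kind, extra, x$grid$n_proj, x$grid$a_min, x$grid$a_max))
  invisible(x)
}

#' Angles of an order, in acquisition sequence
#'
#' @param order An `mtr_order`.
#' @return Numeric vector: the angle (degrees) of the i-th acquired
#'   projection.
#' @export
order_angles <- function(order) {
  stopifnot(inherits(order, "mtr_order"))
  grid_angles(order$grid, order$order)
}

#' @describeIn acq_order_consecutive Tabular view of any order: one row per
#'   acquisition step with the angle index and angle.
#' @param x An `mtr_order`.
#' @param ... Unused.
#' @export
as_tibble.mtr_order <- function(x, ...) {
  tibble::tibble(
    i = seq_along(x$order) - 1L,
    index = x$order,
    angle = order_angles(x)
  )
}

#' @export
tidy.mtr_order <- function(x, ...) as_tibble.mtr_order(x)

#' Per-step angular travel of an acquisition order
#'
#' Distances are between consecutive *acquired* angles: the shortest arc when
#' the stage can rotate both ways (`"bidirectional"`), or the forward arc when
#' it cannot (`"unidirectional"`). The first projection is charged zero travel
#' (initial positioning).
#'
#' @param order An `mtr_order`.
#' @param rotation `"bidirectional"` (default) or `"unidirectional"`.
#' @return A tibble with one row per acquisition step: `i`, `angle`,
#'   `distance` (degrees).
#' @export
step_distances <- function(order,
                           rotation = c("bidirectional", "unidirectional")) {
  stopifnot(inherits(order, "mtr_order"))
  rotation <- match.arg(rotation)
  ang <- order_angles(order)
  d <- if (length(ang) > 1) {
    fwd <- (diff(ang)) %% 360
    if (rotation == "bidirectional") pmin(fwd, 360 - fwd) else fwd
  } else {
    numeric(0)
  }
  tibble::tibble(
    i = seq_along(ang) - 1L,
    angle = ang,
    distance = c(0, d)
  )
}

#' Angular travel metrics of an acquisition order
#'
#' Summarises [step_distances()]: total angular distance `d_total` and the
#' mean per-step distance. For a consecutive order on a full circle
#' `d_total` is ~360 deg independent of the number of projections; for the
#' logarithmic order it tracks `360 * (1 + log2(n_proj / n_prescan))` to
#' within one rotation; for random orders the mean step tends to 90 deg
#' (bidirectional) or 180 deg (unidirectional).
#'
#' @inheritParams step_distances
#' @return One-row tibble: `kind`, `rotation_mode`, `n_steps`, `d_total`,
#'   `mean_step` (all distances in degrees).
#' @export
order_metrics <- function(order,
                          rotation = c("bidirectional", "unidirectional")) {
  rotation <- match.arg(rotation)
  steps <- step_distances(order, rotation)
  moves <- steps$distance[-1]
  tibble::tibble(
    kind = order$kind,
    rotation_mode = rotation,
    n_steps = length(moves),
    d_total = sum(steps$distance),
    mean_step = if (length(moves)) mean(moves) else 0
  )
}

#' Expected total travel of a logarithmic order
#'
#' Closed form `360 * (1 + log2(n_proj / n_prescan))` degrees for
#' unidirectional rotation; the realised travel of the generated order lies
#' within one rotation below this value (the final sweep stops short of
#' wrapping).
#'
#' @param n_proj,n_prescan As in [acq_order_logarithmic()].
#' @return Degrees.
#' @export
logarithmic_d_total <- function(n_proj, n_prescan) {
  360 * (1 + log2(n_proj / n_prescan))
}

#' Read/write an acquisition order as CSV
#'
#' The listing has columns `i` (acquisition step), `index` (angle index) and
#' `angle` (degrees), plus the order kind and grid recorded in a header
#' comment; `read_order()` restores an identical `mtr_order`.
#'
#' @param order An `mtr_order`.
#' @param path File path.
#' @return `write_order()` returns `order` invisibly; `read_order()` returns
#'   an `mtr_order`.
#' @export
write_order <- function(order, path) {
  stopifnot(inherits(order, "mtr_order"))
  hdr <- sprintf(
    "# mtr_order kind=%s a_min=%.10g a_max=%.10g n_proj=%d n_prescan=%d seed=%d",
    order$kind, order$grid$a_min, order$grid$a_max, order$grid$n_proj,
    ifelse(is.na(order$n_prescan), -1L, order$n_prescan),
    ifelse(is.na(order$seed), -1L, order$seed))
  writeLines(hdr, path)
  readr::write_csv(as_tibble.mtr_order(order), path, append = TRUE,
                   col_names = TRUE)
  invisible(order)
}

#' @rdname write_order
#' @export
read_order <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# mtr_order ", "", hdr), " ")[[1]]
  vals <- stats::setNames(
    sub("^[^=]+=", "", kv),
    sub("=.*$", "", kv))
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  grid <- angle_grid(as.numeric(vals["a_min"]), as.numeric(vals["a_max"]),
                     as.integer(vals["n_proj"]))
  n_prescan <- as.integer(vals["n_prescan"])
  seed <- as.integer(vals["seed"])
  new_order(grid, tab$index, vals[["kind"]],
            n_prescan = if (n_prescan < 0) NA_integer_ else n_prescan,
            seed = if (seed < 0) NA_integer_ else seed)
}
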