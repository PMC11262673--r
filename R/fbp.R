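new_partial_recon <- function(acc, n, n_det, order_kind = NA_character_) {
  structure(
    list(acc = acc, n = as.integer(n), n_det = as.integer(n_det),
         order_kind = order_kind),
    class = "mtr_partial_recon"
  )
}

#' Empty partial reconstruction
#'
#' Starting state for the incremental accumulator: zero projections folded
#' in, all-zero image.
#'
#' @param size Reconstruction grid side in pixels.
#' @param n_det Detector bin count of the projections that will be fed in
#'   (defaults to `size`).
#' @return An `mtr_partial_recon` with `n = 0`.
#' @export
fbp_partial_init <- function(size, n_det = size) {
  new_partial_recon(matrix(0, size, size), 0L, n_det)
}

#' Batch filtered back projection from a projection subset
#'
#' Reconstructs from the first `n` projections of an acquisition order (or
#' an explicit `subset` of sinogram rows): each selected row is ramp
#' filtered and backprojected, and the accumulator stores the *average* of
#' the backprojections. The displayed image is read out with
#' [recon_image()], which applies the global scale `pi` appropriate for a
#' full-circle equidistant angle set; partial, non-equidistant sets simply
#' inherit it, which reproduces the characteristic wedge and streak
#' artifacts of limited data.
#'
#' @param sinogram An `mtr_sinogram` of raw projections.
#' @param n Use the first `n` rows (default all); ignored when `subset`
#'   is given.
#' @param subset Explicit row indices (1-based, in acquisition sequence).
#' @param size Reconstruction grid side (default: detector bin count).
#' @param window Ramp apodization, see [filter_profile()].
#' @return An `mtr_partial_recon`.
#' @examples
#' ph <- phantom_image(64)
#' sino <- radon_project(ph, seq(0, 359.9, length.out = 64))
#' rec <- fbp_reconstruct(sino)
#' image_rmse(recon_image(rec), ph)
#' @export
fbp_reconstruct <- function(sinogram, n = NULL, subset = NULL,
                            size = sinogram$n_det,
                            window = c("none", "hann")) {
  stopifnot(inherits(sinogram, "mtr_sinogram"))
  window <- match.arg(window)
  if (is.null(subset)) {
    if (is.null(n)) n <- length(sinogram$angles)
    subset <- seq_len(n)
  }
  if (length(subset) < 1) {
    stop_invalid("At least one projection is required.")
  }
  if (any(subset < 1 | subset > length(sinogram$angles))) {
    stop_invalid("`subset` indexes rows beyond the sinogram.")
  }
  filt <- if (sinogram$filtered) sinogram else filter_sinogram(sinogram, window)
  rows <- filt$values[subset, , drop = FALSE]
  acc <- backproject_sum_cpp(rows, filt$angles[subset] * pi / 180,
                             as.integer(size)) / length(subset)
  new_partial_recon(acc, length(subset), sinogram$n_det)
}

#' Incremental partial-FBP update
#'
#' Folds one new projection into a running partial reconstruction by the
#' recurrence `v_[n+1] = (n * v_n + backproject(filtered row)) / (n + 1)`.
#' The cost is a single filter + backprojection whatever `n` is, which is
#' what makes a reconstruction-per-projection monitored protocol O(1) per
#' update instead of O(n). After feeding rows `subset` in any sequence the
#' accumulator equals [fbp_reconstruct()] on the same subset to floating
#' point accuracy.
#'
#' @param recon An `mtr_partial_recon` (start from [fbp_partial_init()]).
#' @param sinogram The `mtr_sinogram` the projection comes from.
#' @param i Row index (1-based) of the new projection.
#' @inheritParams fbp_reconstruct
#' @return The updated `mtr_partial_recon` (with `n` incremented).
#' @export
fbp_update <- function(recon, sinogram, i, window = c("none", "hann")) {
  stopifnot(inherits(recon, "mtr_partial_recon"))
  stopifnot(inherits(sinogram, "mtr_sinogram"))
  window <- match.arg(window)
  if (sinogram$n_det != recon$n_det) {
    stop_invalid("Detector geometry of the projection does not match the accumulator.")
  }
  row <- sinogram$values[i, ]
  if (!sinogram$filtered) row <- filter_profile(row, window)
  b <- backproject_one_cpp(row, sinogram$angles[i] * pi / 180, nrow(recon$acc))
  acc <- (recon$n * recon$acc + b) / (recon$n + 1)
  new_partial_recon(acc, recon$n + 1L, recon$n_det, recon$order_kind)
}

#' Read out the image of a partial reconstruction
#'
#' Applies the global FBP scale (`pi` for angles covering the full circle,
#' with unit detector spacing) to the stored backprojection average.
#'
#' @param recon An `mtr_partial_recon`.
#' @return Numeric matrix of class `mtr_image`.
#' @export
recon_image <- function(recon) {
  stopifnot(inherits(recon, "mtr_partial_recon"))
  structure(pi * recon$acc, class = c("mtr_image", "matrix", "array"))
}

#' @export
print.mtr_partial_recon <- function(x, ...) {
  cat(sprintf("<partial reconstruction: %d projection%s folded in, %d x %d grid>\n",
              x$n, if (x$n == 1) "" else "s", nrow(x$acc), ncol(x$acc)))
  invisible(x)
}

#' @export
glance.mtr_partial_recon <- function(x, ...) {
  tibble::tibble(n = x$n, size = nrow(x$acc), n_det = x$n_det)
}

#' @export
tidy.mtr_partial_recon <- function(x, ...) {
  img <- recon_image(x)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  df
}

#' @export
autoplot.mtr_partial_recon <- function(object, ...) {
  plot_image_matrix(recon_image(object),
                    sprintf("partial reconstruction, n = %d", object$n))
}

#' Convergence of partial reconstructions along an acquisition order
#'
#' Runs the incremental accumulator along `order`'s acquisition sequence
#' and, at each checkpoint `n`, records the reconstruction error against a
#' reference image and the relative L2 change from the previous checkpoint
#' image (the quality proxy a monitored protocol can compute without a
#' reference).
#'
#' @param sinogram An `mtr_sinogram` whose rows are in grid-index sequence
#'   (row j+1 holds angle index j), e.g. from [radon_project()] on the
#'   grid's angles.
#' @param order An `mtr_order` over the same grid.
#' @param checkpoints Increasing projection counts to report at.
#' @param reference Reference image (e.g. the phantom), or `NULL` to skip
#'   RMSE.
#' @inheritParams fbp_reconstruct
#' @return Tibble: `order_kind`, `n`, `rmse` (relative, vs reference),
#'   `rel_change` (vs previous checkpoint; `NA` at the first).
#' @export
convergence_report <- function(sinogram, order, checkpoints,
                               reference = NULL,
                               window = c("none", "hann")) {
  stopifnot(inherits(order, "mtr_order"))
  window <- match.arg(window)
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop_invalid("`checkpoints` must be strictly increasing.")
  }
  if (max(checkpoints) > length(sinogram$angles)) {
    stop_invalid("Checkpoints exceed the number of projections.")
  }
  filt <- if (sinogram$filtered) sinogram else filter_sinogram(sinogram, window)
  size <- sinogram$n_det
  prev_img <- NULL
  out <- vector("list", length(checkpoints))
  last <- 0L
  acc <- fbp_partial_init(size, sinogram$n_det)
  for (ci in seq_along(checkpoints)) {
    n <- checkpoints[ci]
    rows <- order$order[(last + 1L):n] + 1L # grid index -> sinogram row
    part <- backproject_sum_cpp(
      filt$values[rows, , drop = FALSE],
      filt$angles[rows] * pi / 180, size)
    acc <- new_partial_recon((acc$n * acc$acc + part) / n, n,
                             sinogram$n_det, order$kind)
    last <- n
    img <- recon_image(acc)
    rel <- if (is.null(prev_img)) NA_real_ else {
      sqrt(mean((img - prev_img)^2)) / max(sqrt(mean(prev_img^2)), .Machine$double.eps)
    }
    out[[ci]] <- tibble::tibble(
      order_kind = order$kind, n = n,
      rmse = if (is.null(reference)) NA_real_ else image_rmse(img, reference),
      rel_change = rel)
    prev_img <- img
  }
  dplyr::bind_rows(out)
}
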