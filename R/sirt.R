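#' SIRT iterative reconstruction
#'
#' Simultaneous iterative reconstruction: each iteration forward projects
#' the current estimate, and the row/column-normalised backprojection of
#' the residual is added to the estimate,
#' `x <- x + relax * C * Bt(R * (p - A x))`, where `R` and `C` are the
#' inverse row and column sums of the projection operator (computed by
#' projecting a unit image and backprojecting a unit sinogram). A warm
#' start from a previous partial reconstruction accelerates convergence,
#' which is the natural use in a monitored protocol where each decision
#' point can seed the next.
#'
#' @param sinogram An `mtr_sinogram` of raw (unfiltered) projections.
#' @param iterations Number of iterations (>= 1).
#' @param initial Optional starting image: a matrix or an
#'   `mtr_partial_recon` (its [recon_image()] is used); default zeros.
#' @param relax Relaxation factor in (0, 2).
#' @param size Reconstruction grid side.
#' @param step Ray sampling interval for the forward operator, pixels.
#' @return An `mtr_sirt_recon`: the image estimate plus the per-iteration
#'   residual norms.
#' @export
recon_sirt <- function(sinogram, iterations, initial = NULL, relax = 0.9,
                       size = sinogram$n_det, step = 0.5) {
  stopifnot(inherits(sinogram, "mtr_sinogram"))
  if (iterations < 1) stop_invalid("`iterations` must be >= 1.")
  if (sinogram$filtered) {
    stop_invalid("SIRT expects raw projections, not a filtered sinogram.")
  }
  theta <- sinogram$angles * pi / 180
  p <- sinogram$values
  x <- if (is.null(initial)) {
    matrix(0, size, size)
  } else if (inherits(initial, "mtr_partial_recon")) {
    unclass(recon_image(initial))
  } else {
    unclass(initial)
  }
  stopifnot(all(dim(x) == c(size, size)))

  ones_img <- matrix(1, size, size)
  row_sum <- forward_project_cpp(ones_img, theta, sinogram$n_det, step)
  ones_proj <- matrix(1, nrow(p), ncol(p))
  col_sum <- backproject_sum_cpp(ones_proj, theta, size)
  rinv <- ifelse(row_sum > 1e-8, 1 / row_sum, 0)
  cinv <- ifelse(col_sum > 1e-8, 1 / col_sum, 0)

  residuals <- numeric(iterations)
  for (it in seq_len(iterations)) {
    fp <- forward_project_cpp(x, theta, sinogram$n_det, step)
    res <- p - fp
    residuals[it] <- sqrt(mean(res^2))
    x <- x + relax * cinv * backproject_sum_cpp(res * rinv, theta, size)
  }
  structure(
    list(image = structure(x, class = c("mtr_image", "matrix", "array")),
         iterations = iterations, residuals = residuals, relax = relax),
    class = "mtr_sirt_recon"
  )
}

#' @export
print.mtr_sirt_recon <- function(x, ...) {
  cat(sprintf("<SIRT reconstruction: %d iterations, final residual RMS %.4g>\n",
              x$iterations, tail(x$residuals, 1)))
  invisible(x)
}

#' @export
glance.mtr_sirt_recon <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 first_residual = x$residuals[1],
                 final_residual = tail(x$residuals, 1),
                 relax = x$relax)
}

#' @export
tidy.mtr_sirt_recon <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$iterations), residual = x$residuals)
}
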