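#' Deterministic head phantom
#'
#' The classical piecewise-constant ellipse head phantom (low-contrast
#' variant), rendered on an `size` x `size` pixel grid with attenuation
#' values in [0, 1] and zero background. Used as the reference object for
#' all synthetic reconstruction experiments; two calls with the same size
#' are identical.
#'
#' Pixels crossed by an ellipse boundary are antialiased by `oversample`^2
#' subpixel averaging (partial-volume rendering), so values on edges are
#' intermediate; interior values are exact.
#'
#' @param size Image side in pixels (>= 16).
#' @param oversample Subpixel sampling factor per axis for edge
#'   antialiasing (1 = hard binary edges).
#' @return An `size` x `size` numeric matrix of class `mtr_image`.
#' @examples
#' p <- phantom_image(64)
#' range(p)
#' @export
phantom_image <- function(size, oversample = 2L) {
  if (size < 16) stop_invalid("`size` must be at least 16.")
  if (oversample < 1 || oversample != round(oversample)) {
    stop_invalid("`oversample` must be a positive integer.")
  }
  if (oversample > 1) {
    big <- phantom_render(size * oversample)
    # block-average oversample x oversample subpixels
    m <- size * oversample
    img <- .colSums(
      matrix(aperm(array(big, c(oversample, size, oversample, size)),
                   c(1, 3, 2, 4)),
             nrow = oversample^2),
      oversample^2, size * size) / oversample^2
    img <- matrix(pmin(1, pmax(0, img)), size, size) # float hygiene at edges
    return(structure(img, class = c("mtr_image", "matrix", "array")))
  }
  phantom_render(size)
}

phantom_render <- function(size) {
  # columns: additive value, semi-axes a, b, centre x0, y0, rotation (deg)
  ell <- matrix(c(
     1.0, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.8, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.2, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.2, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.1, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.1, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.1, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.1, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.1, 0.0230, 0.0230,  0.00, -0.6050,   0,
     0.1, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
  c0 <- (size - 1) / 2
  # pixel centres mapped to [-1, 1]; y increases upwards
  x <- (seq_len(size) - 1 - c0) / (size / 2)
  y <- (c0 - (seq_len(size) - 1)) / (size / 2)
  xs <- matrix(x, nrow = size, ncol = size, byrow = TRUE)
  ys <- matrix(y, nrow = size, ncol = size)
  img <- matrix(0, size, size)
  for (e in seq_len(nrow(ell))) {
    phi <- ell[e, 6] * pi / 180
    dx <- xs - ell[e, 4]
    dy <- ys - ell[e, 5]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    inside <- (u / ell[e, 2])^2 + (v / ell[e, 3])^2 <= 1
    img[inside] <- img[inside] + ell[e, 1]
  }
  structure(img, class = c("mtr_image", "matrix", "array"))
}

#' Relative root-mean-square error between two images
#'
#' `sqrt(mean((a - b)^2)) / sqrt(mean(b^2))`, evaluated inside the inscribed
#' circle by default (the region parallel-beam data determines).
#'
#' @param a,b Square numeric matrices of equal size; `b` is the reference.
#' @param circle Restrict to the inscribed circle.
#' @return A single number.
#' @export
image_rmse <- function(a, b, circle = TRUE) {
  stopifnot(all(dim(a) == dim(b)))
  if (circle) {
    n <- nrow(b)
    c0 <- (n - 1) / 2
    d2 <- outer((seq_len(n) - 1 - c0)^2, (seq_len(n) - 1 - c0)^2, "+")
    keep <- d2 <= (n / 2)^2
    a <- a[keep]
    b <- b[keep]
  }
  sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
}

#' @export
print.mtr_image <- function(x, ...) {
  cat(sprintf("<image %d x %d, range [%.3g, %.3g]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
autoplot.mtr_image <- function(object, ...) {
  plot_image_matrix(unclass(object), "image")
}

plot_image_matrix <- function(m, title) {
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL)
}
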