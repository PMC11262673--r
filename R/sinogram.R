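#' Forward projection (discrete line integrals)
#'
#' Computes parallel-beam projections of a square image at the given angles:
#' for each angle and detector bin the image is integrated along the ray by
#' sampling with bilinear interpolation at `step`-pixel intervals. Lengths
#' are in pixel units, so a ray crossing a uniform unit-valued disk of
#' diameter d reads ~d at the centre bin. The operator is linear in the
#' image.
#'
#' @param image Square numeric matrix (e.g. [phantom_image()]).
#' @param angles Projection angles in degrees.
#' @param n_det Number of detector bins (default: image side).
#' @param step Ray sampling interval in pixels.
#' @return An `mtr_sinogram`: projection values (one row per angle),
#'   the angles, and the geometry.
#' @examples
#' sino <- radon_project(phantom_image(64), seq(0, 359, by = 3))
#' @export
radon_project <- function(image, angles, n_det = nrow(image), step = 0.5) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    stop_invalid("`image` must be a square matrix.")
  }
  vals <- forward_project_cpp(unclass(image), angles * pi / 180,
                              as.integer(n_det), step)
  new_sinogram(vals, angles, n_det)
}

new_sinogram <- function(values, angles, n_det,
                         geometry = "parallel", filtered = FALSE) {
  structure(
    list(values = values, angles = as.numeric(angles),
         n_det = as.integer(n_det), geometry = geometry,
         filtered = filtered),
    class = "mtr_sinogram"
  )
}

#' Build a sinogram from raw values
#'
#' For data coming from outside the package (one row per projection angle).
#'
#' @param values Matrix, `length(angles)` rows.
#' @param angles Angles in degrees, one per row.
#' @return An `mtr_sinogram`.
#' @export
as_sinogram <- function(values, angles) {
  if (nrow(values) != length(angles)) {
    stop_invalid("`values` must have one row per angle.")
  }
  new_sinogram(values, angles, ncol(values))
}

#' @export
print.mtr_sinogram <- function(x, ...) {
  cat(sprintf("<%s%s sinogram: %d projections x %d detector bins>\n",
              if (x$filtered) "filtered " else "", x$geometry,
              length(x$angles), x$n_det))
  invisible(x)
}

#' @export
dim.mtr_sinogram <- function(x) dim(x$values)

#' @export
tidy.mtr_sinogram <- function(x, ...) {
  df <- tidyr::expand_grid(projection = seq_along(x$angles),
                           bin = seq_len(x$n_det))
  df$angle <- x$angles[df$projection]
  df$value <- x$values[cbind(df$projection, df$bin)]
  df
}

#' @export
autoplot.mtr_sinogram <- function(object, ...) {
  plot_image_matrix(object$values,
                    sprintf("sinogram (%d angles)", length(object$angles)))
}

# --- ramp filtering -------------------------------------------------------

# Frequency response of the band-limited ramp filter on m samples
# (discrete kernel: h(0) = 1/4, h(+-odd k) = -1/(pi^2 k^2), 0 at even k),
# optionally apodized with a Hann window.
ramp_response <- function(m, window = c("none", "hann")) {
  window <- match.arg(window)
  h <- numeric(m)
  k <- c(0:(m / 2), -(m / 2 - 1):-1) # circular lag of each position
  h[1] <- 0.25
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  resp <- Re(stats::fft(h))
  if (window == "hann") {
    f <- k / m # cycles per sample, in [-0.5, 0.5]
    resp <- resp * (0.5 + 0.5 * cos(2 * pi * f))
  }
  resp
}

next_pow2 <- function(x) 2^ceiling(log2(x))

#' Ramp-filter a detector profile
#'
#' Applies the band-limited ramp (Ram-Lak) filter by FFT convolution with
#' zero padding; an optional Hann window trades resolution for noise
#' suppression. The ramp has zero DC gain, so a constant profile filters to
#' (numerically) zero.
#'
#' @param profile Numeric vector, one detector row.
#' @param window `"none"` (default) or `"hann"`.
#' @return Filtered profile, same length.
#' @export
filter_profile <- function(profile, window = c("none", "hann")) {
  if (length(profile) < 1) stop_invalid("`profile` must be non-empty.")
  window <- match.arg(window)
  n <- length(profile)
  m <- max(64L, next_pow2(2L * n))
  padded <- c(profile, numeric(m - n))
  resp <- ramp_response(m, window)
  out <- Re(stats::fft(stats::fft(padded) * resp, inverse = TRUE)) / m
  out[seq_len(n)]
}

#' Ramp-filter a whole sinogram
#'
#' @param sinogram An `mtr_sinogram` of raw projections.
#' @inheritParams filter_profile
#' @return An `mtr_sinogram` with `filtered = TRUE`.
#' @export
filter_sinogram <- function(sinogram, window = c("none", "hann")) {
  stopifnot(inherits(sinogram, "mtr_sinogram"))
  window <- match.arg(window)
  n <- sinogram$n_det
  m <- max(64L, next_pow2(2L * n))
  resp <- ramp_response(m, window)
  padded <- cbind(sinogram$values,
                  matrix(0, nrow(sinogram$values), m - n))
  ft <- stats::mvfft(t(padded))
  out <- Re(stats::mvfft(ft * resp, inverse = TRUE)) / m
  new_sinogram(t(out)[, seq_len(n), drop = FALSE], sinogram$angles, n,
               sinogram$geometry, filtered = TRUE)
}
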