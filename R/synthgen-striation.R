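#' Ground-truth parameters for a synthetic striation image
#'
#' Describes a quasi-periodic pattern of Gaussian-profile bands emulating the
#' Z-disc (alpha-actinin) striations of a cardiomyocyte: band spacing
#' (sarcomere length), positional jitter of band centers (disorder), band
#' orientation and width, and additive Gaussian pixel noise.
#'
#' @param period_um Band spacing (mean sarcomere length), micrometres.
#' @param jitter_sigma_um SD of the positional jitter of band centers (um).
#' @param orientation_deg Band-normal angle, degrees counterclockwise from the
#'   image x-axis (columns).
#' @param band_sigma_um Gaussian band width (um); emulates diffraction blur.
#' @param amplitude Band peak intensity above baseline (arbitrary units).
#' @param baseline Background intensity.
#' @param noise_sd SD of i.i.d. Gaussian pixel noise.
#' @param seed Integer RNG seed; identical seeds give identical images.
#' @return A `striation_truth` object (named list).
#' @export
striation_truth <- function(period_um = 1.8, jitter_sigma_um = 0,
                            orientation_deg = 0, band_sigma_um = 0.25,
                            amplitude = 1000, baseline = 200,
                            noise_sd = 0, seed = 1L) {
  assert_positive(period_um, "period_um")
  assert_nonneg(jitter_sigma_um, "jitter_sigma_um")
  assert_nonneg(noise_sd, "noise_sd")
  assert_positive(band_sigma_um, "band_sigma_um")
  structure(list(period_um = period_um, jitter_sigma_um = jitter_sigma_um,
                 orientation_deg = orientation_deg,
                 band_sigma_um = band_sigma_um, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "striation_truth")
}

#' Generate a synthetic striation image
#'
#' Renders `baseline + amplitude * sum_k exp(-(u - c_k)^2 / (2 band_sigma^2))`
#' over the pixel grid, where `u` is the coordinate along the band-normal
#' direction and the band centers `c_k = k * period + eps_k` carry i.i.d.
#' Gaussian positional jitter `eps_k ~ N(0, jitter_sigma^2)`; i.i.d. Gaussian
#' pixel noise is added last. The ground truth is attached to the result.
#'
#' @param truth A [striation_truth()] record.
#' @param shape Integer `c(n_rows, n_cols)` of the pixel grid.
#' @param pixel_size_um Pixel size (um/pixel).
#' @return A `striation_image`: list with `pixels` (matrix, rows = y),
#'   `pixel_size_um`, and the attached `truth`.
#' @export
generate_striation_image <- function(truth, shape = c(64L, 256L),
                                     pixel_size_um = 0.1) {
  stopifnot(inherits(truth, "striation_truth"))
  assert_positive(pixel_size_um, "pixel_size_um")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  th <- truth$orientation_deg * pi / 180
  x <- (seq_len(nc) - 1) * pixel_size_um
  y <- (seq_len(nr) - 1) * pixel_size_um
  # band-normal coordinate u = x cos(theta) + y sin(theta)
  u <- outer(y * sin(th), x * cos(th), "+")
  span <- diff(range(u))
  if (span < 10 * truth$period_um) {
    need <- ceiling(10 * truth$period_um / pixel_size_um /
                      max(abs(cos(th)), abs(sin(th))))
    abort(sprintf(
      "image spans %.1f um along the band normal; >= 10 periods (%.1f um) required (about %d px)",
      span, 10 * truth$period_um, need))
  }
  ks <- seq(floor(min(u) / truth$period_um) - 3,
            ceiling(max(u) / truth$period_um) + 3)
  img <- withr::with_seed(truth$seed, {
    eps <- if (truth$jitter_sigma_um > 0)
      rnorm(length(ks), 0, truth$jitter_sigma_um) else numeric(length(ks))
    centers <- ks * truth$period_um + eps
    acc <- matrix(0, nr, nc)
    s2 <- 2 * truth$band_sigma_um^2
    for (ci in centers) acc <- acc + exp(-(u - ci)^2 / s2)
    out <- truth$baseline + truth$amplitude * acc
    if (truth$noise_sd > 0) out <- out + rnorm(nr * nc, 0, truth$noise_sd)
    out
  })
  structure(list(pixels = img, pixel_size_um = pixel_size_um, truth = truth),
            class = "striation_image")
}

#' Construct a striation image from an existing pixel matrix
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y).
#' @param pixel_size_um Pixel size (um/pixel).
#' @param roi Optional `c(row0, row1, col0, col1)` half-open 0-based bounds.
#' @return A `striation_image`.
#' @export
striation_image <- function(pixels, pixel_size_um, roi = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  assert_positive(pixel_size_um, "pixel_size_um")
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4, roi[1] >= 0, roi[3] >= 0,
              roi[2] <= nrow(pixels), roi[4] <= ncol(pixels),
              roi[1] < roi[2], roi[3] < roi[4])
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, roi = roi),
            class = "striation_image")
}

#' @export
print.striation_image <- function(x, ...) {
  cat(sprintf("<striation_image> %d x %d px, %.3g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}
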