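#' 2D power spectrum of a striation image
#'
#' Applies the region of interest (if any), subtracts the mean, applies a
#' separable periodic Hann window, and computes the squared-magnitude 2D
#' discrete Fourier spectrum with frequency axes in cycles/um. The DC bin is
#' retained but flagged; all scoring downstream uses off-DC energy only.
#'
#' @param image A `striation_image`.
#' @return A `power_spectrum`: list with `power` (matrix, FFT bin order),
#'   `freq_row`, `freq_col` (cycles/um, signed), `pixel_size_um`,
#'   `windowed_energy` (sum of squared windowed intensities) and `no_signal`
#'   (TRUE when the image is constant).
#' @export
power_spectrum_2d <- function(image) {
  stopifnot(inherits(image, "striation_image"))
  px <- image$pixels
  if (!is.null(image$roi)) {
    r <- image$roi
    px <- px[(r[1] + 1):r[2], (r[3] + 1):r[4], drop = FALSE]
  }
  if (nrow(px) < 32 || ncol(px) < 32)
    abort("image (or ROI) must be at least 32 x 32 px")
  x <- px - mean(px)
  no_signal <- max(abs(x)) <= 1e-12 * max(abs(px), 1)
  w <- hann(nrow(px)) %o% hann(ncol(px))
  xw <- x * w
  F <- fft(xw)
  structure(list(power = Mod(F)^2, windowed = xw,
                 freq_row = fft_freq(nrow(px)) / image$pixel_size_um,
                 freq_col = fft_freq(ncol(px)) / image$pixel_size_um,
                 pixel_size_um = image$pixel_size_um,
                 windowed_energy = sum(xw^2),
                 no_signal = no_signal),
            class = "power_spectrum")
}

# bilinear interpolation of a spectrum at arbitrary (fy, fx), using the
# fftshift-sorted grid; points outside the grid are clamped to the border
interp_spectrum <- function(P, freq_row, freq_col, fy, fx) {
  oy <- order(freq_row); ox <- order(freq_col)
  gy <- freq_row[oy]; gx <- freq_col[ox]
  P <- P[oy, ox, drop = FALSE]
  iy <- findInterval(fy, gy, all.inside = TRUE)
  ix <- findInterval(fx, gx, all.inside = TRUE)
  ty <- pmin(pmax((fy - gy[iy]) / (gy[iy + 1] - gy[iy]), 0), 1)
  tx <- pmin(pmax((fx - gx[ix]) / (gx[ix + 1] - gx[ix]), 0), 1)
  P[cbind(iy, ix)] * (1 - ty) * (1 - tx) +
    P[cbind(iy + 1, ix)] * ty * (1 - tx) +
    P[cbind(iy, ix + 1)] * (1 - ty) * tx +
    P[cbind(iy + 1, ix + 1)] * ty * tx
}

#' Locate the primary spectral peak within a period band
#'
#' Searches the annulus of spatial frequencies corresponding to periods in
#' `band_um` over all orientations. The search runs on a 4x zero-padded
#' (sinc-interpolated) spectrum of the windowed image so closely spaced
#' local maxima are resolved; the radial frequency is then refined below
#' the padded-grid spacing by 3-point parabolic interpolation of the
#' log-power along the ray through the peak (ties broken toward lower
#' frequency, then smaller angle). The regularity score
#' (`peak_power_fraction`) is the energy in the 3x3 original-grid bin
#' neighborhood of the peak plus its Hermitian mirror, as a fraction of
#' total off-DC energy.
#'
#' @param spectrum A `power_spectrum` from [power_spectrum_2d()].
#' @param band_um Period search band `c(min_period, max_period)` in um.
#' @return A one-row tibble: `peak_frequency_cyc_per_um`, `orientation_deg`
#'   (band-normal angle in `[0, 180)`), `power` (peak power fraction in
#'   `[0, 1]`) and `no_signal`.
#' @export
find_primary_peak <- function(spectrum, band_um = c(1.2, 3.0), pad = 4L) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            length(band_um) == 2, band_um[1] > 0, band_um[1] < band_um[2])
  fr <- spectrum$freq_row; fc <- spectrum$freq_col
  lo <- 1 / band_um[2]; hi <- 1 / band_um[1]
  nyq <- min(max(abs(fr)), max(abs(fc)))
  if (lo > nyq)
    abort("period band lies outside the resolvable (Nyquist) frequency range")
  P <- spectrum$power
  off_dc <- sum(P) - P[1, 1]
  if (spectrum$no_signal || off_dc <= 0) {
    return(tibble::tibble(peak_frequency_cyc_per_um = NA_real_,
                          orientation_deg = NA_real_, power = 0,
                          no_signal = TRUE))
  }
  nr <- length(fr); nc <- length(fc)
  px_um <- spectrum$pixel_size_um
  # sinc-interpolated (zero-padded) spectrum for the peak search
  xp <- matrix(0, pad * nr, pad * nc)
  xp[seq_len(nr), seq_len(nc)] <- spectrum$windowed
  Pf <- Mod(fft(xp))^2
  ffr <- fft_freq(pad * nr) / px_um
  ffc <- fft_freq(pad * nc) / px_um
  Rf <- sqrt(outer(ffr^2, ffc^2, "+"))
  annf <- Rf >= lo & Rf <= hi
  if (!any(annf))
    abort("period band lies outside the resolvable (Nyquist) frequency range")
  Pm <- Pf
  Pm[!annf] <- -Inf
  best <- max(Pm)
  cand <- which(Pm >= best * (1 - 1e-12), arr.ind = TRUE)
  angs <- (atan2(ffr[cand[, 1]], ffc[cand[, 2]]) * 180 / pi) %% 180
  ordc <- order(Rf[cand], angs)
  i <- cand[ordc[1], 1]; j <- cand[ordc[1], 2]
  f0 <- c(ffr[i], ffc[j])                     # (fy, fx)
  r0 <- sqrt(sum(f0^2))
  ang <- (atan2(f0[1], f0[2]) * 180 / pi) %% 180
  ca <- f0[2] / r0; sa <- f0[1] / r0          # unit ray through the peak
  # radial step: one padded-grid bin equivalent along the ray
  delta <- sqrt((ca / (pad * nc * px_um))^2 + (sa / (pad * nr * px_um))^2)
  rs <- r0 + delta * c(-1, 0, 1)
  pv <- interp_spectrum(Pf, ffr, ffc, rs * sa, rs * ca)
  r_hat <- r0
  if (all(pv > 0) && pv[2] >= pv[1] && pv[2] >= pv[3]) {
    lp <- log(pv)
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < -1e-15) {
      h <- 0.5 * (lp[1] - lp[3]) / den
      r_hat <- r0 + max(min(h, 0.5), -0.5) * delta
    }
  }
  # polish to the continuum maximum of the windowed spectrum along the ray
  u <- outer((seq_len(nr) - 1) * px_um * sa, (seq_len(nc) - 1) * px_um * ca,
             "+")
  radial_mag <- function(f) Mod(sum(spectrum$windowed * exp(-2i * pi * f * u)))
  opt <- stats::optimize(radial_mag, lower = max(r0 - delta, lo),
                         upper = min(r0 + delta, hi), maximum = TRUE,
                         tol = delta * 1e-4)
  if (opt$objective >= radial_mag(r_hat)) r_hat <- opt$maximum
  # peak power fraction on the original grid: 3x3 neighborhood of the bin
  # nearest the refined peak, plus its Hermitian mirror, over off-DC energy
  i0 <- which.min(abs(fr - r_hat * sa))
  j0 <- which.min(abs(fc - r_hat * ca))
  neigh <- expand.grid(di = -1:1, dj = -1:1)
  ii <- ((i0 - 1 + neigh$di) %% nr) + 1
  jj <- ((j0 - 1 + neigh$dj) %% nc) + 1
  mi <- ((1 - ii) %% nr) + 1                   # Hermitian mirror indices
  mj <- ((1 - jj) %% nc) + 1
  idx <- unique(rbind(cbind(ii, jj), cbind(mi, mj)))
  idx <- idx[!(idx[, 1] == 1 & idx[, 2] == 1), , drop = FALSE]  # exclude DC
  frac <- sum(P[idx]) / off_dc
  tibble::tibble(peak_frequency_cyc_per_um = r_hat,
                 orientation_deg = ang,
                 power = min(max(frac, 0), 1),
                 no_signal = FALSE)
}

#' Score sarcomere organization of a striation image
#'
#' Composes [power_spectrum_2d()] and [find_primary_peak()]: the primary
#' off-DC peak of the windowed 2D power spectrum within the period band
#' gives the mean sarcomere length (`period_um = 1 / peak frequency`), the
#' band-normal orientation, and the regularity score `power` (peak-
#' neighborhood energy fraction of total off-DC energy, in `[0, 1]`; higher
#' means more organized striations).
#'
#' @param image A `striation_image`.
#' @param band_um Period search band in um (default 1.2-3.0, bracketing
#'   physiological sarcomere lengths).
#' @return A one-row tibble of class `sarcomere_score`: `power`,
#'   `period_um`, `orientation_deg`, `peak_frequency_cyc_per_um`,
#'   `no_signal`.
#' @export
score_sarcomere <- function(image, band_um = c(1.2, 3.0)) {
  spec <- power_spectrum_2d(image)
  pk <- find_primary_peak(spec, band_um = band_um)
  out <- tibble::tibble(power = pk$power,
                        period_um = 1 / pk$peak_frequency_cyc_per_um,
                        orientation_deg = pk$orientation_deg,
                        peak_frequency_cyc_per_um = pk$peak_frequency_cyc_per_um,
                        no_signal = pk$no_signal)
  tibble::new_tibble(out, class = "sarcomere_score")
}

#' Score every ROI of a set of striation images
#'
#' @param images A list of `striation_image` objects (optionally named).
#' @param rois Optional tibble `image, row0, row1, col0, col1` of half-open
#'   0-based ROIs; when absent each whole image is one ROI.
#' @param band_um Period search band in um.
#' @return A tibble `image, roi, power, period_um, orientation_deg`.
#' @export
score_sarcomeres <- function(images, rois = NULL, band_um = c(1.2, 3.0)) {
  if (inherits(images, "striation_image")) images <- list(images)
  nm <- names(images) %||% sprintf("image_%03d", seq_along(images))
  if (is.null(rois)) {
    rois <- tibble::tibble(image = nm, roi = 1L,
                           row0 = NA_integer_, row1 = NA_integer_,
                           col0 = NA_integer_, col1 = NA_integer_)
  } else {
    rois <- dplyr::mutate(dplyr::group_by(rois, .data$image),
                          roi = dplyr::row_number())
    rois <- dplyr::ungroup(rois)
  }
  purrr::pmap_dfr(rois, function(image, roi, row0, row1, col0, col1, ...) {
    img <- images[[image]]
    if (!is.na(row0))
      img <- striation_image(img$pixels, img$pixel_size_um,
                             roi = c(row0, row1, col0, col1))
    sc <- score_sarcomere(img, band_um = band_um)
    tibble::tibble(image = image, roi = roi, power = sc$power,
                   period_um = sc$period_um,
                   orientation_deg = sc$orientation_deg)
  })
}
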