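make_cosine_image <- function(n = 64, period_px = 10, pixel_size_um = 0.2) {
  x <- outer(rep(1, n), 0:(n - 1))
  striation_image(100 + 50 * cos(2 * pi * x / period_px),
                  pixel_size_um = pixel_size_um)
}

test_that("spectrum of a constant image is flagged and zero off DC", {
  img <- striation_image(matrix(5, 64, 64), pixel_size_um = 0.1)
  sp <- power_spectrum_2d(img)
  expect_true(sp$no_signal)
  off <- sp$power
  off[1, 1] <- 0
  expect_lt(max(off), 1e-18)
  sc <- score_sarcomere(img)
  expect_true(sc$no_signal)
  expect_equal(sc$power, 0)
})

test_that("spectrum satisfies Parseval against a direct O(N^2) DFT", {
  set.seed(42)
  px <- matrix(runif(32 * 32), 32, 32)
  img <- striation_image(px, pixel_size_um = 0.1)
  sp <- power_spectrum_2d(img)
  # windowed-image energy equals the spectrum mean
  expect_equal(sp$windowed_energy, mean(sp$power), tolerance = 1e-6)
  # and the spectrum itself matches the direct DFT of the windowed image
  x <- px - mean(px)
  hw <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  P_direct <- direct_dft_power(x * (hw(32) %o% hw(32)))
  expect_equal(sp$power, P_direct, tolerance = 1e-8)
})

test_that("pure cosine gives the exact period with high power", {
  img <- make_cosine_image(n = 80, period_px = 10, pixel_size_um = 0.2)
  sc <- score_sarcomere(img, band_um = c(1.2, 3.0))
  expect_equal(sc$period_um, 2.0, tolerance = 1e-3)
  expect_gte(sc$power, 0.9)
  expect_equal(sc$orientation_deg, 0, tolerance = 1e-6)
})

test_that("peak frequency matches the dense direct-DFT oracle on 32x32 combs", {
  for (seed in c(3, 4)) {
    tr <- striation_truth(period_um = 1.8, jitter_sigma_um = 0.25,
                          noise_sd = 30, seed = seed)
    img <- generate_striation_image(tr, shape = c(32, 32),
                                    pixel_size_um = 0.6)
    sc <- score_sarcomere(img, band_um = c(1.2, 3.0))
    f_oracle <- dense_dft_peak_freq(img$pixels, 0.6, c(1.2, 3.0),
                                    angles_deg = seq(0, 179, by = 1))
    fine_bin <- 1 / (32 * 0.6 * 10)
    expect_lt(abs(sc$peak_frequency_cyc_per_um - f_oracle), fine_bin / 2)
  }
})

test_that("score is invariant to intensity scaling", {
  tr <- striation_truth(period_um = 1.8, jitter_sigma_um = 0.2,
                        noise_sd = 40, seed = 9)
  img <- generate_striation_image(tr, shape = c(64, 256),
                                  pixel_size_um = 0.1)
  s1 <- score_sarcomere(img)
  img2 <- striation_image(img$pixels * 2.5, img$pixel_size_um)
  s2 <- score_sarcomere(img2)
  expect_equal(s1$power, s2$power, tolerance = 1e-9)
  expect_equal(s1$period_um, s2$period_um, tolerance = 1e-9)
  expect_equal(s1$orientation_deg, s2$orientation_deg, tolerance = 1e-9)
})

test_that("circular shifts barely change power and period", {
  # 1.6 um / 0.1 um = 16 px divides the 256 px width, so a circular shift
  # introduces no wrap seam and probes only the window interaction
  tr <- striation_truth(period_um = 1.6, jitter_sigma_um = 0,
                        noise_sd = 50, seed = 4)
  img <- generate_striation_image(tr, shape = c(64, 256),
                                  pixel_size_um = 0.1)
  s1 <- score_sarcomere(img)
  for (sh in c(7, 40, 100)) {
    shifted <- img$pixels[, c((sh + 1):256, 1:sh)]
    s2 <- score_sarcomere(striation_image(shifted, 0.1))
    expect_lt(abs(s2$power - s1$power) / s1$power, 0.01)
    bin_period <- s1$period_um^2 / (256 * 0.1)
    expect_lt(abs(s2$period_um - s1$period_um), bin_period / 2)
  }
})

test_that("rotating the image by 90 degrees rotates the orientation only", {
  tr <- striation_truth(period_um = 1.8, jitter_sigma_um = 0.15,
                        noise_sd = 20, seed = 6)
  img <- generate_striation_image(tr, shape = c(160, 160),
                                  pixel_size_um = 0.15)
  s1 <- score_sarcomere(img)
  rot <- t(img$pixels)[, rev(seq_len(nrow(img$pixels)))]  # 90 deg rotation
  s2 <- score_sarcomere(striation_image(rot, 0.15))
  expect_equal(s2$period_um, s1$period_um, tolerance = 1e-4)
  expect_equal(s2$power, s1$power, tolerance = 1e-4)
  expect_equal((s2$orientation_deg - s1$orientation_deg) %% 180, 90,
               tolerance = 1e-4)
})

test_that("period is recovered within one interpolated bin at low jitter", {
  for (period in c(1.6, 2.0)) {
    for (seed in 1:3) {
      tr <- striation_truth(period_um = period, jitter_sigma_um = 0.1,
                            amplitude = 1000, noise_sd = 100, seed = seed)
      img <- generate_striation_image(tr, shape = c(64, 256),
                                      pixel_size_um = 0.1)
      sc <- score_sarcomere(img)
      bin_period <- period^2 / (256 * 0.1)
      expect_lt(abs(sc$period_um - period), bin_period)
    }
  }
})

test_that("mean power decreases strictly with band jitter", {
  jitters <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  mean_power <- vapply(jitters, function(j) {
    mean(vapply(1:20, function(s) {
      tr <- striation_truth(period_um = 1.8, jitter_sigma_um = j,
                            noise_sd = 100, seed = s)
      img <- generate_striation_image(tr, shape = c(64, 256),
                                      pixel_size_um = 0.1)
      score_sarcomere(img)$power
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(mean_power, decreasing = TRUE), seq_along(jitters))
})

test_that("band outside the resolvable range errors; ROI scoring works", {
  img <- generate_striation_image(striation_truth(), shape = c(64, 256),
                                  pixel_size_um = 0.1)
  expect_error(find_primary_peak(power_spectrum_2d(img),
                                 band_um = c(0.05, 0.09)), "Nyquist")
  rois <- tibble::tibble(image = "image_001", row0 = 0L, row1 = 64L,
                         col0 = 0L, col1 = 128L)
  res <- score_sarcomeres(list(image_001 = img), rois = rois)
  expect_equal(nrow(res), 1)
  expect_equal(res$period_um, 1.8, tolerance = 0.05)
})
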