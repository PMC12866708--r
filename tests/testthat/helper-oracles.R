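# Independent oracles used across the suite. These deliberately avoid the
# package's own FFT/matching code paths.

# direct O(N^2) 2D DFT squared magnitude (matrix DFT product)
direct_dft_power <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  W1 <- exp(-2i * pi * outer(0:(n1 - 1), 0:(n1 - 1)) / n1)
  W2 <- exp(-2i * pi * outer(0:(n2 - 1), 0:(n2 - 1)) / n2)
  Mod(W1 %*% x %*% W2)^2
}

# dense direct DFT magnitude over a polar grid; returns the argmax radial
# frequency (cycles/um). Applies the same Hann window + mean subtraction as
# the analysis (it is an oracle for the windowed spectrum's peak) but sums
# the DFT directly.
dense_dft_peak_freq <- function(pixels, pixel_size_um, band_um,
                                angles_deg = seq(0, 175, by = 5),
                                refine = 10) {
  x <- pixels - mean(pixels)
  hw <- function(n) if (n == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  xw <- x * (hw(nrow(x)) %o% hw(ncol(x)))
  X <- outer(rep(1, nrow(x)), (seq_len(ncol(x)) - 1) * pixel_size_um)
  Y <- outer((seq_len(nrow(x)) - 1) * pixel_size_um, rep(1, ncol(x)))
  fine_bin <- 1 / (max(dim(x)) * pixel_size_um * refine)
  radii <- seq(1 / band_um[2], 1 / band_um[1], by = fine_bin)
  best <- c(val = -Inf, freq = NA)
  for (a in angles_deg * pi / 180) {
    u <- X * cos(a) + Y * sin(a)
    for (f in radii) {
      m <- Mod(sum(xw * exp(-2i * pi * f * u)))
      if (m > best["val"]) best <- c(val = m, freq = f)
    }
  }
  unname(best["freq"])
}

# FFT-upsampled cross-correlation displacement between two frames
# (phase-correlation style oracle, independent of the block matcher)
upsampled_shift_oracle <- function(a, b, upsample = 10) {
  a <- a - mean(a); b <- b - mean(b)
  Fa <- fft(a); Fb <- fft(b)
  R <- Fb * Conj(Fa)
  n1 <- nrow(a); n2 <- ncol(a)
  N1 <- n1 * upsample; N2 <- n2 * upsample
  # zero-pad the cross-spectrum symmetrically (sinc interpolation of the
  # correlation surface)
  P <- matrix(0 + 0i, N1, N2)
  h1 <- ceiling(n1 / 2); h2 <- ceiling(n2 / 2)
  P[1:h1, 1:h2] <- R[1:h1, 1:h2]
  P[1:h1, (N2 - (n2 - h2) + 1):N2] <- R[1:h1, (h2 + 1):n2]
  P[(N1 - (n1 - h1) + 1):N1, 1:h2] <- R[(h1 + 1):n1, 1:h2]
  P[(N1 - (n1 - h1) + 1):N1, (N2 - (n2 - h2) + 1):N2] <- R[(h1 + 1):n1, (h2 + 1):n2]
  cc <- Re(fft(P, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sy <- unname(pk[1]) - 1; sx <- unname(pk[2]) - 1
  if (sy > N1 / 2) sy <- sy - N1
  if (sx > N2 / 2) sx <- sx - N2
  c(dy = sy / upsample, dx = sx / upsample)
}

# threshold-crossing beat counter on a noiseless trace (detection oracle)
threshold_beat_count <- function(values, diastolic, amplitude) {
  lvl <- diastolic + amplitude / 2
  above <- values > lvl
  sum(diff(above) == 1) + as.integer(above[1])
}

# balanced two-way ANOVA via base R aov (cross-check route)
aov_two_way <- function(df) {
  fit <- stats::aov(value ~ factor_a * factor_b, data = df)
  as.data.frame(summary(fit)[[1]])
}

# exact circular sub-pixel shift via the Fourier phase ramp
fourier_shift <- function(x, dy, dx) {
  n1 <- nrow(x); n2 <- ncol(x)
  ky <- (((0:(n1 - 1)) + floor(n1 / 2)) %% n1) - floor(n1 / 2)
  kx <- (((0:(n2 - 1)) + floor(n2 / 2)) %% n2) - floor(n2 / 2)
  ph <- exp(-2i * pi * (outer(ky, rep(1, n2)) * dy / n1 +
                          outer(rep(1, n1), kx) * dx / n2))
  Re(fft(fft(x) * ph, inverse = TRUE)) / (n1 * n2)
}

# circularly smooth band-limited random texture
circular_texture <- function(n = 64, seed = 1, bandwidth = 200) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(n * n), n, n)
    fr <- (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n
    H <- exp(-outer(fr^2, fr^2, "+") * bandwidth)
    tex <- Re(fft(fft(w) * H, inverse = TRUE)) / (n * n)
    (tex - min(tex)) / (max(tex) - min(tex))
  })
}
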