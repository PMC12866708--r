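#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib cardiofunc, .registration = TRUE
#' @importFrom rlang .data abort %||%
#' @importFrom stats fft mad median quantile rnorm runif sd var qnorm pf pt
#'   coef fitted resid lm
NULL

# signed DFT sample frequencies (cycles per sample), fft bin order
fft_freq <- function(n) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n
}

# periodic Hann window
hann <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

# lower/upper truncated normal draws via inverse-CDF (exact, vectorized)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

#' @importFrom stats pnorm
NULL

# separable Gaussian blur with replicate edge padding
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
  }
  out <- apply(mat, 2, conv1)
  t(apply(out, 1, conv1))
}

# bilinear sampling of `mat` at fractional (row, col) positions, replicate edges
bilinear_sample <- function(mat, rows, cols) {
  nr <- nrow(mat); nc <- ncol(mat)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- as.vector(rows - r0); fc <- as.vector(cols - c0)
  rv <- as.vector(r0); cv <- as.vector(c0)
  i00 <- cbind(rv, cv); i10 <- cbind(rv + 1, cv)
  i01 <- cbind(rv, cv + 1); i11 <- cbind(rv + 1, cv + 1)
  v <- mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
  matrix(v, nrow = nrow(rows), ncol = ncol(rows))
}

# robust SD of additive noise from the scaled MAD of first differences
robust_noise_sd <- function(x) {
  mad(diff(x)) / sqrt(2)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    abort(paste0("`", name, "` must be a positive finite number"))
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    abort(paste0("`", name, "` must be a non-negative finite number"))
  invisible(x)
}
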