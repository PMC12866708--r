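#' Ground-truth parameters for a synthetic beating-monolayer video
#'
#' The video is a static band-pass noise texture warped by a displacement
#' field `d(x, t) = m(x) * s(t) * u_hat`, where `m(x)` is a smooth spatial
#' mask occupying `beating_area_fraction` of the frame, `u_hat` a fixed unit
#' direction, and `s(t)` a per-beat raised-cosine displacement pulse whose
#' time derivative attains `+peak_contraction_velocity_um_s` during the rise
#' and `-peak_relaxation_velocity_um_s` during the (slower or faster) fall.
#'
#' @param peak_contraction_velocity_um_s Peak contraction speed (um/s).
#' @param peak_relaxation_velocity_um_s Peak relaxation speed (um/s).
#' @param beat_rate_hz Beat frequency (Hz).
#' @param beating_area_fraction Fraction of the frame that moves, in `[0, 1]`.
#' @param pixel_size_um Pixel size (um/pixel).
#' @param frame_interval_s Frame interval (s).
#' @param seed Integer RNG seed.
#' @return A `motion_truth` object.
#' @export
motion_truth <- function(peak_contraction_velocity_um_s = 10,
                         peak_relaxation_velocity_um_s = 5,
                         beat_rate_hz = 1, beating_area_fraction = 1,
                         pixel_size_um = 0.8, frame_interval_s = 0.05,
                         seed = 1L) {
  vc <- peak_contraction_velocity_um_s
  vr <- peak_relaxation_velocity_um_s
  if (vc < 0 || vr < 0 || xor(vc == 0, vr == 0))
    abort("peak velocities must both be positive, or both zero (static video)")
  if (beating_area_fraction < 0 || beating_area_fraction > 1)
    abort("beating_area_fraction must lie in [0, 1]")
  assert_positive(beat_rate_hz, "beat_rate_hz")
  assert_positive(pixel_size_um, "pixel_size_um")
  assert_positive(frame_interval_s, "frame_interval_s")
  structure(list(peak_contraction_velocity_um_s = vc,
                 peak_relaxation_velocity_um_s = vr,
                 beat_rate_hz = beat_rate_hz,
                 beating_area_fraction = beating_area_fraction,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 seed = as.integer(seed)),
            class = "motion_truth")
}

# displacement pulse s(t) in um; raised-cosine rise over t_c then fall over
# t_r, active for the first half of each beat period
motion_pulse <- function(t, truth) {
  vc <- truth$peak_contraction_velocity_um_s
  vr <- truth$peak_relaxation_velocity_um_s
  if (vc == 0 && vr == 0) return(numeric(length(t)))
  period <- 1 / truth$beat_rate_hz
  D <- period / (pi * (1 / vc + 1 / vr))  # so that t_c + t_r = period / 2
  t_c <- D * pi / (2 * vc)
  t_r <- D * pi / (2 * vr)
  ph <- t %% period
  s <- numeric(length(t))
  up <- ph < t_c
  dn <- ph >= t_c & ph < t_c + t_r
  s[up] <- D * (1 - cos(pi * ph[up] / t_c)) / 2
  s[dn] <- D * (1 + cos(pi * (ph[dn] - t_c) / t_r)) / 2
  s
}

#' Generate a synthetic beating-monolayer video
#'
#' @param truth A [motion_truth()] record.
#' @param shape Integer `c(n_rows, n_cols)` of each frame.
#' @param n_frames Number of frames; must cover at least 2 beats.
#' @param direction_deg Motion direction, degrees from the x-axis.
#' @return A `motion_video`: list with `frames` (rows x cols x n_frames
#'   array, intensities in `[0, 1]`), `pixel_size_um`, `frame_interval_s`,
#'   the attached `truth`, the smooth `mask`, and ground-truth per-frame-pair
#'   `truth_speed_um_s` (mean speed) and `truth_velocity_um_s` (signed).
#' @export
generate_motion_video <- function(truth, shape = c(64L, 64L), n_frames = 50L,
                                  direction_deg = 20) {
  stopifnot(inherits(truth, "motion_truth"))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  dt <- truth$frame_interval_s
  if (n_frames * dt < 2 / truth$beat_rate_hz)
    abort("n_frames must cover at least 2 beats")
  t <- (seq_len(n_frames) - 1) * dt
  s <- motion_pulse(t, truth)
  disp_px <- s / truth$pixel_size_um
  if (max(abs(disp_px)) > min(nr, nc) / 4)
    abort(sprintf(
      "peak displacement %.1f px exceeds a quarter of the frame size (%d px)",
      max(abs(disp_px)), min(nr, nc) %/% 4L))

  texture <- withr::with_seed(truth$seed, {
    w <- matrix(rnorm(nr * nc), nr, nc)
    bp <- gauss_blur(w, 1.5) - gauss_blur(w, 6)  # correlation length ~ 4 px
    bp <- (bp - mean(bp)) / sd(bp)
    pmin(pmax(0.5 + 0.15 * bp, 0), 1)
  })

  frac <- truth$beating_area_fraction
  if (frac >= 1) {
    mask <- matrix(1, nr, nc)
  } else if (frac <= 0) {
    mask <- matrix(0, nr, nc)
  } else {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    d <- sqrt(outer(((seq_len(nr) - cy))^2, ((seq_len(nc) - cx))^2, "+"))
    r <- sqrt(frac * nr * nc / pi)
    mask <- 1 / (1 + exp(d - r))  # ~1 px soft edge
  }

  ux <- cos(direction_deg * pi / 180)
  uy <- sin(direction_deg * pi / 180)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  frames <- array(0, dim = c(nr, nc, n_frames))
  for (k in seq_len(n_frames)) {
    if (disp_px[k] == 0) {
      frames[, , k] <- texture
    } else {
      dyk <- mask * disp_px[k] * uy
      dxk <- mask * disp_px[k] * ux
      frames[, , k] <- bilinear_sample(texture, rows - dyk, cols - dxk)
    }
  }
  mm <- mean(mask)
  truth_velocity <- mm * diff(s) / dt
  structure(list(frames = frames, pixel_size_um = truth$pixel_size_um,
                 frame_interval_s = dt, truth = truth, mask = mask,
                 truth_speed_um_s = abs(truth_velocity),
                 truth_velocity_um_s = truth_velocity,
                 pulse_um = s),
            class = "motion_video")
}

#' Construct a motion video from a frame array
#'
#' @param frames Numeric array `rows x cols x n_frames` (>= 3 frames).
#' @param pixel_size_um Pixel size (um/pixel).
#' @param frame_interval_s Frame interval (s).
#' @return A `motion_video`.
#' @export
motion_video <- function(frames, pixel_size_um, frame_interval_s) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[3] >= 3)
  assert_positive(pixel_size_um, "pixel_size_um")
  assert_positive(frame_interval_s, "frame_interval_s")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "motion_video")
}

#' @export
print.motion_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<motion_video> %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}
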