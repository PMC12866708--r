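#' Block-matching displacement field between two frames
#'
#' Tiles `frame_a` into `block_px` blocks (with a `search_px` margin so
#' every candidate patch stays inside the frame) and, for each block with
#' intensity variance at least `texture_floor`, finds the integer
#' displacement maximizing the normalized cross-correlation against
#' `frame_b` within `+/- search_px`, refined to sub-pixel precision by
#' separable 3-point parabolic interpolation of the correlation surface.
#' Perfect (correlation 1) matches are kept integer. Ties break toward the
#' smaller displacement magnitude, then lexicographically (row, col).
#'
#' @param frame_a,frame_b Numeric matrices of identical dimensions.
#' @param block_px Block size in pixels (>= 8 advised; default 16).
#' @param search_px Search radius in pixels (default 7).
#' @param texture_floor Minimum per-pixel intensity variance for a block to
#'   be considered textured enough to match.
#' @return A tibble with one row per block: `block_row`, `block_col`,
#'   `row0`, `col0` (0-based top-left corner), `dy_px`, `dx_px`, `mag_px`,
#'   `ncc`, `valid`.
#' @export
block_displacement <- function(frame_a, frame_b, block_px = 16L,
                               search_px = 7L, texture_floor = 1e-8) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b))
  if (!all(dim(frame_a) == dim(frame_b)))
    abort("frames must have identical dimensions")
  res <- bm_block_match(frame_a, frame_b, as.integer(block_px),
                        as.integer(search_px), texture_floor)
  nbr <- length(res$row0); nbc <- length(res$col0)
  tibble::tibble(
    block_row = rep(seq_len(nbr), times = nbc),
    block_col = rep(seq_len(nbc), each = nbr),
    row0 = rep(res$row0, times = nbc),
    col0 = rep(res$col0, each = nbr),
    dy_px = as.vector(res$dy_px),
    dx_px = as.vector(res$dx_px),
    mag_px = sqrt(as.vector(res$dy_px)^2 + as.vector(res$dx_px)^2),
    ncc = as.vector(res$ncc),
    valid = as.vector(res$valid))
}

#' Frame-to-frame mean displacement velocity of a beating video
#'
#' For each adjacent frame pair, the mean displacement magnitude over valid
#' (textured) blocks is scaled by `pixel_size_um / frame_interval_s` to a
#' speed in um/s. Pairs in which every block is invalid are flagged gaps
#' (NA speed).
#'
#' @param video A `motion_video`.
#' @inheritParams block_displacement
#' @return A `velocity_trace` tibble `time_s, mean_speed_um_s` (length
#'   `n_frames - 1`; `time_s` is the midpoint of each frame pair), with the
#'   per-pair displacement fields in the `fields` attribute and acquisition
#'   metadata attached.
#' @export
velocity_trace <- function(video, block_px = 16L, search_px = 7L,
                           texture_floor = 1e-8) {
  stopifnot(inherits(video, "motion_video"))
  nf <- dim(video$frames)[3]
  fields <- vector("list", nf - 1)
  speed <- numeric(nf - 1)
  for (k in seq_len(nf - 1)) {
    fld <- block_displacement(video$frames[, , k], video$frames[, , k + 1],
                              block_px = block_px, search_px = search_px,
                              texture_floor = texture_floor)
    fields[[k]] <- fld
    ok <- fld$valid
    speed[k] <- if (any(ok)) mean(fld$mag_px[ok]) *
      video$pixel_size_um / video$frame_interval_s else NA_real_
  }
  out <- tibble::new_tibble(
    tibble::tibble(time_s = (seq_len(nf - 1) - 0.5) * video$frame_interval_s,
                   mean_speed_um_s = speed),
    class = "velocity_trace")
  attr(out, "fields") <- fields
  attr(out, "pixel_size_um") <- video$pixel_size_um
  attr(out, "frame_interval_s") <- video$frame_interval_s
  attr(out, "n_gaps") <- sum(is.na(speed))
  out
}

# local maxima of v with prominence >= prom_min
speed_peaks <- function(v, prom_min) {
  n <- length(v)
  if (n < 3) return(integer())
  cand <- which(v > c(-Inf, v[-n]) & v >= c(v[-1], -Inf))
  cand <- cand[cand > 1 & cand < n]
  if (!length(cand)) return(integer())
  cand[peak_prominences(v, cand) >= prom_min]
}

# vertex value of the parabola through a peak sample and its neighbors:
# recovers the underlying speed maximum lost to frame-interval sampling
refine_peak_value <- function(v, p) {
  if (p <= 1 || p >= length(v)) return(v[p])
  den <- v[p - 1] - 2 * v[p] + v[p + 1]
  if (den >= -1e-15) return(v[p])
  v[p] - (v[p - 1] - v[p + 1])^2 / (8 * den)
}

# width of the peak at half its prominence, in samples
half_prom_width <- function(v, p, prom) {
  lvl <- v[p] - prom / 2
  l <- p; while (l > 1 && v[l] > lvl) l <- l - 1
  r <- p; n <- length(v); while (r < n && v[r] > lvl) r <- r + 1
  r - l
}

#' Per-beat contraction/relaxation kinetics from a velocity trace
#'
#' Beats are segmented as episodes where the mean speed exceeds
#' `quiescence_frac` of the global maximum. Within each episode the first
#' prominent speed peak is the contraction peak and the last the relaxation
#' peak; durations are widths at half of each peak's prominence. The
#' beating-area fraction is the fraction of valid blocks whose maximum
#' per-beat displacement exceeds `area_threshold_px`. Per-video values are
#' means over beats.
#'
#' @param vel A `velocity_trace` (with its `fields` attribute).
#' @param quiescence_frac Fraction of the global speed maximum below which
#'   the monolayer is considered quiescent.
#' @param area_threshold_px Displacement threshold (px) defining a "beating"
#'   block.
#' @return A one-row tibble of class `beat_kinetics`:
#'   `contraction_peak_um_s`, `relaxation_peak_um_s`,
#'   `contraction_duration_s`, `relaxation_duration_s`,
#'   `beating_area_fraction`, `n_beats`.
#' @export
beat_kinetics <- function(vel, quiescence_frac = 0.1,
                          area_threshold_px = 0.2) {
  stopifnot(inherits(vel, "velocity_trace"))
  v <- vel$mean_speed_um_s
  dt <- attr(vel, "frame_interval_s")
  empty <- tibble::new_tibble(
    tibble::tibble(contraction_peak_um_s = NA_real_,
                   relaxation_peak_um_s = NA_real_,
                   contraction_duration_s = NA_real_,
                   relaxation_duration_s = NA_real_,
                   beating_area_fraction = NA_real_, n_beats = 0L),
    class = "beat_kinetics")
  if (all(is.na(v))) return(empty)
  vmax <- max(v, na.rm = TRUE)
  if (vmax <= 0) return(empty)
  thr <- quiescence_frac * vmax
  active <- !is.na(v) & v >= thr
  # the speed passes through zero between the contraction and relaxation
  # phases of one beat: bridge quiescent gaps much shorter than the longest
  # (inter-beat) gap so a beat episode stays in one piece
  g <- rle(active)
  gaps <- g$lengths[!g$values]
  if (length(gaps) > 1) {
    short <- max(2L, floor(0.5 * max(gaps)))
    pos <- cumsum(g$lengths)
    for (i in seq_along(g$lengths)) {
      if (!g$values[i] && g$lengths[i] < short && i > 1 && i < length(g$lengths))
        active[(pos[i] - g$lengths[i] + 1):pos[i]] <- TRUE
    }
  }
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  eps <- which(runs$values)
  con_pk <- rel_pk <- con_du <- rel_du <- area <- numeric(0)
  fields <- attr(vel, "fields")
  for (e in eps) {
    i0 <- starts[e]; i1 <- ends[e]
    seg <- v[i0:i1]
    pks <- speed_peaks(seg, prom_min = 0.05 * vmax)
    if (!length(pks)) {
      if (length(seg) < 2) next
      pks <- which.max(seg)
    }
    p_con <- pks[1]; p_rel <- pks[length(pks)]
    proms <- peak_prominences(seg, c(p_con, p_rel))
    con_pk <- c(con_pk, refine_peak_value(seg, p_con))
    rel_pk <- c(rel_pk, refine_peak_value(seg, p_rel))
    con_du <- c(con_du, half_prom_width(seg, p_con, proms[1]) * dt)
    rel_du <- c(rel_du, half_prom_width(seg, p_rel, proms[2]) * dt)
    if (!is.null(fields)) {
      mags <- purrr::map(fields[i0:i1], function(f) ifelse(f$valid, f$mag_px, NA))
      mmax <- purrr::reduce(mags, pmax, na.rm = TRUE)
      ok <- fields[[i0]]$valid
      area <- c(area, mean(mmax[ok] > area_threshold_px, na.rm = TRUE))
    }
  }
  if (!length(con_pk)) return(empty)
  tibble::new_tibble(
    tibble::tibble(contraction_peak_um_s = mean(con_pk),
                   relaxation_peak_um_s = mean(rel_pk),
                   contraction_duration_s = mean(con_du),
                   relaxation_duration_s = mean(rel_du),
                   beating_area_fraction = if (length(area)) mean(area) else NA_real_,
                   n_beats = length(con_pk)),
    class = "beat_kinetics")
}

#' Analyze one beating video end to end
#'
#' Convenience wrapper composing [velocity_trace()] and [beat_kinetics()].
#'
#' @inheritParams velocity_trace
#' @inheritParams beat_kinetics
#' @return A one-row `beat_kinetics` tibble.
#' @export
analyze_motion_video <- function(video, block_px = 16L, search_px = 7L,
                                 texture_floor = 1e-8, quiescence_frac = 0.1,
                                 area_threshold_px = 0.2) {
  beat_kinetics(velocity_trace(video, block_px = block_px,
                               search_px = search_px,
                               texture_floor = texture_floor),
                quiescence_frac = quiescence_frac,
                area_threshold_px = area_threshold_px)
}
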