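#' Compute the F340/F380 ratio trace
#'
#' Elementwise ratio of the two Fura-2 excitation channels. The F380 channel
#' is checked against a floor after light smoothing (5-sample moving
#' average) so isolated noise dips do not abort the run, but a genuinely
#' degenerate denominator raises an error naming the first offending sample.
#'
#' @param trace A `ratiometric_trace`.
#' @param f380_floor Minimum admissible smoothed F380 value.
#' @return A ratio-valued `fluorescence_trace`.
#' @export
compute_ratio <- function(trace, f380_floor = 0) {
  stopifnot(inherits(trace, "ratiometric_trace"))
  f380s <- as.numeric(stats::filter(trace$f380, rep(1 / 5, 5), sides = 2))
  f380s[is.na(f380s)] <- trace$f380[is.na(f380s)]
  bad <- which(f380s <= f380_floor)
  if (length(bad) > 0)
    abort(sprintf("F380 channel at or below floor %.3g at sample %d (t = %.3f s)",
                  f380_floor, bad[1], trace$time_s[bad[1]]))
  out <- fluorescence_trace(trace$time_s, trace$f340 / trace$f380,
                            units = "ratio")
  attr(out, "truth") <- attr(trace, "truth")
  attr(out, "onsets_s") <- attr(trace, "onsets_s")
  out
}

# prominence of each local maximum: height above the higher of the two
# minima separating it from higher terrain (or the trace ends)
peak_prominences <- function(v, peaks) {
  vapply(peaks, function(p) {
    l <- p; lmin <- v[p]
    while (l > 1 && v[l] <= v[p]) { l <- l - 1; lmin <- min(lmin, v[l]) }
    if (v[l] <= v[p]) lmin <- min(v[seq_len(p)])
    r <- p; rmin <- v[p]
    n <- length(v)
    while (r < n && v[r] <= v[p]) { r <- r + 1; rmin <- min(rmin, v[r]) }
    if (v[r] <= v[p]) rmin <- min(v[p:n])
    v[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect calcium transients in a fluorescence trace
#'
#' Peaks are local maxima with prominence at least `k` times the robust
#' noise SD (scaled median absolute deviation of the first differences).
#' Peaks closer than a refractory window (`0.25 / expected rate`) are
#' merged, keeping the higher. In paced mode the search is windowed around
#' multiples of the pacing period (at most one peak per pacing cycle). The
#' onset of each beat is the last crossing of `diastolic + 10% amplitude`
#' before its peak.
#'
#' @param trace A `fluorescence_trace` (use [compute_ratio()] first for
#'   ratiometric data).
#' @param rhythm `"spontaneous"` or `"paced"`.
#' @param pacing_hz Pacing frequency (required for paced rhythm).
#' @param k Prominence threshold in robust noise SDs.
#' @return A tibble `beat, onset_idx, peak_idx, onset_time_s, peak_time_s`;
#'   zero rows (flagged via the `empty` attribute) when no beats are found.
#' @export
detect_transients <- function(trace, rhythm = c("spontaneous", "paced"),
                              pacing_hz = NULL, k = 5) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  rhythm <- match.arg(rhythm)
  if (rhythm == "paced" && is.null(pacing_hz))
    abort("pacing_hz is required for paced rhythm")
  v <- trace$f
  t <- trace$time_s
  fs <- attr(trace, "sampling_hz")
  empty <- function() {
    out <- tibble::tibble(beat = integer(), onset_idx = integer(),
                          peak_idx = integer(), onset_time_s = numeric(),
                          peak_time_s = numeric())
    attr(out, "empty") <- TRUE
    out
  }
  n <- length(v)
  if (n < 5 || diff(range(v)) == 0) return(empty())
  noise <- robust_noise_sd(v)
  cand <- which(v > c(v[1] - 1, v[-n]) & v >= c(v[-1], v[n] - 1))
  cand <- cand[cand > 1 & cand < n]
  if (length(cand) == 0) return(empty())
  prom <- peak_prominences(v, cand)
  thr <- max(k * noise, 1e-3 * diff(range(v)), .Machine$double.eps)
  keep <- cand[prom >= thr]
  if (length(keep) == 0) return(empty())

  if (rhythm == "paced") {
    period <- 1 / pacing_hz
    cycle <- floor(t[keep] / period)
    keep <- vapply(split(keep, cycle), function(ix) ix[which.max(v[ix])],
                   integer(1))
    keep <- sort(unname(keep))
  } else {
    refr <- if (length(keep) > 1) 0.25 * median(diff(t[keep])) else 0
    merged <- keep[1]
    for (p in keep[-1]) {
      if (t[p] - t[merged[length(merged)]] < refr) {
        if (v[p] > v[merged[length(merged)]]) merged[length(merged)] <- p
      } else merged <- c(merged, p)
    }
    keep <- merged
  }

  onsets <- integer(length(keep))
  for (b in seq_along(keep)) {
    p <- keep[b]
    seg_start <- if (b == 1) 1L else keep[b - 1]
    # robust diastolic estimate over the later part of the inter-peak
    # segment: a low quantile sits on the settled baseline rather than on
    # the decay tail or the next rise
    mid <- seg_start + (p - seg_start) %/% 2L
    base <- quantile(v[mid:p], 0.2, names = FALSE)
    lvl <- base + 0.1 * (v[p] - base)
    below <- which(v[seg_start:p] <= lvl)
    onsets[b] <- if (length(below)) seg_start + max(below) - 1L else seg_start
  }
  tibble::tibble(beat = seq_along(keep), onset_idx = onsets, peak_idx = keep,
                 onset_time_s = t[onsets], peak_time_s = t[keep])
}

fit_decay <- function(tt, yy) {
  C0 <- min(yy)
  A0 <- max(yy[1] - C0, .Machine$double.eps)
  drop_i <- which(yy - C0 <= A0 / exp(1))
  tau0 <- if (length(drop_i)) max(tt[drop_i[1]], diff(range(tt)) / 10)
          else diff(range(tt)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau) + C,
                      start = list(A = A0, tau = tau0, C = C0),
                      lower = c(0, 1e-4, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  list(tau = coef(fit)[["tau"]], r2 = min(r2, 1))
}

#' Extract per-cell calcium transient features
#'
#' Single-channel traces are first normalized to F/F0 with F0 taken as the
#' 10th percentile of the trace; ratio traces are used as-is (ratio units
#' are already concentration-calibrated up to a constant). Features:
#' diastolic level (median over inter-beat baselines, last 25\% of each
#' inter-beat interval), amplitude (mean peak minus preceding diastolic),
#' rise time (mean onset-to-peak), decay tau (mean of per-beat
#' mono-exponential `A exp(-t/tau) + C` fits from peak to next onset; fits
#' with r-squared below `min_fit_r2` are excluded), and beat rate from the
#' peak-to-peak span.
#'
#' @param trace A `fluorescence_trace`.
#' @param beats Beat table from [detect_transients()]; detected on the fly
#'   when `NULL`.
#' @param rhythm,pacing_hz Passed to [detect_transients()] when needed.
#' @param normalize `"auto"` normalizes unless the trace units are
#'   `"ratio"`; `TRUE`/`FALSE` force the choice.
#' @param min_fit_r2 Minimum per-beat decay-fit r-squared retained.
#' @return A one-row tibble: `beat_rate_bpm`, `amplitude`, `rise_time_s`,
#'   `decay_tau_s`, `diastolic_level`, `n_beats`, `fit_r2`, `reason`
#'   (NA when features are valid).
#' @export
extract_features <- function(trace, beats = NULL,
                             rhythm = c("spontaneous", "paced"),
                             pacing_hz = NULL, normalize = "auto",
                             min_fit_r2 = 0.8) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  rhythm <- match.arg(rhythm)
  if (is.null(beats))
    beats <- detect_transients(trace, rhythm = rhythm, pacing_hz = pacing_hz)
  missing_row <- function(reason, n_beats = nrow(beats)) {
    tibble::tibble(beat_rate_bpm = NA_real_, amplitude = NA_real_,
                   rise_time_s = NA_real_, decay_tau_s = NA_real_,
                   diastolic_level = NA_real_, n_beats = n_beats,
                   fit_r2 = NA_real_, reason = reason)
  }
  if (nrow(beats) < 2) return(missing_row("fewer than 2 beats detected"))

  do_norm <- if (identical(normalize, "auto"))
    !identical(attr(trace, "units"), "ratio") else isTRUE(normalize)
  v <- trace$f
  if (do_norm) {
    f0 <- quantile(v, 0.10, names = FALSE)
    if (f0 <= 0) return(missing_row("non-positive F0 baseline"))
    v <- v / f0
  }
  t <- trace$time_s
  nb <- nrow(beats)

  # per-interval diastolic: last 25 % of each inter-beat (onset-to-onset)
  # interval, i.e. the samples just before each onset from the 2nd on
  dia_seg <- vapply(seq_len(nb - 1), function(b) {
    i0 <- beats$onset_idx[b]; i1 <- beats$onset_idx[b + 1]
    lo <- i1 - max(1L, floor(0.25 * (i1 - i0)))
    median(v[max(lo, i0):i1])
  }, numeric(1))
  diastolic <- median(dia_seg)
  # diastolic preceding each beat (first beat: its own onset neighborhood)
  dia_before <- c(if (nb >= 2) dia_seg[1] else diastolic, dia_seg)
  dia_before[1] <- median(v[max(1, beats$onset_idx[1] - 5):beats$onset_idx[1]])

  amp <- mean(v[beats$peak_idx] - dia_before[seq_len(nb)])
  rise <- mean(beats$peak_time_s - beats$onset_time_s)

  fits <- purrr::compact(purrr::map(seq_len(nb), function(b) {
    # start one sample after the peak: with finite sampling the maximal
    # sample can sit on the rising ramp, and any suffix of the decay is
    # still a clean mono-exponential
    i0 <- beats$peak_idx[b] + 1L
    i1 <- if (b < nb) {
      beats$onset_idx[b + 1] - 1L
    } else {
      # a further beat whose peak lies beyond the trace end may have begun;
      # stop the window at the minimum so its rise never contaminates the fit
      i0 - 1L + which.min(v[i0:length(v)])
    }
    if (i1 - i0 < 4) return(NULL)
    fit_decay(t[i0:i1] - t[i0], v[i0:i1])
  }))
  taus <- purrr::map_dbl(fits, "tau")
  r2s <- purrr::map_dbl(fits, "r2")
  ok <- r2s >= min_fit_r2
  if (!any(ok)) return(missing_row("no acceptable decay fits"))

  tibble::tibble(
    beat_rate_bpm = 60 * (nb - 1) /
      (beats$peak_time_s[nb] - beats$peak_time_s[1]),
    amplitude = amp,
    rise_time_s = rise,
    decay_tau_s = mean(taus[ok]),
    diastolic_level = diastolic,
    n_beats = nb,
    fit_r2 = mean(r2s[ok]),
    reason = NA_character_)
}

#' Analyze one calcium trace end to end
#'
#' Convenience wrapper: ratio computation (if ratiometric), transient
#' detection, and feature extraction.
#'
#' @inheritParams extract_features
#' @param trace A `fluorescence_trace` or `ratiometric_trace`.
#' @return A one-row `TransientFeatures` tibble (see [extract_features()]).
#' @export
analyze_calcium_trace <- function(trace, rhythm = c("spontaneous", "paced"),
                                  pacing_hz = NULL, normalize = "auto",
                                  min_fit_r2 = 0.8) {
  rhythm <- match.arg(rhythm)
  if (inherits(trace, "ratiometric_trace")) trace <- compute_ratio(trace)
  extract_features(trace, rhythm = rhythm, pacing_hz = pacing_hz,
                   normalize = normalize, min_fit_r2 = min_fit_r2)
}
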