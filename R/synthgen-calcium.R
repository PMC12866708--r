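#' Ground-truth parameters for a synthetic calcium transient trace
#'
#' Each beat is a linear rise to `amplitude` over `rise_time_s` followed by a
#' mono-exponential decay with time constant `decay_tau_s`, superimposed on a
#' diastolic baseline. Two kinetic invariants are enforced so transients
#' resolve between beats and are well sampled:
#' `rise_time_s + 3 * decay_tau_s < 1 / beat_rate_hz` and
#' `sampling_hz >= 20 * beat_rate_hz`.
#'
#' @param mode `"single_channel"` (Fluo-4-like, arbitrary F units) or
#'   `"ratiometric"` (Fura-2-like F340/F380 ratio units).
#' @param rhythm `"spontaneous"` (jittered inter-beat intervals) or `"paced"`
#'   (beat onsets at exact multiples of `1 / beat_rate_hz`).
#' @param beat_rate_hz Beat frequency (Hz).
#' @param amplitude Transient amplitude: dF/F0 units (single channel) or
#'   ratio units (ratiometric).
#' @param rise_time_s Linear rise duration, onset to peak (s).
#' @param decay_tau_s Mono-exponential decay time constant (s).
#' @param diastolic_level Baseline: F0 units (single channel, default 1) or
#'   diastolic ratio (ratiometric, e.g. 0.5).
#' @param noise_sd SD of additive Gaussian noise, trace units.
#' @param duration_s Trace duration (s).
#' @param sampling_hz Sampling rate (Hz).
#' @param seed Integer RNG seed.
#' @return A `transient_truth` object.
#' @export
transient_truth <- function(mode = c("single_channel", "ratiometric"),
                            rhythm = c("spontaneous", "paced"),
                            beat_rate_hz = 0.5, amplitude = 1,
                            rise_time_s = 0.1, decay_tau_s = 0.4,
                            diastolic_level = if (match.arg(mode) == "ratiometric") 0.5 else 1,
                            noise_sd = 0, duration_s = 20,
                            sampling_hz = 50, seed = 1L) {
  mode <- match.arg(mode)
  rhythm <- match.arg(rhythm)
  assert_positive(beat_rate_hz, "beat_rate_hz")
  assert_nonneg(amplitude, "amplitude")
  assert_positive(rise_time_s, "rise_time_s")
  assert_positive(decay_tau_s, "decay_tau_s")
  assert_nonneg(noise_sd, "noise_sd")
  assert_positive(duration_s, "duration_s")
  assert_positive(sampling_hz, "sampling_hz")
  if (rise_time_s + 3 * decay_tau_s >= 1 / beat_rate_hz)
    abort(sprintf(
      "kinetic invariant violated: rise_time_s + 3*decay_tau_s = %.3f s must be < 1/beat_rate_hz = %.3f s",
      rise_time_s + 3 * decay_tau_s, 1 / beat_rate_hz))
  if (sampling_hz < 20 * beat_rate_hz)
    abort("sampling_hz must be >= 20 * beat_rate_hz")
  structure(list(mode = mode, rhythm = rhythm, beat_rate_hz = beat_rate_hz,
                 amplitude = amplitude, rise_time_s = rise_time_s,
                 decay_tau_s = decay_tau_s, diastolic_level = diastolic_level,
                 noise_sd = noise_sd, duration_s = duration_s,
                 sampling_hz = sampling_hz, seed = as.integer(seed)),
            class = "transient_truth")
}

transient_kernel <- function(s, amplitude, rise, tau) {
  out <- numeric(length(s))
  up <- s >= 0 & s < rise
  dn <- s >= rise
  out[up] <- amplitude * s[up] / rise
  out[dn] <- amplitude * exp(-(s[dn] - rise) / tau)
  out
}

#' Generate a synthetic calcium transient trace
#'
#' Builds `diastolic + sum over beats of kernel(t - onset) + noise`. Paced
#' rhythm places beat onsets at exact multiples of the pacing period;
#' spontaneous rhythm jitters inter-beat intervals with coefficient of
#' variation `interbeat_cv`. In ratiometric mode the ratio signal `R(t)` is
#' factorized as a constant-mean F380 channel (with its own small noise) and
#' `F340 = R(t) * F380`, so that `F340 / F380` reconstructs `R(t)` exactly.
#'
#' @param truth A [transient_truth()] record.
#' @param interbeat_cv Inter-beat interval CV for spontaneous rhythm.
#' @param f380_mean,f380_noise_sd Mean and noise SD of the synthetic F380
#'   channel (ratiometric mode only).
#' @return A tibble of class `fluorescence_trace` (`time_s`, `f`) or
#'   `ratiometric_trace` (`time_s`, `f340`, `f380`), with attributes
#'   `sampling_hz`, `truth` and `onsets_s` (true beat onset times).
#' @export
generate_calcium_trace <- function(truth, interbeat_cv = 0.05,
                                   f380_mean = 1000, f380_noise_sd = 5) {
  stopifnot(inherits(truth, "transient_truth"))
  fs <- truth$sampling_hz
  t <- seq(0, truth$duration_s - 1 / fs, by = 1 / fs)
  period <- 1 / truth$beat_rate_hz
  res <- withr::with_seed(truth$seed, {
    onsets <- if (truth$rhythm == "paced") {
      seq(0, truth$duration_s - 1e-9, by = period)
    } else {
      iv <- period * (1 + interbeat_cv * rnorm(ceiling(truth$duration_s / period) + 5))
      iv <- pmax(iv, truth$rise_time_s + 3 * truth$decay_tau_s)
      on <- cumsum(c(0, iv))
      on[on < truth$duration_s]
    }
    r <- rep(truth$diastolic_level, length(t))
    for (on in onsets)
      r <- r + transient_kernel(t - on, truth$amplitude,
                                truth$rise_time_s, truth$decay_tau_s)
    if (truth$noise_sd > 0) r <- r + rnorm(length(t), 0, truth$noise_sd)
    if (truth$mode == "ratiometric") {
      f380 <- f380_mean + if (f380_noise_sd > 0)
        rnorm(length(t), 0, f380_noise_sd) else 0
      list(onsets = onsets, f340 = r * f380, f380 = f380)
    } else {
      list(onsets = onsets, f = r)
    }
  })
  if (truth$mode == "ratiometric") {
    out <- tibble::tibble(time_s = t, f340 = res$f340, f380 = res$f380)
    out <- tibble::new_tibble(out, class = "ratiometric_trace")
  } else {
    out <- tibble::tibble(time_s = t, f = res$f)
    out <- tibble::new_tibble(out, class = "fluorescence_trace")
  }
  attr(out, "sampling_hz") <- fs
  attr(out, "truth") <- truth
  attr(out, "onsets_s") <- res$onsets
  out
}

#' Construct a fluorescence trace from time and value vectors
#'
#' @param time_s Uniformly spaced sample times (s).
#' @param values Fluorescence (or ratio) values.
#' @param units Label for the value units (informational).
#' @return A `fluorescence_trace` tibble with a `sampling_hz` attribute.
#' @export
fluorescence_trace <- function(time_s, values, units = "au") {
  stopifnot(length(time_s) == length(values), all(is.finite(values)))
  dt <- diff(time_s)
  if (length(dt) > 0 && diff(range(dt)) > 1e-6)
    abort("time_s must be uniformly sampled (to 1e-6 s)")
  out <- tibble::new_tibble(tibble::tibble(time_s = time_s, f = values),
                            class = "fluorescence_trace")
  attr(out, "sampling_hz") <- if (length(dt)) 1 / mean(dt) else NA_real_
  attr(out, "units") <- units
  out
}

#' Construct a ratiometric (F340/F380) trace
#'
#' @param time_s Uniform sample times (s).
#' @param f340,f380 Channel values (same length as `time_s`).
#' @return A `ratiometric_trace` tibble with a `sampling_hz` attribute.
#' @export
ratiometric_trace <- function(time_s, f340, f380) {
  stopifnot(length(time_s) == length(f340), length(f340) == length(f380))
  dt <- diff(time_s)
  if (length(dt) > 0 && diff(range(dt)) > 1e-6)
    abort("time_s must be uniformly sampled (to 1e-6 s)")
  out <- tibble::new_tibble(tibble::tibble(time_s = time_s, f340 = f340,
                                           f380 = f380),
                            class = "ratiometric_trace")
  attr(out, "sampling_hz") <- if (length(dt)) 1 / mean(dt) else NA_real_
  out
}
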