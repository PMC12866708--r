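#' Define a two-factor synthetic study design
#'
#' A design is a tibble with one row per factor combination (`genotype` x
#' `treatment`) holding the per-cell parameter distributions (mean + SD,
#' truncated-Normal draws at physical bounds) for the calcium, striation and
#' motion generators, plus the per-group sample size and a seed.
#'
#' @param params Tibble with columns `genotype`, `treatment` and the
#'   `<param>_mean` / `<param>_sd` columns used by
#'   [generate_group_dataset()]. See [pln_stress_design()] for the shape.
#' @param n_per_group Cells per factor combination (>= 2).
#' @param seed Integer RNG seed.
#' @return A `group_design` object.
#' @export
group_design <- function(params, n_per_group = 50L, seed = 1L) {
  stopifnot(is.data.frame(params),
            all(c("genotype", "treatment") %in% names(params)))
  if (n_per_group < 2) abort("n_per_group must be >= 2")
  combos <- with(expand.grid(genotype = unique(params$genotype),
                             treatment = unique(params$treatment)),
                 paste(genotype, treatment))
  have <- paste(params$genotype, params$treatment)
  if (!all(combos %in% have))
    abort(paste("missing factor combinations:",
                paste(setdiff(combos, have), collapse = ", ")))
  sds <- params[grepl("_sd$", names(params))]
  if (any(vapply(sds, function(x) any(x <= 0), logical(1))))
    abort("all parameter SDs must be positive")
  structure(list(params = tibble::as_tibble(params),
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "group_design")
}

#' A corrected-vs-mutant under metabolic stress design
#'
#' Default 2x2 design emulating a genotype (isogenic corrected `Corr` vs
#' mutant `PA`) by treatment (baseline `Base` vs metabolic stress medium
#' `MM`) experiment. Under stress the mutant is programmed with reduced
#' transient amplitude (-30\%), elevated diastolic level (+20\%), slowed
#' calcium reuptake (decay tau +30\%), reduced contraction/relaxation peak
#' velocities (-30\%) and increased striation jitter (reduced sarcomere
#' organization); the remaining groups share control parameters.
#'
#' @param n_per_group Cells per group.
#' @param seed Integer RNG seed.
#' @return A `group_design`.
#' @export
pln_stress_design <- function(n_per_group = 50L, seed = 1L) {
  base <- tibble::tibble(
    amplitude_mean = 0.60, amplitude_sd = 0.09,
    diastolic_mean = 0.50, diastolic_sd = 0.05,
    tau_mean = 0.40, tau_sd = 0.05,
    rise_mean = 0.12, rise_sd = 0.02,
    ca_rate_mean = 0.40, ca_rate_sd = 0.04,
    period_mean = 1.8, period_sd = 0.05,
    jitter_mean = 0.10, jitter_sd = 0.02,
    vc_mean = 10, vc_sd = 1.5,
    vr_mean = 6, vr_sd = 1.0,
    motion_rate_mean = 1.0, motion_rate_sd = 0.05
  )
  params <- dplyr::bind_rows(
    dplyr::mutate(base, genotype = "Corr", treatment = "Base"),
    dplyr::mutate(base, genotype = "PA", treatment = "Base"),
    dplyr::mutate(base, genotype = "Corr", treatment = "MM"),
    dplyr::mutate(base, genotype = "PA", treatment = "MM",
                  amplitude_mean = 0.42,  # -30 %
                  diastolic_mean = 0.60,  # +20 %
                  tau_mean = 0.52,        # +30 %
                  vc_mean = 7, vr_mean = 4.2,  # -30 %
                  jitter_mean = 0.30)     # disorganized sarcomeres
  )
  group_design(params, n_per_group = n_per_group, seed = seed)
}

#' Generate a synthetic per-cell study dataset
#'
#' For each factor combination, draws `n_per_group` per-cell parameter sets
#' from the design's truncated-Normal distributions and materializes raw data
#' with the per-modality generators. The returned truth table records the
#' drawn (true) per-cell parameters; analysis code operates only on the raw
#' data.
#'
#' @param design A [group_design()].
#' @param modalities Any of `"calcium"`, `"striation"`, `"motion"`.
#' @param snr_db Amplitude-to-noise-SD ratio, dB, for calcium traces.
#' @param pacing_hz Field-pacing frequency of the ratiometric protocol.
#' @param striation_shape,striation_pixel_um Striation image geometry.
#' @param motion_shape,motion_frames Motion video geometry.
#' @param ca_duration_s,ca_sampling_hz Calcium trace geometry.
#' @return A list with `truth` (tibble of per-cell true parameters) and
#'   `data` (tibble with `cell_id`, factors, and list-columns of raw
#'   objects).
#' @export
generate_group_dataset <- function(design,
                                   modalities = c("calcium", "striation", "motion"),
                                   snr_db = 20,
                                   striation_shape = c(64L, 256L),
                                   striation_pixel_um = 0.1,
                                   motion_shape = c(64L, 64L),
                                   motion_frames = 50L,
                                   ca_duration_s = 20,
                                   ca_sampling_hz = 50,
                                   pacing_hz = 0.5) {
  stopifnot(inherits(design, "group_design"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  n <- design$n_per_group
  p <- design$params

  draws <- withr::with_seed(design$seed, {
    purrr::pmap(p, function(...) {
      row <- list(...)
      d <- tibble::tibble(
        genotype = row$genotype, treatment = row$treatment,
        amplitude = rnorm_trunc(n, row$amplitude_mean, row$amplitude_sd, lower = 0.05),
        diastolic = rnorm_trunc(n, row$diastolic_mean, row$diastolic_sd, lower = 0.1),
        rise = rnorm_trunc(n, row$rise_mean, row$rise_sd, lower = 0.04, upper = 0.2),
        ca_rate = rnorm_trunc(n, row$ca_rate_mean, row$ca_rate_sd,
                              lower = 0.25, upper = 0.55),
        period = rnorm_trunc(n, row$period_mean, row$period_sd, lower = 1.3, upper = 2.8),
        jitter = rnorm_trunc(n, row$jitter_mean, row$jitter_sd, lower = 0.01),
        vc = rnorm_trunc(n, row$vc_mean, row$vc_sd, lower = 0.5),
        vr = rnorm_trunc(n, row$vr_mean, row$vr_sd, lower = 0.5),
        motion_rate = rnorm_trunc(n, row$motion_rate_mean, row$motion_rate_sd,
                                  lower = 0.9, upper = 1.2),
        cell_seed = sample.int(2^30, n)
      )
      # decay tau truncated so each cell satisfies the kinetic invariant
      # at the pacing rate used for the ratiometric recordings
      d$tau <- purrr::map_dbl(seq_len(n), function(i) {
        upper <- 0.95 * (1 / 0.5 - d$rise[i]) / 3
        rnorm_trunc(1, row$tau_mean, row$tau_sd, lower = 0.05, upper = upper)
      })
      d
    })
  })
  truth <- dplyr::bind_rows(draws)
  truth$cell_id <- sprintf("cell_%03d", seq_len(nrow(truth)))
  truth <- dplyr::relocate(truth, "cell_id")

  noise_factor <- 10^(-snr_db / 20)
  data <- truth[c("cell_id", "genotype", "treatment")]
  if ("calcium" %in% modalities) {
    data$calcium <- purrr::pmap(truth, function(...) {
      r <- list(...)
      generate_calcium_trace(transient_truth(
        mode = "ratiometric", rhythm = "paced",
        beat_rate_hz = pacing_hz, amplitude = r$amplitude,
        rise_time_s = r$rise, decay_tau_s = r$tau,
        diastolic_level = r$diastolic,
        noise_sd = r$amplitude * noise_factor,
        duration_s = ca_duration_s, sampling_hz = ca_sampling_hz,
        seed = r$cell_seed))
    })
  }
  if ("striation" %in% modalities) {
    data$striation <- purrr::pmap(truth, function(...) {
      r <- list(...)
      generate_striation_image(striation_truth(
        period_um = r$period, jitter_sigma_um = r$jitter,
        amplitude = 1000, baseline = 200, noise_sd = 100,
        seed = r$cell_seed + 1L),
        shape = striation_shape, pixel_size_um = striation_pixel_um)
    })
  }
  if ("motion" %in% modalities) {
    data$motion <- purrr::pmap(truth, function(...) {
      r <- list(...)
      generate_motion_video(motion_truth(
        peak_contraction_velocity_um_s = r$vc,
        peak_relaxation_velocity_um_s = r$vr,
        beat_rate_hz = r$motion_rate, beating_area_fraction = 1,
        seed = r$cell_seed + 2L),
        shape = motion_shape, n_frames = motion_frames)
    })
  }
  list(truth = truth, data = data)
}
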