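#' Read a single-channel TIFF as a striation image
#'
#' Grayscale 8/16-bit TIFFs only; RGB or float images are rejected unless
#' `convert = TRUE`, which averages channels. Physical units always come
#' from the caller (file resolution tags are instrument-dependent).
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size (um/pixel).
#' @param roi Optional `c(row0, row1, col0, col1)` half-open 0-based ROI.
#' @param convert Allow RGB/float input by channel averaging.
#' @return A `striation_image` (intensities in `[0, 1]`).
#' @export
read_striation_tiff <- function(path, pixel_size_um, roi = NULL,
                                convert = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3) {
    if (!convert)
      abort("multi-channel TIFF; pass convert = TRUE to average channels")
    img <- apply(img, c(1, 2), mean)
  }
  striation_image(img, pixel_size_um = pixel_size_um, roi = roi)
}

#' Read a multi-page TIFF as a motion video
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size (um/pixel).
#' @param frame_interval_s Frame interval (s).
#' @param convert Allow RGB input by channel averaging.
#' @return A `motion_video` (intensities in `[0, 1]`).
#' @export
read_motion_tiff <- function(path, pixel_size_um, frame_interval_s,
                             convert = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (!convert)
        abort("multi-channel TIFF; pass convert = TRUE to average channels")
      p <- apply(p, c(1, 2), mean)
    }
    p
  })
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  motion_video(frames, pixel_size_um = pixel_size_um,
               frame_interval_s = frame_interval_s)
}

# scale a matrix into [0, 1] for 16-bit TIFF storage
scale_unit <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

#' Write a striation image as a 16-bit grayscale TIFF
#'
#' Intensities are rescaled to `[0, 1]` and quantized to 16 bits; the
#' round trip is idempotent (reading and re-writing reproduces the file)
#' but the quantization step means arbitrary intensities are only preserved
#' to one part in 65535 of their range.
#'
#' @param image A `striation_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_striation_tiff <- function(image, path) {
  stopifnot(inherits(image, "striation_image"))
  tiff::writeTIFF(scale_unit(image$pixels), path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a motion video as a multi-page 16-bit TIFF
#'
#' @param video A `motion_video`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_tiff <- function(video, path) {
  stopifnot(inherits(video, "motion_video"))
  rng <- range(video$frames)
  fr <- if (diff(rng) == 0) video$frames * 0
        else (video$frames - rng[1]) / diff(rng)
  pages <- purrr::map(seq_len(dim(fr)[3]), function(k) fr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a fluorescence or ratiometric trace as CSV
#'
#' Header `time_s,f` (single channel) or `time_s,f340,f380` (ratiometric);
#' '.' decimal, UTF-8.
#'
#' @param trace A `fluorescence_trace` or `ratiometric_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read a trace CSV
#'
#' Accepts `time_s,f` or `time_s,f340,f380` headers (an optional leading
#' `cell_id` column turns the result into a list of per-cell traces).
#'
#' @param path CSV file path.
#' @return A `fluorescence_trace`, a `ratiometric_trace`, or a named list
#'   of them when a `cell_id` column is present.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  build <- function(d) {
    if (all(c("f340", "f380") %in% names(d)))
      ratiometric_trace(d$time_s, d$f340, d$f380)
    else if ("f" %in% names(d))
      fluorescence_trace(d$time_s, d$f)
    else abort("expected columns time_s,f or time_s,f340,f380")
  }
  if ("cell_id" %in% names(df)) {
    purrr::map(split(df, df$cell_id), build)
  } else {
    build(df)
  }
}
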