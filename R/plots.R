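#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_col geom_errorbar labs theme_minimal scale_fill_viridis_c
#'   position_dodge geom_vline
#' @export
ggplot2::autoplot

#' Plot a fluorescence trace with detected transients
#'
#' @param object A `fluorescence_trace`.
#' @param beats Optional beat table from [detect_transients()]; peaks and
#'   onsets are overlaid when supplied.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fluorescence_trace
#' @export
autoplot.fluorescence_trace <- function(object, beats = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$f)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)",
         y = if (identical(attr(object, "units"), "ratio"))
           "F340/F380 ratio" else "fluorescence (a.u.)") +
    theme_minimal()
  if (!is.null(beats) && nrow(beats) > 0) {
    pk <- tibble::tibble(t = beats$peak_time_s,
                         f = object$f[beats$peak_idx], what = "peak")
    on <- tibble::tibble(t = beats$onset_time_s,
                         f = object$f[beats$onset_idx], what = "onset")
    p <- p + geom_point(data = rbind(pk, on),
                        aes(x = .data$t, y = .data$f, colour = .data$what),
                        inherit.aes = FALSE, size = 1.5)
  }
  p
}

#' Plot a displacement-velocity trace
#'
#' @param object A `velocity_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot velocity_trace
#' @export
autoplot.velocity_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$mean_speed_um_s)) +
    geom_line() +
    labs(x = "time (s)", y = "mean displacement speed (um/s)") +
    theme_minimal()
}

#' Plot a striation image
#'
#' @param object A `striation_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot striation_image
#' @export
autoplot.striation_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$intensity <- as.vector(t(px))[(df$row - 1) * ncol(px) + df$col]
  ggplot(df, aes(x = .data$col * object$pixel_size_um,
                 y = .data$row * object$pixel_size_um,
                 fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "x (um)", y = "y (um)", fill = "intensity") +
    theme_minimal()
}

#' Bar-and-error plot of per-group means with SEM
#'
#' @param data A data frame.
#' @param value Response column name.
#' @param ... Grouping columns (first is mapped to x, second to fill).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(data, value = "value", ...) {
  sm <- summarize_groups(data, {{ value }}, ...)
  gcols <- setdiff(names(sm), c("mean", "sem", "n"))
  p <- if (length(gcols) >= 2) {
    ggplot(sm, aes(x = .data[[gcols[1]]], y = .data$mean,
                   fill = .data[[gcols[2]]]))
  } else {
    ggplot(sm, aes(x = .data[[gcols[1]]], y = .data$mean))
  }
  p + geom_col(position = position_dodge(0.9), width = 0.8) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(0.9), width = 0.25) +
    labs(y = "mean +/- SEM") +
    theme_minimal()
}
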