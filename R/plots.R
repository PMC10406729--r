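#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_tile
#'   scale_y_reverse labs theme_minimal facet_wrap scale_fill_viridis_c
#'   scale_x_reverse
NULL

#' @export
ggplot2::autoplot

#' Plot an HSQC image in conventional spectrum orientation
#'
#' Raster view of the gridded spectrum with ppm axes increasing towards
#' the top-left, channels facetted for multiplicity-edited input.
#'
#' @param object an `hsqc_image`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hsqc_image <- function(object, ...) {
  b <- object$bounds
  d <- dim(object$grid)
  df <- do.call(rbind, lapply(seq_len(d[3]), function(ch) {
    data.frame(
      h = b$h_max - (rep(seq_len(d[2]), each = d[1]) - 0.5) / d[2] *
        (b$h_max - b$h_min),
      c = b$c_max - (rep(seq_len(d[1]), times = d[2]) - 0.5) / d[1] *
        (b$c_max - b$c_min),
      value = as.vector(object$grid[, , ch]),
      channel = paste0("channel ", ch)
    )
  }))
  p <- ggplot(df, aes(x = .data$h, y = .data$c, fill = .data$value)) +
    geom_raster() +
    scale_x_reverse() + scale_y_reverse() +
    scale_fill_viridis_c() +
    labs(x = "1H shift (ppm)", y = "13C shift (ppm)", fill = "intensity") +
    theme_minimal()
  if (d[3] > 1) p <- p + facet_wrap(~channel)
  p
}

#' Plot a training history
#'
#' Training and validation loss per epoch.
#'
#' @param object an `hsqc_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hsqc_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("epoch", "loss", "val_loss")],
    -"epoch", names_to = "series", values_to = "value"
  )
  ggplot(h, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' Heatmap of peak-to-atom attributions
#'
#' The peaks x atoms matrix of an occlusion analysis, as in a
#' spectrum-to-substructure correlation heatmap.
#'
#' @param object an `atom_attribution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.atom_attribution <- function(object, ...) {
  df <- tidy.atom_attribution(object)
  ggplot(df, aes(x = .data$atom, y = .data$peak, fill = .data$score)) +
    geom_tile() +
    scale_fill_viridis_c() +
    scale_y_reverse() +
    labs(x = "atom index", y = "peak index", fill = "attribution") +
    theme_minimal()
}
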