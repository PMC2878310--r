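#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chromatogram with optional de-noised overlay and peak region
#'
#' Raw trace in red, de-noised trace in blue, the integrated region shaded in
#' green and the background level in cyan — the conventional colouring for
#' isotope-pair quantification review.
#'
#' @param object A [chromatogram()].
#' @param denoised Optional de-noised trace to overlay.
#' @param region Optional peak-region row to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatogram <- function(object, denoised = NULL, region = NULL, ...) {
  df <- tibble::tibble(rt = object$rt, intensity = object$intensity)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line(colour = "red", linewidth = 0.3) +
    ggplot2::labs(x = "retention time (s)", y = "intensity")
  if (!is.null(region) && !is.null(denoised)) {
    idx <- which(object$scan >= region$start_scan & object$scan <= region$end_scan)
    bg <- if (is.na(region$background)) 0 else region$background
    shade <- tibble::tibble(
      rt = object$rt[idx], ymin = bg, ymax = pmax(denoised[idx], bg)
    )
    p <- p + ggplot2::geom_ribbon(
      data = shade,
      ggplot2::aes(x = .data$rt, ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = "green", alpha = 0.35
    ) +
      ggplot2::geom_hline(yintercept = bg, colour = "cyan3", linetype = 2)
  }
  if (!is.null(denoised)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(rt = object$rt, intensity = denoised),
      colour = "blue", linewidth = 0.5
    )
  }
  p
}

#' Plot the outlier-elimination audit of a protein quantification
#'
#' Peptide ratios as points (survivors filled, eliminated open) with each
#' round's acceptance interval as a horizontal band and the final protein
#' ratio as a dashed line.
#'
#' @param object A `protein_quant` from [protein_ratio()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_quant <- function(object, ...) {
  pts <- tibble::tibble(
    idx = seq_along(object$ratios), ratio = object$ratios,
    survivor = object$surviving
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$idx, y = .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$survivor), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_hline(
      yintercept = object$final_ratio, linetype = 2, colour = "blue"
    ) +
    ggplot2::labs(
      x = "peptide", y = "light/heavy ratio",
      title = if (!is.na(object$protein)) object$protein else NULL
    )
  if (nrow(object$rounds)) {
    bands <- dplyr::mutate(object$rounds,
      xmin = 0.5, xmax = nrow(pts) + 0.5
    )
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$lower, ymax = .data$upper
      ),
      inherit.aes = FALSE, fill = "grey60", alpha = 0.15
    )
  }
  p
}
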