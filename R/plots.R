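# Quality-control plots.

#' Plot a phantom radiograph with its ground-truth knee boxes
#'
#' @param record One-row cohort tibble from [generate_phantom()] /
#'   [generate_cohort()].
#' @return A ggplot object.
#' @export
plot_radiograph <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  img <- record$image[[1]]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.numeric(img)[(df$col - 1) * nrow(img) + df$row]
  boxes <- bind_rows(
    as_tibble(as.list(record$truth_left[[1]])),
    as_tibble(as.list(record$truth_right[[1]]))
  )
  boxes$side <- c("left", "right")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_rect(data = boxes, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$col_start + 0.5,
                                    xmax = .data$col_end + 0.5,
                                    ymin = .data$row_start + 0.5,
                                    ymax = .data$row_end + 0.5,
                                    color = .data$side),
                       fill = NA, linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s  (KL left %d, right %d)",
                                  record$patient_id, record$grade_left,
                                  record$grade_right),
                  x = NULL, y = NULL, color = NULL) +
    ggplot2::theme_void()
}

#' Plot an isolated knee slice
#'
#' @param pixels `224 x 224` matrix in `[0, 1]`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(pixels, title = NULL) {
  assert_gray_image(pixels, "pixels")
  df <- tidyr::expand_grid(row = seq_len(nrow(pixels)), col = seq_len(ncol(pixels)))
  df$value <- as.numeric(pixels)[(df$col - 1) * nrow(pixels) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
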