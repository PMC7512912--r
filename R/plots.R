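# ggplot2 views of profiles and similarity maps.

#' @describeIn compress_dna Plot the (optionally smoothed) information
#'   profile of a compression result.
#' @param object A `compression_result`.
#' @param window Smoothing window passed to [smooth_profile()].
#' @param ... Unused.
#' @export
autoplot.compression_result <- function(object, window = 501L, ...) {
  df <- tibble::tibble(position = seq_along(object$bits) - 1L,
                       bits = smooth_profile(object$bits, window))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "position", y = "bits / symbol",
                  title = paste0("Information profile (", object$mode, ")")) +
    ggplot2::theme_minimal()
  if (!is.na(object$boundary))
    p <- p + ggplot2::geom_vline(xintercept = object$boundary,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' @describeIn similarity_map Ribbon-style plot of a similarity map:
#'   smoothed profiles for both sides with detected segments shaded.
#' @param object A `similarity_map`.
#' @param ... Unused.
#' @export
autoplot.similarity_map <- function(object, ...) {
  prof <- dplyr::bind_rows(
    tibble::tibble(side = paste0("x: ", object$ids[["x"]]),
                   position = seq_along(object$profile_x) - 1L,
                   bits = object$profile_x),
    tibble::tibble(side = paste0("y: ", object$ids[["y"]]),
                   position = seq_along(object$profile_y) - 1L,
                   bits = object$profile_y))
  segs <- dplyr::bind_rows(
    dplyr::mutate(object$segments_x, side = paste0("x: ", object$ids[["x"]])),
    dplyr::mutate(object$segments_y, side = paste0("y: ", object$ids[["y"]])))
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dotted") +
    ggplot2::facet_wrap(~side, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position", y = "bits / symbol") +
    ggplot2::theme_minimal()
  if (nrow(segs))
    p <- p + ggplot2::geom_rect(
      data = segs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.25)
  p
}

#' Plot measure curves from an experiment sweep
#'
#' Lines of measure value against substitution rate (or mutation multiple),
#' one line per measure / slope.
#'
#' @param curve A tibble with a rate-like first column and one or more
#'   measure columns, as returned by [sweep_substitution_rates()] or
#'   [nrc_expectation_curve()].
#' @return A ggplot.
#' @export
plot_measure_curve <- function(curve) {
  xvar <- names(curve)[1]
  long <- tidyr_pivot(curve, xvar)
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(y = "measure value") +
    ggplot2::theme_minimal()
}

# minimal long-format pivot over the numeric measure columns
tidyr_pivot <- function(df, xvar) {
  cols <- setdiff(names(df), xvar)
  cols <- cols[vapply(df[cols], is.numeric, logical(1))]
  purrr::map_dfr(cols, function(cn) {
    out <- tibble::tibble(x = df[[xvar]], series = cn, value = df[[cn]])
    names(out)[1] <- xvar
    out
  })
}
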