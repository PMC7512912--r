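# Information-profile tools: smoothing, low-information segmentation and
# two-way similarity maps between sequences.

profile_bits <- function(x) {
  if (inherits(x, "compression_result")) x$bits else as.numeric(x)
}

#' Smooth an information profile
#'
#' Centered moving average with edge truncation: near the boundaries the
#' window shrinks to the available positions, so the output has the same
#' length as the input.
#'
#' @param profile A `compression_result` or numeric bits vector.
#' @param window Odd window length (`>= 1`).
#' @return Numeric vector of smoothed bits.
#' @export
smooth_profile <- function(profile, window = 501L) {
  bits <- profile_bits(profile)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be an odd length >= 1")
  n <- length(bits)
  if (window == 1L || n == 0L) return(bits)
  half <- window %/% 2L
  cs <- cumsum(c(0, bits))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment low-information (similar) regions
#'
#' Maximal runs of positions whose profile value is strictly below
#' `threshold`, discarding runs shorter than `min_len`. Segments are
#' non-overlapping, sorted, and use 0-based half-open coordinates.
#'
#' @param profile A (typically smoothed) numeric bits vector or
#'   `compression_result`.
#' @param threshold Bits threshold (> 0); positions below it count as
#'   similar. The default 1.5 sits between the worst excursions of a
#'   genuinely similar region (mutated copies drift up to ~1.4 bits after
#'   smoothing) and the floor of unrelated uniform DNA (~1.8 bits), so
#'   copies at a few percent substitutions are kept whole while unrelated
#'   sequence never qualifies.
#' @param min_len Minimum segment length in positions.
#' @return A tibble with columns `start`, `end`, `length`, `mean_bits`.
#' @export
segment_low_information <- function(profile, threshold = 1.5, min_len = 100L) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  bits <- profile_bits(profile)
  below <- bits < threshold
  if (!any(below))
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), mean_bits = numeric()))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(
    start = starts[keep] - 1L,
    end = ends[keep],
    length = r$lengths[keep],
    mean_bits = vapply(which(keep), function(i)
      mean(bits[starts[i]:ends[i]]), numeric(1)))
}

#' Two-way similarity map between two sequences
#'
#' Computes the relative information profiles `C(x||y)` and `C(y||x)`,
#' smooths each and segments the low-information regions on both sides.
#' The two segment lists are reported side by side; no pairing of
#' individual segments is attempted (the coder keeps no positional
#' traceback into the reference).
#'
#' @param x,y [dna_seq()]s.
#' @param config A [mixture_config()] for the relative coder.
#' @param threshold,min_len,window Segmentation parameters, see
#'   [segment_low_information()] and [smooth_profile()].
#' @return A list of class `similarity_map` with `segments_x`,
#'   `segments_y` (tibbles), the smoothed profiles, and the parameters.
#' @export
similarity_map <- function(x, y, config = preset_config("synthetic-relative"),
                           threshold = 1.5, min_len = 100L, window = 501L) {
  px <- smooth_profile(compress_relative(x, y, config), window)
  py <- smooth_profile(compress_relative(y, x, config), window)
  structure(list(
    segments_x = segment_low_information(px, threshold, min_len),
    segments_y = segment_low_information(py, threshold, min_len),
    profile_x = px, profile_y = py,
    ids = c(x = x$id, y = y$id),
    threshold = threshold, min_len = min_len, window = window),
    class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat("<similarity_map> ", x$ids[["x"]], " vs ", x$ids[["y"]], "\n", sep = "")
  cat("  ", nrow(x$segments_x), " segment(s) in x, ",
      nrow(x$segments_y), " segment(s) in y (threshold ", x$threshold,
      " bits, min_len ", x$min_len, ", window ", x$window, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.similarity_map <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$segments_x, sequence = x$ids[["x"]], side = "x"),
    dplyr::mutate(x$segments_y, sequence = x$ids[["y"]], side = "y"))
}

#' Write segments as BED
#'
#' BED uses 0-based half-open coordinates, matching the segment tables.
#'
#' @param segments A segments tibble (from [segment_low_information()]) or
#'   a `similarity_map`.
#' @param path Output path.
#' @param seqname Sequence name for the first BED column (ignored for a
#'   `similarity_map`, which writes both sides).
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path, seqname = "seq") {
  if (inherits(segments, "similarity_map")) {
    df <- tidy(segments)
    bed <- data.frame(chrom = df$sequence, start = df$start, end = df$end,
                      name = paste0(df$side, "_seg", seq_len(nrow(df))))
  } else {
    bed <- data.frame(chrom = seqname, start = segments$start,
                      end = segments$end,
                      name = paste0("seg", seq_len(nrow(segments))))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
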