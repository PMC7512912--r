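# Normalized comparison measures built on the coding engine: NC, NCD
# (conjoint and conditional forms) and NRC. Values slightly above 1 are
# possible with real compressors and are preserved.

new_measure_result <- function(value, measure, components, mode,
                               clamped = FALSE) {
  structure(list(value = value, measure = measure, components = components,
                 mode = mode, clamped = clamped),
            class = "measure_result")
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf("<measure_result> %s = %.6f  (%s)\n", x$measure, x$value, x$mode))
  comp <- paste(names(x$components),
                sprintf("%.1f", x$components), sep = " = ")
  cat("  ", paste(comp, collapse = ", "), "\n", sep = "")
  if (x$clamped) cat("  note: a negative conditional was clamped to 0\n")
  invisible(x)
}

#' @export
tidy.measure_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, value = x$value, mode = x$mode,
                 component = names(x$components), bits = unname(x$components))
}

#' @export
glance.measure_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, value = x$value, mode = x$mode,
                 clamped = x$clamped)
}

#' Normalized Compression (NC)
#'
#' `NC(x) = C(x) / (|x| log2 4) = C(x) / (2 |x|)`. Approximately 1 for
#' incompressible (uniform i.i.d.) input and near 0 for highly redundant
#' input. The normalization constant is fixed at 2 bits per symbol (DNA
#' alphabet), even if the input contained replaced characters.
#'
#' @param x A [dna_seq()], non-empty.
#' @param config A [mixture_config()] for the reference-free coder.
#' @return A `measure_result`; `components` holds the raw bit total.
#' @export
nc <- function(x, config = preset_config("synthetic-ref-free")) {
  cx <- compress_dna(x, config)
  n <- length(cx$bits)
  new_measure_result(cx$total_bits / (2 * n), "NC",
                     c(Cx = cx$total_bits, n = n), "reference-free")
}

#' Normalized Compression Distance (NCD)
#'
#' The conjoint form (default) is
#' `NCD(x,y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y))`, where the
#' conjoint compression `C(xy)` is approximated by coding the concatenation
#' (the split description being asymptotically negligible). The
#' conditional form derives both conditionals through the chain rule,
#' `C(x|y) = C(yx) - C(y)`, and computes
#' `max(C(x|y), C(y|x)) / max(C(x), C(y))`. A negative conditional
#' (possible under imperfect compression) is clamped to 0 and flagged.
#'
#' @param x,y [dna_seq()]s, non-empty.
#' @param config A [mixture_config()] for the reference-free/conjoint coder.
#' @param type `"conjoint"` (default) or `"conditional"`.
#' @return A `measure_result` with the raw bit totals in `components`.
#' @export
ncd <- function(x, y, config = preset_config("synthetic-ref-free"),
                type = c("conjoint", "conditional")) {
  type <- match.arg(type)
  cx <- compress_dna(x, config)$total_bits
  cy <- compress_dna(y, config)$total_bits
  cyx <- compress_conjoint(x, y, config)$total_bits  # y then x
  if (type == "conjoint") {
    value <- (cyx - min(cx, cy)) / max(cx, cy)
    return(new_measure_result(value, "NCD",
                              c(Cx = cx, Cy = cy, Cxy = cyx), "conjoint"))
  }
  cxy <- compress_conjoint(y, x, config)$total_bits  # x then y
  cond_xy <- cyx - cy  # C(x|y)
  cond_yx <- cxy - cx  # C(y|x)
  clamped <- cond_xy < 0 || cond_yx < 0
  value <- max(max(cond_xy, 0), max(cond_yx, 0)) / max(cx, cy)
  new_measure_result(value, "NCD",
                     c(Cx = cx, Cy = cy, Cyx = cyx, Cxy = cxy,
                       C_x_given_y = max(cond_xy, 0),
                       C_y_given_x = max(cond_yx, 0)),
                     "conditional", clamped = clamped)
}

#' Normalized Relative Compression (NRC)
#'
#' `NRC(x||y) = C(x||y) / (2 |x|)`: the fraction of `x` that cannot be
#' described using only a model of `y`. Generally asymmetric, and
#' insensitive to repeats within `x` (describing n concatenated copies of
#' `x` costs about n times one copy, since the frozen model cannot learn
#' the repetition).
#'
#' @param x Target [dna_seq()].
#' @param y Reference [dna_seq()].
#' @param config A [mixture_config()] for the relative coder.
#' @return A `measure_result`.
#' @export
nrc <- function(x, y, config = preset_config("synthetic-relative")) {
  cr <- compress_relative(x, y, config)
  n <- length(cr$bits)
  new_measure_result(cr$total_bits / (2 * n), "NRC",
                     c(Cx_given_y_rel = cr$total_bits, n = n), "relative")
}

#' All-vs-all measure matrix
#'
#' Computes a measure between every ordered pair of sequences and returns
#' a tidy tibble; useful for exporting distance matrices for external tree
#' tools.
#'
#' @param seqs Named list of [dna_seq()]s.
#' @param measure `"ncd"` or `"nrc"`.
#' @param config A [mixture_config()].
#' @return A tibble with columns `x`, `y`, `value`.
#' @export
measure_matrix <- function(seqs, measure = c("ncd", "nrc"),
                           config = NULL) {
  measure <- match.arg(measure)
  if (is.null(config))
    config <- preset_config(if (measure == "nrc") "synthetic-relative"
                            else "synthetic-ref-free")
  ids <- vapply(seqs, function(s) s$id, character(1))
  grid <- expand.grid(i = seq_along(seqs), j = seq_along(seqs))
  grid <- grid[grid$i != grid$j | measure == "nrc", , drop = FALSE]
  purrr::pmap_dfr(grid, function(i, j) {
    v <- if (measure == "ncd") ncd(seqs[[i]], seqs[[j]], config)$value
         else nrc(seqs[[i]], seqs[[j]], config)$value
    tibble::tibble(x = ids[i], y = ids[j], value = v)
  })
}
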