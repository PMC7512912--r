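# The mixture coding engine: three compression modes returning per-symbol
# ideal code lengths (-log2 of the blended probability of the observed
# symbol). No bitstream is emitted; compression is used purely as a
# measurement device.

new_compression_result <- function(bits, mode, config, boundary = NA_integer_,
                                   diagnostics = list()) {
  structure(list(total_bits = sum(bits), bits = bits, mode = mode,
                 boundary = boundary, config = config,
                 diagnostics = diagnostics),
            class = "compression_result")
}

#' @export
print.compression_result <- function(x, ...) {
  n <- length(x$bits)
  cat("<compression_result> mode = ", x$mode, "\n", sep = "")
  cat(sprintf("  %d symbols, %.1f bits total, %.4f bits/symbol\n",
              n, x$total_bits, x$total_bits / n))
  if (!is.na(x$boundary))
    cat("  conjoint boundary at position ", x$boundary, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.compression_result <- function(x, ...) {
  tibble::tibble(position = seq_along(x$bits) - 1L, bits = x$bits)
}

#' @export
glance.compression_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = length(x$bits),
                 total_bits = x$total_bits,
                 bits_per_symbol = x$total_bits / length(x$bits))
}

as_codes <- function(x, arg = "x") {
  if (inherits(x, "dna_seq")) x <- x$symbols
  x <- as.integer(x)
  if (length(x) < 1L) stop(arg, " must be a non-empty sequence")
  x
}

run_engine <- function(stream, train_len, config, relative) {
  v <- config_vectors(config)
  engine_run_cpp(stream, as.integer(train_len), v$depth, v$alpha, v$ir,
                 v$tol, v$pair, v$gamma, v$cache, 16777213, relative)
}

#' Reference-free compression C(x)
#'
#' One adaptive pass over `x`: every model starts with zero counts and
#' uniform mixture weights and is updated throughout. The first k positions
#' of each model use a context left-padded with `A`.
#'
#' @param x A [dna_seq()] (or integer code vector), non-empty.
#' @param config A [mixture_config()]; defaults to the
#'   `"synthetic-ref-free"` preset.
#' @return A `compression_result` with fields `total_bits`, `bits` (the
#'   per-symbol information profile), `mode`, and diagnostics
#'   (`max_prob_dev`, `max_weight_dev`: worst deviation of the blended
#'   distribution and of the weight sum from 1).
#' @export
compress_dna <- function(x, config = preset_config("synthetic-ref-free")) {
  x <- as_codes(x)
  r <- run_engine(x, 0L, config, FALSE)
  new_compression_result(r$bits, "reference-free", config,
                         diagnostics = list(max_prob_dev = r$max_prob_dev,
                                            max_weight_dev = r$max_weight_dev))
}

#' Conjoint compression C(yx)
#'
#' One adaptive pass over the concatenation of `y` followed by `x`. The
#' profile covers the full concatenation; `boundary` records where `x`
#' starts.
#'
#' @param x,y [dna_seq()]s (or integer code vectors), non-empty.
#' @inheritParams compress_dna
#' @return A `compression_result` of mode `"conjoint"` over `y . x`.
#' @export
compress_conjoint <- function(x, y,
                              config = preset_config("synthetic-ref-free")) {
  x <- as_codes(x, "x"); y <- as_codes(y, "y")
  r <- run_engine(c(y, x), 0L, config, FALSE)
  new_compression_result(r$bits, "conjoint", config, boundary = length(y),
                         diagnostics = list(max_prob_dev = r$max_prob_dev,
                                            max_weight_dev = r$max_weight_dev))
}

#' Relative compression C(x||y)
#'
#' Phase 1 makes an adaptive pass over the reference `y`, updating counts
#' only (no bits recorded). All memories are then frozen, mixture weights
#' reset to uniform and model contexts reset to `x`'s own padded past.
#' Phase 2 codes `x` read-only: only the mixture weights and the tolerant
#' models' private histories adapt. Repeated calls are identical — no state
#' leaks between calls.
#'
#' @param x Target [dna_seq()] (coded).
#' @param y Reference [dna_seq()] (modelled, then frozen).
#' @param config A [mixture_config()]; defaults to the
#'   `"synthetic-relative"` preset.
#' @return A `compression_result` of mode `"relative"`; `bits` holds the
#'   per-symbol relative information profile of `x` given `y`.
#' @export
compress_relative <- function(x, y,
                              config = preset_config("synthetic-relative")) {
  x <- as_codes(x, "x"); y <- as_codes(y, "y")
  r <- run_engine(c(y, x), length(y), config, TRUE)
  new_compression_result(r$bits, "relative", config,
                         diagnostics = list(max_prob_dev = r$max_prob_dev,
                                            max_weight_dev = r$max_weight_dev))
}

#' Mixture weight update rule
#'
#' The soft-blending update: `w_m <- normalize((w_m)^gamma * p_m)`, where
#' `p_m` is model m's probability of the symbol just observed and `gamma`
#' in `[0, 1)` acts as a forgetting factor on past performance. After
#' normalization, weights are floored at 1e-12 and renormalized so no model
#' dies permanently under finite precision. Blending always uses the
#' weights as they stood *before* observing the symbol (the causal,
#' decodable reading).
#'
#' @param w Current weights (sum to 1).
#' @param p Per-model probabilities of the observed symbol.
#' @param gamma Forgetting factor in `[0, 1)`.
#' @return Updated weight vector summing to 1.
#' @export
mixture_weight_update <- function(w, p, gamma) {
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)")
  mix_update_cpp(as.numeric(w), as.numeric(p), as.numeric(gamma))
}

#' Read / write a per-symbol information profile as TSV
#'
#' Two columns: 0-based `position` and `bits`.
#'
#' @param x A `compression_result` or numeric bits vector.
#' @param path File path.
#' @return For `read_profile_tsv`, a numeric bits vector.
#' @export
write_profile_tsv <- function(x, path) {
  bits <- if (inherits(x, "compression_result")) x$bits else as.numeric(x)
  utils::write.table(data.frame(position = seq_along(bits) - 1L, bits = bits),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path)
  df$bits[order(df$position)]
}
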