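# Independent oracles used across the suite. Deliberately written as plain
# R loops / brute-force counting so they share no code path with the
# compiled engine.

# Adaptive single-model code length: order-k counting with alpha smoothing,
# context left-padded with A, counts updated after each symbol.
oracle_adaptive_code_length <- function(symbols, k, alpha) {
  counts <- matrix(0L, nrow = 4L^k, ncol = 4L)
  ctx <- 0L  # all-A padding
  bits <- numeric(length(symbols))
  for (i in seq_along(symbols)) {
    s <- symbols[i] + 1L
    row <- ctx + 1L
    tot <- sum(counts[row, ])
    bits[i] <- -log2((counts[row, s] + alpha) / (tot + 4 * alpha))
    counts[row, s] <- counts[row, s] + 1L
    ctx <- (ctx * 4L + (s - 1L)) %% (4L^k)
  }
  bits
}

# Brute-force (k+1)-mer occurrence counts over a padded sequence, as a
# named vector "context|symbol" -> count.
oracle_kmer_counts <- function(symbols, k) {
  padded <- c(rep(0L, k), symbols)
  out <- new.env(parent = emptyenv())
  for (i in seq_along(symbols)) {
    w <- padded[i:(i + k)]
    key <- paste(w, collapse = "")
    cur <- if (is.null(out[[key]])) 0L else out[[key]]
    out[[key]] <- cur + 1L
  }
  out
}

oracle_revcomp <- function(codes) rev(3L - codes)

random_codes <- function(n, seed) {
  withr::with_seed(seed, sample.int(4L, n, replace = TRUE) - 1L)
}

# mean of a profile over the 0-based half-open interval [start, end)
region_mean <- function(bits, start, end) mean(bits[(start + 1L):end])
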