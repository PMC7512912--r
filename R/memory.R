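# Low-level access to a single context-model memory (count store). The
# mixture engine builds its own memories internally; this interface exposes
# the same compiled store for inspection, unit-level use and the tolerant
# state machine.

#' Create a context-model memory
#'
#' A mutable map from k-mer contexts to 4 symbol counts, starting all-zero.
#' Depths up to 11 use a direct count table; deeper models use a hashed
#' store where `cache_bound > 0` keeps at most that many contexts per hash
#' bucket (FIFO: the oldest context in a full bucket is evicted when a new
#' one is inserted).
#'
#' @param depth Context order k.
#' @param inverted_repeats Also count the reverse complement of every
#'   update window.
#' @param cache_bound Per-bucket capacity (0 = unbounded).
#' @param table_size Number of hash buckets (deep models only). Mainly a
#'   testing knob; the default suits real use.
#' @return An external pointer of class `cm_memory`.
#' @export
cm_memory <- function(depth, inverted_repeats = FALSE, cache_bound = 0L,
                      table_size = 16777213) {
  ptr <- cm_new_cpp(as.integer(depth), isTRUE(inverted_repeats),
                    as.integer(cache_bound), as.numeric(table_size))
  class(ptr) <- "cm_memory"
  ptr
}

#' @export
print.cm_memory <- function(x, ...) {
  cat("<cm_memory> depth ", cm_depth_cpp(x), ", ",
      format(cm_n_contexts_cpp(x), big.mark = ","), " contexts",
      if (cm_is_frozen(x)) ", frozen" else "", "\n", sep = "")
  invisible(x)
}

#' Update a memory with one (k+1)-mer window
#'
#' Increments `count[w1..wk][w(k+1)]`; with inverted repeats on,
#' additionally increments `count[rc(w2..w(k+1))][complement(w1)]`.
#' Cache-hash eviction is applied after inserting a new context. Errors on
#' a frozen memory.
#'
#' @param mem A [cm_memory()].
#' @param window Integer vector of k+1 codes in `0:3`.
#' @return `mem`, invisibly.
#' @export
cm_update <- function(mem, window) {
  cm_update_cpp(mem, as.integer(window))
  invisible(mem)
}

#' Train a memory over a whole sequence
#'
#' Slides the (k+1)-mer window over the sequence with the context
#' left-padded with `A` for the first k positions, applying [cm_update()]
#' at every position.
#'
#' @param mem A [cm_memory()].
#' @param x A [dna_seq()] or integer code vector.
#' @return `mem`, invisibly.
#' @export
cm_train <- function(mem, x) {
  if (inherits(x, "dna_seq")) x <- x$symbols
  cm_train_cpp(mem, as.integer(x))
  invisible(mem)
}

#' Predict the next-symbol distribution for a context
#'
#' `P(s) = (n_s + alpha) / (sum(n) + 4 alpha)`; an absent context yields
#' the uniform distribution.
#'
#' @param mem A [cm_memory()].
#' @param context Integer vector of k codes.
#' @param alpha Smoothing parameter (> 0).
#' @return Numeric probability 4-vector (A, C, G, T), summing to 1.
#' @export
cm_predict <- function(mem, context, alpha) {
  cm_predict_cpp(mem, as.integer(context), as.numeric(alpha))
}

#' Freeze a memory
#'
#' After freezing, updates raise an error and predictions are read-only;
#' counts are unchanged. Idempotent.
#'
#' @param mem A [cm_memory()].
#' @return `mem`, invisibly.
#' @export
cm_freeze <- function(mem) {
  cm_freeze_cpp(mem)
  invisible(mem)
}

#' @rdname cm_freeze
#' @export
cm_is_frozen <- function(mem) cm_is_frozen_cpp(mem)

#' Inspect stored counts
#'
#' @param mem A [cm_memory()].
#' @param context Integer vector of k codes.
#' @return Integer 4-vector of counts (zero for an absent context).
#' @export
cm_counts <- function(mem, context) cm_counts_cpp(mem, as.integer(context))

#' @rdname cm_counts
#' @export
cm_n_contexts <- function(mem) cm_n_contexts_cpp(mem)

# internal (testing): hash bucket a context maps to
cm_bucket <- function(mem, context) cm_bucket_cpp(mem, as.integer(context))

#' Run the substitution-tolerant state machine
#'
#' Steps the tolerant context model over `symbols` against a shared memory
#' used read-only. At each step the model predicts from its *private*
#' history; if the true symbol equals the argmax prediction (ties broken in
#' A<C<G<T order) it is appended to the history, otherwise the predicted
#' symbol is appended and the miss count incremented. When the miss count
#' exceeds `tolerance` the history is reset to the true past (including the
#' current symbol) and the miss count to zero.
#'
#' @param mem A [cm_memory()] (typically the same-depth plain model's).
#' @param symbols True symbols to process (integer codes or [dna_seq()]).
#' @param alpha Smoothing parameter for predictions.
#' @param tolerance Allowed substitutions (> 0).
#' @param init_past Integer vector of k codes initializing both the private
#'   history and the true past (defaults to all-`A` padding).
#' @return A list with per-step `predicted` (argmax symbol), `miss` (count
#'   after the step), `reset` (logical), `history` (matrix, rows = steps,
#'   oldest to newest) and `probs` (matrix of predictive distributions).
#' @export
stcm_run <- function(mem, symbols, alpha, tolerance,
                     init_past = rep(0L, cm_depth_cpp(mem))) {
  if (inherits(symbols, "dna_seq")) symbols <- symbols$symbols
  stcm_run_cpp(mem, as.numeric(alpha), as.integer(tolerance),
               as.integer(symbols), as.integer(init_past))
}
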