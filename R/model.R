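# Model specification, mixture configuration and the named presets.

#' Specify one context model
#'
#' @param depth Context order k (contiguous past symbols), `1 <= k <= 28`.
#' @param alpha Smoothing parameter of the count estimator
#'   `P(s) = (n_s + alpha) / (n + 4 alpha)`; `alpha > 0`. Large alpha pulls
#'   towards uniform, small alpha trusts the counts.
#' @param inverted_repeats If `TRUE`, every (k+1)-mer update also counts
#'   its reverse complement, so reverse-complemented repeats are modelled.
#'   Affects updates only; prediction never queries the complemented context.
#' @param tolerance Allowed substitutions `t >= 0`. `t = 0` gives a plain
#'   context model; `t > 0` gives a substitution-tolerant context model that
#'   shares the memory of the same-depth plain model in the mixture.
#' @return A `model_spec` list.
#' @export
model_spec <- function(depth, alpha, inverted_repeats = FALSE, tolerance = 0L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L || depth > 28L) stop("depth must be in [1, 28]")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  tolerance <- as.integer(tolerance)
  if (is.na(tolerance) || tolerance < 0L) stop("tolerance must be >= 0")
  structure(list(depth = depth, alpha = as.numeric(alpha),
                 inverted_repeats = isTRUE(inverted_repeats),
                 tolerance = tolerance),
            class = "model_spec")
}

#' Configure a model mixture
#'
#' @param models List of [model_spec()]s (at least one). Every tolerant
#'   spec must have a same-depth plain spec in the list whose memory it
#'   shares.
#' @param gamma Forgetting factor in `[0, 1)` applied to every model's
#'   weight before multiplying in its last prediction; one shared value.
#' @param cache_hash Cache-hash bound `B >= 0`: each hash bucket of a
#'   deep-model store retains at most `B` contexts (most recent first in,
#'   first out). `0` disables eviction. Shallow models (depth <= 11) use
#'   direct count tables and are never evicted.
#' @return A `mixture_config` list.
#' @export
mixture_config <- function(models, gamma = 0.95, cache_hash = 0L) {
  if (inherits(models, "model_spec")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "model_spec")))
  if (!is.numeric(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must be in [0, 1)")
  cache_hash <- as.integer(cache_hash)
  if (is.na(cache_hash) || cache_hash < 0L) stop("cache_hash must be >= 0")
  depths <- vapply(models, `[[`, integer(1), "depth")
  tols <- vapply(models, `[[`, integer(1), "tolerance")
  for (i in which(tols > 0L)) {
    if (!any(tols == 0L & depths == depths[i]))
      stop("tolerant model of depth ", depths[i],
           " has no same-depth plain model to share memory with")
  }
  structure(list(models = models, gamma = as.numeric(gamma),
                 cache_hash = cache_hash),
            class = "mixture_config")
}

#' @export
print.mixture_config <- function(x, ...) {
  cat("<mixture_config> ", length(x$models), " models, gamma = ", x$gamma,
      ", cache_hash = ", x$cache_hash, "\n", sep = "")
  for (m in x$models) {
    cat(sprintf("  %s depth %2d  alpha %-6g ir %-3s tolerance %d\n",
                if (m$tolerance > 0) "STCM" else "CM  ",
                m$depth, m$alpha,
                if (m$inverted_repeats) "yes" else "no", m$tolerance))
  }
  invisible(x)
}

# internal: flatten a config into the vectors the C++ engine takes
config_vectors <- function(config) {
  stopifnot(inherits(config, "mixture_config"))
  depths <- vapply(config$models, `[[`, integer(1), "depth")
  alphas <- vapply(config$models, `[[`, numeric(1), "alpha")
  irs <- vapply(config$models, `[[`, logical(1), "inverted_repeats")
  tols <- vapply(config$models, `[[`, integer(1), "tolerance")
  pair <- rep(-1L, length(depths))
  for (i in which(tols > 0L))
    pair[i] <- which(tols == 0L & depths == depths[i])[1] - 1L
  list(depth = depths, alpha = alphas, ir = irs, tol = tols, pair = pair,
       gamma = config$gamma, cache = config$cache_hash)
}

#' Named mixture presets
#'
#' Ready-made mixtures tuned to a data scale and coding mode:
#'
#' * `"synthetic-ref-free"`: 8 models, gamma 0.95, cache-hash 30 — for
#'   reference-free `C(x)` and conjoint `C(xy)` on synthetic data.
#' * `"synthetic-relative"`: 7 models, gamma 0.95, cache-hash 30 — for
#'   relative `C(x||y)` on synthetic data.
#' * `"mtDNA"` / `"mtDNA-relative"`: 5 models, gamma 0.95 — mitochondrial
#'   scale (~16 kb).
#' * `"mRNA"` / `"mRNA-relative"`: 7 models, gamma 0.88, cache-hash 200.
#' * `"gDNA"` / `"gDNA-relative"`: 6 models, gamma 0.88, cache-hash 250 —
#'   whole-genome scale.
#'
#' The `-relative` variants differ only in the depth-14 alpha (0.01) where
#' such a model exists; the relative coder benefits from trusting the
#' frozen counts slightly more.
#'
#' @param name Preset name (see above).
#' @return A [mixture_config()].
#' @export
preset_config <- function(name = c("synthetic-ref-free", "synthetic-relative",
                                   "mtDNA", "mRNA", "gDNA",
                                   "mtDNA-relative", "mRNA-relative",
                                   "gDNA-relative")) {
  name <- match.arg(name)
  cm <- function(d, a, ir = FALSE) model_spec(d, a, inverted_repeats = ir)
  tcm <- function(d, a, t) model_spec(d, a, tolerance = t)
  switch(name,
    "synthetic-relative" = mixture_config(list(
      tcm(17, 0.02, 5), cm(17, 0.002), tcm(14, 0.1, 3), cm(14, 0.005),
      cm(11, 0.01), cm(8, 0.1), cm(5, 1)), gamma = 0.95, cache_hash = 30L),
    "synthetic-ref-free" = mixture_config(list(
      tcm(17, 0.1, 5), cm(17, 0.005), tcm(14, 1, 3), cm(14, 0.01),
      cm(11, 0.1), cm(8, 1), cm(5, 1), cm(3, 1)),
      gamma = 0.95, cache_hash = 30L),
    "mtDNA" = ,
    "mtDNA-relative" = mixture_config(list(
      tcm(13, 0.1, 5), cm(13, 0.005, TRUE), cm(10, 0.01, TRUE),
      cm(6, 1), cm(3, 1)), gamma = 0.95, cache_hash = 0L),
    "mRNA" = mixture_config(list(
      tcm(20, 0.1, 5), cm(20, 0.005, TRUE), cm(14, 0.02, TRUE),
      cm(13, 0.05), cm(11, 0.1), cm(9, 1), cm(4, 1)),
      gamma = 0.88, cache_hash = 200L),
    "mRNA-relative" = mixture_config(list(
      tcm(20, 0.1, 5), cm(20, 0.005, TRUE), cm(14, 0.01, TRUE),
      cm(13, 0.05), cm(11, 0.1), cm(9, 1), cm(4, 1)),
      gamma = 0.88, cache_hash = 200L),
    "gDNA" = mixture_config(list(
      tcm(20, 0.1, 5), cm(20, 0.005, TRUE), cm(14, 0.02, TRUE),
      cm(13, 0.05), cm(11, 0.1), cm(9, 1)),
      gamma = 0.88, cache_hash = 250L),
    "gDNA-relative" = mixture_config(list(
      tcm(20, 0.1, 5), cm(20, 0.005, TRUE), cm(14, 0.01, TRUE),
      cm(13, 0.05), cm(11, 0.1), cm(9, 1)),
      gamma = 0.88, cache_hash = 250L))
}
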