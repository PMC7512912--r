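# Drivers for the controlled synthetic experiments: substitution-rate
# sweeps comparing NCD and NRC, the rearrangement profile demonstration,
# and the NRC expectation curve under increasing mutation load.

#' NCD / NRC substitution-rate sweep
#'
#' At each substitution rate, builds a pair where `x` contains material
#' copied from `y` and mutated at that rate, and computes NCD (both
#' orders, conjoint form) and NRC (both directions). Substitutions are
#' applied only to the material copied from `y`, after copying.
#'
#' With `architecture = "uniform"`, `y` is uniform-random and `x` is
#' entirely a copy of `y` mutated at the rate. With
#' `architecture = "repeat-rich"`, both sequences emulate non-uniform,
#' repetitive genomic data: `y` is a repeat-laden sequence with a skewed
#' (AT-rich) base composition ([generate_repeat_rich()]) and only a
#' quarter of `x` is a mutated copy of the leading part of `y`; the rest
#' is `x`'s own material of the same composition. Because the relative
#' coder pays full price for everything private to `x` while NCD
#' normalizes that material away, NCD dominates NRC on this architecture
#' across the whole rate sweep.
#'
#' @param n Sequence length for both members of the pair.
#' @param rates Substitution rates to sweep.
#' @param seed Integer seed.
#' @param architecture `"uniform"` or `"repeat-rich"`.
#' @param config_ref_free Config for C(x)/C(xy) (NCD).
#' @param config_relative Config for C(x||y) (NRC).
#' @param proportion Length of `x` as a fraction of `n` (the copied
#'   material is the leading part of `y`); default 1 (equal sizes).
#' @return A tibble with columns `rate`, `ncd_xy`, `ncd_yx`, `nrc_xy`
#'   (NRC(x||y)) and `nrc_yx`.
#' @export
sweep_substitution_rates <- function(n = 1e5,
                                     rates = seq(0, 0.5, by = 0.1),
                                     seed = 1L,
                                     architecture = c("uniform", "repeat-rich"),
                                     config_ref_free = preset_config("synthetic-ref-free"),
                                     config_relative = preset_config("synthetic-relative"),
                                     proportion = 1) {
  architecture <- match.arg(architecture)
  if (architecture == "uniform") {
    y <- generate_random(n, seed = seed, id = "y")
    nx <- max(1L, as.integer(round(n * proportion)))
    own <- integer()
    copied <- rep_len(y$symbols, nx)
  } else {
    skew <- c(0.3, 0.2, 0.2, 0.3)
    y <- generate_repeat_rich(n, n_copies = max(1L, as.integer(n / 1e4)),
                              copy_len = as.integer(n / 20),
                              sub_rate = 0.01, seed = seed, id = "y",
                              base_probs = skew)
    nx <- max(2L, as.integer(round(n * proportion)))
    # only a quarter of x is copied from y; the rest is x's own material
    # drawn from the same skewed composition (the copied part inherits
    # y's repeats). The composition bias is learnable by every coder, but
    # the frozen reference model can never exploit structure private to
    # x, which is what separates NCD from NRC on this architecture.
    own_len <- (3L * nx) %/% 4L
    own <- withr::with_seed(seed + 500L,
      sample.int(4L, own_len, replace = TRUE, prob = skew) - 1L)
    copied <- rep_len(y$symbols, nx - own_len)
  }
  purrr::map_dfr(seq_along(rates), function(i) {
    mut <- mutate_substitutions(dna_seq("cp", copied), rates[i],
                                seed = seed + 1000L * i)
    x <- dna_seq("x", c(own, mut$symbols))
    tibble::tibble(
      rate = rates[i],
      ncd_xy = ncd(x, y, config_ref_free)$value,
      ncd_yx = ncd(y, x, config_ref_free)$value,
      nrc_xy = nrc(x, y, config_relative)$value,
      nrc_yx = nrc(y, x, config_relative)$value)
  })
}

#' Block architecture for the rearrangement profile demonstration
#'
#' A two-sequence layout exercising every way a region can relate to the
#' reference: `y` carries source regions B, C (high entropy) and D, F (low
#' entropy); `x` carries unmatched high-entropy regions A and N, an
#' unmatched low-entropy region H, mutated copies of reference regions
#' (E and L from B, J from C, each at 1% substitutions; I from F and K
#' from D verbatim), plus a high-entropy region G and its internal copy M.
#' Because G lives in `x` and not in `y`, M is cheap for the adaptive
#' reference-free coder but expensive for the relative coder — the
#' defining difference between the two modes.
#'
#' @param block_len Length of every block.
#' @return A [block_plan()].
#' @export
rearrangement_demo_plan <- function(block_len = 10000L) {
  block_plan(
    label = c("B", "C", "D", "F",
              "A", "E", "G", "H", "I", "J", "K", "L", "M", "N"),
    target = c("y", "y", "y", "y",
               "x", "x", "x", "x", "x", "x", "x", "x", "x", "x"),
    length = block_len,
    source = c("random", "random", "low-entropy", "low-entropy",
               "random", "copy:B", "random", "low-entropy", "copy:F",
               "copy:C", "copy:D", "copy:B", "copy:G", "random"),
    rate = c(0, 0, 0, 0,
             0, 0.01, 0, 0, 0, 0.01, 0, 0.01, 0, 0))
}

#' Rearrangement profile demonstration
#'
#' Generates the [rearrangement_demo_plan()] pair and computes the three
#' profiles compared in the package vignette: relative `C(x||y)`, conjoint
#' `C(yx)` and reference-free `C(x)`.
#'
#' @param block_len Block length.
#' @param seed Integer seed.
#' @param config_ref_free,config_relative Mixture configs for the two modes.
#' @return A list with the generated `x`, `y`, `annotations`, and the
#'   `relative`, `conjoint` and `ref_free` compression results.
#' @export
rearrangement_demo <- function(block_len = 10000L, seed = 1L,
                               config_ref_free = preset_config("synthetic-ref-free"),
                               config_relative = preset_config("synthetic-relative")) {
  g <- generate_blocks(rearrangement_demo_plan(block_len), seed = seed)
  list(x = g$x, y = g$y, annotations = g$annotations,
       relative = compress_relative(g$x, g$y, config_relative),
       conjoint = compress_conjoint(g$x, g$y, config_ref_free),
       ref_free = compress_dna(g$x, config_ref_free))
}

#' NRC expectation curve under increasing mutation load
#'
#' For each multiple m and slope s, mutates a copy of the reference at
#' rate `m * s` and computes `NRC(mutated || reference)`. Doubling the
#' slope should give a uniformly higher curve; short references produce
#' visibly noisier curves than long ones at equal rates.
#'
#' @param y Reference [dna_seq()].
#' @param multiples Integer mutation multiples (0 allowed: the unmutated
#'   baseline).
#' @param slopes Rate increments per multiple; default 1% and 2%.
#' @param config A [mixture_config()] for the relative coder.
#' @param seed Integer seed.
#' @return A tibble with columns `slope`, `multiple`, `rate`, `nrc`.
#' @export
nrc_expectation_curve <- function(y, multiples = 0:8,
                                  slopes = c(0.01, 0.02),
                                  config = preset_config("synthetic-relative"),
                                  seed = 1L) {
  stopifnot(inherits(y, "dna_seq"))
  grid <- expand.grid(slope = slopes, multiple = multiples)
  purrr::pmap_dfr(grid, function(slope, multiple) {
    rate <- slope * multiple
    x <- mutate_substitutions(y, rate,
                              seed = seed + round(1e4 * slope) + multiple)
    tibble::tibble(slope = slope, multiple = multiple, rate = rate,
                   nrc = nrc(x, y, config)$value)
  })
}
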