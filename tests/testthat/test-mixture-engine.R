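# The soft-blended mixture: weight updates, the three coding modes, and
# their contracts.

test_that("mixture weight update follows the forgetting-factor rule", {
  # hand-evaluated: (0.5)^0.95 * 0.9 and (0.5)^0.95 * 0.25, normalized
  w <- mixture_weight_update(c(0.5, 0.5), c(0.9, 0.25), 0.95)
  expect_equal(w, c(0.9, 0.25) / 1.15, tolerance = 1e-12)
  # gamma = 0 forgets everything: weights proportional to p
  w0 <- mixture_weight_update(c(0.5, 0.5), c(0.9, 0.1), 0)
  expect_equal(w0, c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(sum(mixture_weight_update(c(0.2, 0.8), c(1e-20, 1), 0.5)), 1)
  expect_error(mixture_weight_update(c(1, 0), c(0.5, 0.5), 1), "gamma")
})

test_that("mixture_config validates tolerant/plain pairing and parameters", {
  expect_error(mixture_config(list(model_spec(5, 1, tolerance = 2))),
               "plain model")
  expect_error(mixture_config(list(model_spec(5, 1)), gamma = 1), "gamma")
  expect_error(model_spec(0, 1), "depth")
  expect_error(model_spec(5, 0), "alpha")
  cfg <- mixture_config(list(model_spec(5, 1, tolerance = 2),
                             model_spec(5, 0.1)))
  expect_s3_class(cfg, "mixture_config")
})

test_that("a single-model mixture reproduces the brute-force adaptive code length", {
  syms <- random_codes(3000, seed = 41)
  for (k in c(1L, 2L, 4L)) {
    for (alpha in c(1, 0.1)) {
      cfg <- mixture_config(list(model_spec(k, alpha)), gamma = 0.95)
      r <- compress_dna(syms, cfg)
      expect_equal(r$total_bits,
                   sum(oracle_adaptive_code_length(syms, k, alpha)),
                   tolerance = 1e-6)
    }
  }
})

test_that("one model predicting 1/4 charges exactly 2 bits per symbol", {
  cfg <- mixture_config(list(model_spec(3, 1e9)))  # huge alpha ~ uniform
  r <- compress_dna(random_codes(100, seed = 1), cfg)
  expect_equal(r$bits, rep(2, 100), tolerance = 1e-6)
})

test_that("profiles are consistent with totals and inputs", {
  x <- generate_random(5000, seed = 42)
  y <- generate_random(4000, seed = 43)
  r <- compress_conjoint(x, y)
  expect_identical(length(r$bits), 9000L)
  expect_identical(r$boundary, 4000L)
  expect_equal(r$total_bits, sum(r$bits), tolerance = 1e-6)
  expect_true(all(is.finite(r$bits)) && all(r$bits >= 0))
  expect_error(compress_dna(dna_seq("e", integer())), "non-empty")
})

test_that("probability and weight normalization hold at every step", {
  x <- generate_random(20000, seed = 44)
  for (preset in c("synthetic-ref-free", "mtDNA")) {
    r <- compress_dna(x, preset_config(preset))
    expect_lt(r$diagnostics$max_prob_dev, 1e-9)
    expect_lt(r$diagnostics$max_weight_dev, 1e-12)
  }
})

test_that("coding is deterministic and relative mode is stateless", {
  x <- generate_random(8000, seed = 45)
  y <- generate_random(8000, seed = 46)
  r1 <- compress_relative(x, y)
  # an unrelated compression in between must not influence the result
  invisible(compress_dna(generate_random(5000, seed = 47)))
  r2 <- compress_relative(x, y)
  expect_identical(r1$bits, r2$bits)
  expect_identical(compress_dna(x)$bits, compress_dna(x)$bits)
})

test_that("conjoint coding makes the second copy of a sequence nearly free", {
  x <- generate_random(5e4, seed = 48)
  r <- compress_conjoint(x, x)  # y . x with y = x
  first <- mean(r$bits[1:5e4])
  second <- mean(r$bits[(5e4 + 1):1e5])
  expect_gt(first, 1.9)      # fresh uniform data is incompressible
  expect_lt(second, 0.15)    # repeat detected by the deep models
})

test_that("conjoint coding of independent sequences is nearly additive", {
  x <- generate_random(1e5, seed = 49)
  y <- generate_random(1e5, seed = 50)
  cxy <- compress_conjoint(x, y)$total_bits
  cx <- compress_dna(x)$total_bits
  cy <- compress_dna(y)$total_bits
  expect_lt(abs(cxy - (cx + cy)) / (cx + cy), 0.02)
})

test_that("relative mode: self-description is cheap, independent data costs ~2 bits", {
  x <- generate_random(3e4, seed = 51)
  rself <- compress_relative(x, x)
  expect_lt(rself$total_bits / length(x), 0.5)
  y <- generate_random(3e4, seed = 52)
  rind <- compress_relative(x, y)
  expect_gt(rind$total_bits / (2 * length(x)), 0.95)
})

test_that("adding a duplicate model only splits weight mass, not probabilities", {
  syms <- random_codes(4000, seed = 53)
  base <- mixture_config(list(model_spec(4, 0.1), model_spec(8, 1)))
  dup <- mixture_config(list(model_spec(4, 0.1), model_spec(8, 1),
                             model_spec(8, 1)))
  b1 <- compress_dna(syms, base)$total_bits
  b2 <- compress_dna(syms, dup)$total_bits
  expect_lt(abs(b1 - b2) / b1, 0.01)
})

test_that("periodic input becomes nearly free once a model has warmed up", {
  cfg <- mixture_config(list(model_spec(8, 1)))
  r <- compress_dna(rep(0:3, 25000), cfg)
  expect_lt(mean(r$bits[50001:100000]), 0.05)
})
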