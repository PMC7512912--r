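# Synthetic generators: uniform sequences, substitution mutation, block
# architectures and repeat-rich backbones.

test_that("generate_random is uniform, deterministic, and handles n = 0", {
  expect_identical(length(generate_random(0)), 0L)
  x <- generate_random(1e6, seed = 11)
  freqs <- tabulate(x$symbols + 1L, 4L) / 1e6
  # binomial: sd = sqrt(.25*.75/1e6) ~ 4.3e-4; 0.002 is ~4.6 sigma
  expect_true(all(abs(freqs - 0.25) < 0.002))
  expect_identical(generate_random(1000, seed = 5)$symbols,
                   generate_random(1000, seed = 5)$symbols)
})

test_that("mutate_substitutions changes exactly the selected positions", {
  x <- generate_random(1000, seed = 1)
  expect_identical(mutate_substitutions(x, 0, seed = 2)$symbols, x$symbols)
  m1 <- mutate_substitutions(x, 1, seed = 2)
  expect_identical(sum(m1$symbols != x$symbols), 1000L)

  big <- generate_random(1e5, seed = 3)
  m <- mutate_substitutions(big, 0.1, seed = 4)
  d <- sum(m$symbols != big$symbols)
  # binomial sd = sqrt(1e5*.1*.9) ~ 95; 300 ~ 3.2 sigma
  expect_true(abs(d - 10000) < 300)
  expect_error(mutate_substitutions(big, 1.5), "rate")
})

test_that("expected Hamming distance matches rate over several seeds", {
  x <- generate_random(2e4, seed = 10)
  for (seed in 1:5) {
    for (rate in c(0.05, 0.3)) {
      d <- sum(mutate_substitutions(x, rate, seed = seed)$symbols != x$symbols)
      sigma <- sqrt(2e4 * rate * (1 - rate))
      expect_lt(abs(d - rate * 2e4), 4 * sigma)
    }
  }
})

test_that("generate_blocks builds targets in plan order with correct annotations", {
  plan <- block_plan(
    label = c("B", "E"), target = c("y", "x"),
    length = 1000L, source = c("random", "copy:B"), rate = c(0, 0.01))
  g <- generate_blocks(plan, seed = 3)
  expect_identical(length(g$x), 1000L)
  expect_identical(length(g$y), 1000L)
  d <- sum(g$x$symbols != g$y$symbols)
  expect_lt(abs(d - 10), 4 * sqrt(1000 * 0.01 * 0.99) + 1)
  ann <- g$annotations
  expect_identical(ann$start, c(0L, 0L))
  expect_identical(ann$end, c(1000L, 1000L))

  # lengths equal the per-target sums for a bigger mixed plan
  plan2 <- block_plan(
    label = c("B", "C", "A", "E", "R"),
    target = c("y", "y", "x", "x", "x"),
    length = c(500L, 300L, 400L, 500L, 200L),
    source = c("random", "low-entropy", "random", "copy:B", "rc-copy:C"),
    rate = c(0, 0, 0, 0.05, 0))
  g2 <- generate_blocks(plan2, seed = 4)
  expect_identical(length(g2$y), 800L)
  expect_identical(length(g2$x), 1100L)
  expect_identical(g2$annotations$end[g2$annotations$label == "R"], 1100L)
  # rc-copy content is the reverse complement of its (truncated) source
  csrc <- g2$y$symbols[501:800]
  rblk <- g2$x$symbols[901:1100]
  expect_identical(rblk, rev(3L - csrc[1:200]))
})

test_that("block plans validate references and round-trip through TSV", {
  expect_error(block_plan("E", "x", 100L, "copy:B", 0), "undefined")
  expect_error(block_plan(c("B", "B"), c("y", "x"), 100L, "random", 0),
               "unique")
  plan <- rearrangement_demo_plan(1000L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_block_plan(plan, f)
  back <- read_block_plan(f)
  expect_equal(as.data.frame(back), as.data.frame(plan))
})

test_that("the rearrangement demo plan lays out the documented region map", {
  g <- generate_blocks(rearrangement_demo_plan(1000L), seed = 1)
  ann <- g$annotations
  expect_identical(ann$label[ann$target == "y"], c("B", "C", "D", "F"))
  expect_identical(ann$label[ann$target == "x"],
                   c("A", "E", "G", "H", "I", "J", "K", "L", "M", "N"))
  # E is a 1%-mutated copy of B
  e <- ann[ann$label == "E", ]; b <- ann[ann$label == "B", ]
  de <- sum(g$x$symbols[(e$start + 1):e$end] != g$y$symbols[(b$start + 1):b$end])
  expect_lt(abs(de - 10), 4 * sqrt(1000 * 0.01 * 0.99) + 1)
  # M is a verbatim copy of G (both inside x)
  m <- ann[ann$label == "M", ]; gg <- ann[ann$label == "G", ]
  expect_identical(g$x$symbols[(m$start + 1):m$end],
                   g$x$symbols[(gg$start + 1):gg$end])
})

test_that("generate_repeat_rich packs copies and is deterministic", {
  expect_error(generate_repeat_rich(100, 3, 50), "pack")
  r1 <- generate_repeat_rich(1e4, 5, 1000, sub_rate = 0, seed = 6)
  r2 <- generate_repeat_rich(1e4, 5, 1000, sub_rate = 0, seed = 6)
  expect_identical(r1$symbols, r2$symbols)
  # with no copies the output is the plain uniform backbone
  expect_identical(generate_repeat_rich(5000, 0, 10, seed = 7)$symbols,
                   generate_random(5000, seed = 7)$symbols)
})

test_that("repeat-rich sequences compress better than uniform ones", {
  cfg <- preset_config("synthetic-ref-free")
  rep_rich <- generate_repeat_rich(1e5, 10, 5000, sub_rate = 0, seed = 8)
  unif <- generate_random(1e5, seed = 8)
  expect_lt(nc(rep_rich, cfg)$value, nc(unif, cfg)$value)
})
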