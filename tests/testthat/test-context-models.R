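# Context-model memories: alpha-smoothed prediction, inverted-repeat
# updates, freezing, cache-hash eviction and the tolerant state machine.

test_that("cm_predict applies the alpha estimator", {
  m <- cm_memory(2)
  # empty memory: uniform fallback at any alpha
  expect_equal(cm_predict(m, c(0, 0), 1), rep(0.25, 4))
  expect_equal(sum(cm_predict(m, c(3, 1), 0.002)), 1, tolerance = 1e-12)

  # order-1 model fed the interior windows of "AACA": ctx A saw {A:1, C:1}
  m1 <- cm_memory(1)
  cm_update(m1, c(0, 0))  # A -> A
  cm_update(m1, c(0, 1))  # A -> C
  expect_equal(cm_predict(m1, 0, 1)[1], 2 / 6)  # (1+1)/(2+4)

  m2 <- cm_memory(1)
  for (i in 1:1000) cm_update(m2, c(2, 0))
  p <- cm_predict(m2, 2, 0.002)
  expect_equal(p[1], 1000.002 / 1000.008, tolerance = 1e-12)

  expect_error(cm_predict(m1, 0, 0), "alpha")
  expect_error(cm_predict(m1, c(0, 1), 1), "length")
})

test_that("cm_update counts the window and, with IR, its reverse complement", {
  m <- cm_memory(2)
  cm_update(m, c(0L, 1L, 2L))          # "ACG": ctx AC -> G
  expect_identical(cm_counts(m, c(0L, 1L)), c(0L, 0L, 1L, 0L))

  mir <- cm_memory(2, inverted_repeats = TRUE)
  cm_update(mir, c(0L, 1L, 2L))        # rc("ACG") = "CGT": ctx CG -> T
  expect_identical(cm_counts(mir, c(0L, 1L)), c(0L, 0L, 1L, 0L))
  expect_identical(cm_counts(mir, c(1L, 2L)), c(0L, 0L, 0L, 1L))
})

test_that("trained counts equal brute-force (k+1)-mer occurrence counts", {
  syms <- random_codes(3000, seed = 21)
  for (k in c(1L, 3L)) {
    m <- cm_memory(k)
    cm_train(m, syms)
    oracle <- oracle_kmer_counts(syms, k)
    # every oracle window count must match the stored count exactly
    for (key in ls(oracle)) {
      w <- as.integer(strsplit(key, "")[[1]])
      expect_identical(cm_counts(m, w[1:k])[w[k + 1] + 1L], oracle[[key]])
    }
    # total mass equals the number of windows
    tot <- sum(vapply(ls(oracle), function(key) oracle[[key]], integer(1)))
    expect_identical(tot, length(syms))
  }
})

test_that("IR doubles the total count mass", {
  syms <- random_codes(2000, seed = 22)
  k <- 4L
  mir <- cm_memory(k, inverted_repeats = TRUE)
  cm_train(mir, syms)
  # sum counts over all contexts seen either way: enumerate via both the
  # forward windows and their reverse complements
  padded <- c(rep(0L, k), syms)
  mass <- 0L
  seen <- character()
  keys <- unique(c(
    vapply(seq_along(syms), function(i)
      paste(padded[i:(i + k - 1L)], collapse = ""), character(1)),
    vapply(seq_along(syms), function(i)
      paste(oracle_revcomp(padded[(i + 1L):(i + k)]), collapse = ""),
      character(1))))
  for (key in keys) {
    ctx <- as.integer(strsplit(key, "")[[1]])
    mass <- mass + sum(cm_counts(mir, ctx))
  }
  expect_identical(mass, 2L * length(syms))
})

test_that("freezing blocks updates, preserves counts, and is idempotent", {
  m <- cm_memory(2)
  cm_update(m, c(0L, 1L, 2L))
  before <- cm_predict(m, c(0L, 1L), 0.5)
  cm_freeze(m)
  expect_true(cm_is_frozen(m))
  expect_error(cm_update(m, c(0L, 1L, 2L)), "frozen")
  expect_error(cm_train(m, c(0L, 1L, 2L)), "frozen")
  expect_identical(cm_predict(m, c(0L, 1L), 0.5), before)
  cm_freeze(m)  # idempotent
  expect_identical(cm_counts(m, c(0L, 1L)), c(0L, 0L, 1L, 0L))

  empty <- cm_freeze(cm_memory(3))
  expect_equal(cm_predict(empty, c(0, 1, 2), 1), rep(0.25, 4))
})

test_that("cache-hash keeps at most B most-recent contexts per bucket", {
  # table_size 1 forces every context into the same bucket
  m <- cm_memory(12, cache_bound = 1L, table_size = 1)
  ctx1 <- rep(0L, 12)
  ctx2 <- rep(1L, 12)
  cm_update(m, c(ctx1, 2L))
  cm_update(m, c(ctx2, 3L))
  expect_identical(sum(cm_counts(m, ctx1)), 0L)   # evicted
  expect_identical(cm_counts(m, ctx2), c(0L, 0L, 0L, 1L))
  expect_identical(cm_n_contexts(m), 1)

  # B = 2 retains both; a third context evicts the oldest only
  m2 <- cm_memory(12, cache_bound = 2L, table_size = 1)
  ctx3 <- rep(2L, 12)
  cm_update(m2, c(ctx1, 0L))
  cm_update(m2, c(ctx2, 0L))
  cm_update(m2, c(ctx3, 0L))
  expect_identical(sum(cm_counts(m2, ctx1)), 0L)
  expect_identical(sum(cm_counts(m2, ctx2)), 1L)
  expect_identical(sum(cm_counts(m2, ctx3)), 1L)
})

test_that("tolerant state machine: hits, misses, and reset to the true past", {
  # memory that has only ever seen ctx AA -> A
  m <- cm_memory(2)
  for (i in 1:10) cm_update(m, c(0L, 0L, 0L))
  # hit: true symbol equals the argmax
  r <- stcm_run(m, symbols = 0L, alpha = 1, tolerance = 2)
  expect_identical(r$predicted[1], 0L)
  expect_identical(r$miss[1], 0L)
  expect_false(r$reset[1])
  expect_identical(r$history[1, ], c(0L, 0L))

  # miss: prediction (A) is substituted into the private history
  r2 <- stcm_run(m, symbols = 1L, alpha = 1, tolerance = 2)
  expect_identical(r2$miss[1], 1L)
  expect_identical(r2$history[1, ], c(0L, 0L))  # appended A, not the true C

  # tolerance 1, two consecutive misses: reset to true past, miss back to 0
  r3 <- stcm_run(m, symbols = c(1L, 1L), alpha = 1, tolerance = 1)
  expect_identical(r3$miss, c(1L, 0L))
  expect_identical(r3$reset, c(FALSE, TRUE))
  # true past after two C's is "CC"
  expect_identical(r3$history[2, ], c(1L, 1L))

  expect_error(stcm_run(m, symbols = 0L, alpha = 1, tolerance = 0),
               "tolerance")
})

test_that("STCM never resets on a perfectly predictable source", {
  m <- cm_memory(3)
  period <- rep(c(0L, 1L, 2L, 3L), 50)
  cm_train(m, period)
  r <- stcm_run(m, symbols = rep(c(0L, 1L, 2L, 3L), 25), alpha = 0.01,
                tolerance = 1, init_past = c(1L, 2L, 3L))
  expect_false(any(r$reset))
  expect_true(all(r$miss == 0L))
})

test_that("STCM on uniform-random input resets at roughly geometric intervals", {
  m <- cm_memory(4)
  cm_train(m, random_codes(2000, seed = 31))
  cm_freeze(m)
  syms <- random_codes(4000, seed = 32)
  r <- stcm_run(m, symbols = syms, alpha = 1, tolerance = 2)
  n_reset <- sum(r$reset)
  # with ~3/4 miss probability a reset needs 3 misses: expect roughly one
  # reset every ~4 positions; require a broad plausible band
  expect_gt(n_reset, 400)
  expect_lt(n_reset, 1400)
  gaps <- diff(which(r$reset))
  expect_gt(mean(gaps), 3)
  expect_lt(mean(gaps), 10)
})
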