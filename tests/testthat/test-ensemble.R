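test_that("breakpoint frequency counts cells sharing each index", {
  b <- bps_set(list(5L, 5L, 5L), 20)
  expect_equal(breakpoint_frequency(b), c("5" = 3L))
  b2 <- bps_set(list(5L, 7L), 20)
  expect_equal(breakpoint_frequency(b2), c("5" = 1L, "7" = 1L))
  b3 <- bps_set(c(replicate(40, c(10L), simplify = FALSE),
                  list(11L),
                  replicate(59, integer(0), simplify = FALSE)), 20)
  expect_equal(breakpoint_frequency(b3), c("10" = 40L, "11" = 1L))
})

test_that("ensemble keeps shared breakpoints and CBS-confirmed ones", {
  cand <- bps_set(c(replicate(6, c(3L), simplify = FALSE),
                    list(c(3L, 9L))), 50)
  cbs <- bps_set(c(replicate(6, integer(0), simplify = FALSE),
                   list(c(9L, 14L))), 50)
  fin <- ensemble_breakpoints(cand, cbs, t = 5)
  expect_equal(fin$bps[[7]], c(3L, 9L))

  # unshared, unconfirmed: filtered out
  cand2 <- bps_set(list(9L, integer(0), integer(0), integer(0), integer(0)), 50)
  cbs2 <- bps_set(replicate(5, integer(0), simplify = FALSE), 50)
  expect_equal(ensemble_breakpoints(cand2, cbs2, t = 5)$bps[[1]], integer(0))

  # t = 1 reduces to the candidates
  fin1 <- ensemble_breakpoints(cand, cbs, t = 1)
  expect_equal(fin1$bps, cand$bps)
})

test_that("final breakpoints are always a subset of the candidates", {
  set.seed(31)
  for (r in 1:50) {
    n <- 8
    cand <- bps_set(replicate(n, sort(sample(0:38, sample(0:6, 1))),
                              simplify = FALSE), 40)
    cbs <- bps_set(replicate(n, sort(sample(0:38, sample(0:6, 1))),
                             simplify = FALSE), 40)
    t <- sample(1:6, 1)
    fin <- ensemble_breakpoints(cand, cbs, t)
    for (i in seq_len(n)) expect_true(all(fin$bps[[i]] %in% cand$bps[[i]]))
  }
})

test_that("segments tile chromosomes between breakpoints", {
  bt <- make_bt(6)
  f <- make_features(matrix(c(1, 1, 1, 2, 2, 2), 1),
                     matrix(0.5, 1, 6), bt)
  segs <- build_segments(bps_set(list(2L), 6), f)$segments[[1]]
  expect_equal(segs$start_bin, c(1, 4))
  expect_equal(segs$end_bin, c(3, 6))

  # no breakpoints: one segment per chromosome
  bt2 <- make_bt(8, n_chroms = 2)
  f2 <- make_features(matrix(1, 1, 8), matrix(0.5, 1, 8), bt2)
  segs2 <- build_segments(bps_set(list(integer(0)), 8), f2)$segments[[1]]
  expect_equal(nrow(segs2), 2)

  # segment means
  f3 <- make_features(matrix(c(1, 1, 2, 2), 1), matrix(0.5, 1, 4), make_bt(4))
  segs3 <- build_segments(bps_set(list(1L), 4), f3)$segments[[1]]
  expect_equal(segs3$rdr_mean, c(1, 2))

  # unmasked bin counts add up
  bt4 <- make_bt(10)
  bt4$masked[c(3, 8)] <- TRUE
  rdr <- matrix(1, 1, 10); rdr[, bt4$masked] <- NA
  f4 <- make_features(rdr, rdr * 0.5, bt4)
  segs4 <- build_segments(bps_set(list(c(1L, 5L)), 10), f4)$segments[[1]]
  expect_equal(sum(segs4$n_unmasked), 8)
})
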