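test_that("LSSE identities hold", {
  truth <- matrix(c(2, 2, 3, 4), 1)
  expect_equal(lsse(truth, truth), 0)
  off1 <- truth; off1[1, 2] <- 3
  expect_equal(lsse(truth, off1), log(2))
  # permutation invariance over bins
  perm <- c(3, 1, 4, 2)
  expect_equal(lsse(truth[, perm, drop = FALSE], off1[, perm, drop = FALSE]),
               lsse(truth, off1))
})

test_that("allele LSSE compares mirrored pairs", {
  tmin <- matrix(1, 1, 3); tmaj <- matrix(2, 1, 3)
  expect_equal(allele_lsse(tmin, tmaj, tmaj, tmin), 0)
  expect_gt(allele_lsse(tmin, tmaj, tmin * 0, tmaj), 0)
})

test_that("ploidy-adjusted LSSE removes pure scale errors", {
  truth <- matrix(c(2, 2, 4), 1)
  est <- matrix(c(1, 1, 2), 1)
  expect_equal(adjusted_lsse(truth, est, 2, 1), 0)
  expect_equal(adjusted_lsse(truth, 2 * truth, 2, 4), 0)
  # correct ploidy: equals plain lsse
  est2 <- matrix(c(2, 3, 4), 1)
  expect_equal(adjusted_lsse(truth, est2, 2, 2), lsse(truth, est2))
})

test_that("breakpoint matching respects the tolerance and 1:1 rule", {
  expect_equal(unname(breakpoint_prf(c(10, 20), c(10, 21), 1)[1:3]),
               c(1, 1, 1))
  r <- breakpoint_prf(10, c(9, 11), 1)
  expect_equal(unname(r[1:3]), c(0.5, 1, 2 / 3))
  # maximum (not greedy) matching
  expect_equal(unname(breakpoint_prf(c(5, 6), c(5, 6), 1)["f1"]), 1)
  # empty-set conventions
  expect_equal(unname(breakpoint_prf(integer(0), integer(0), 1)[1:3]),
               c(1, 1, 1))
  expect_equal(unname(breakpoint_prf(c(3), integer(0), 1)[c(1, 2)]), c(1, 0))
})

test_that("matching equals the brute-force oracle on random sets", {
  set.seed(17)
  for (r in 1:100) {
    tb <- sort(sample(0:30, sample(0:6, 1)))
    pb <- sort(sample(0:30, sample(0:6, 1)))
    l <- sample(0:3, 1)
    got <- breakpoint_prf(tb, pb, l)["matched"]
    expect_equal(unname(got), oracle_matching(tb, pb, l))
  }
})

test_that("zero tolerance reduces matching to set intersection", {
  set.seed(19)
  for (r in 1:25) {
    tb <- sample(0:20, 6)
    pb <- sample(0:20, 6)
    expect_equal(unname(breakpoint_prf(tb, pb, 0)["matched"]),
                 length(intersect(tb, pb)))
  }
})

test_that("recall is monotone in the tolerance", {
  set.seed(23)
  tb <- sort(sample(0:60, 8))
  pb <- sort(sample(0:60, 8))
  rec <- vapply(0:5, function(l) breakpoint_prf(tb, pb, l)["recall"], 1)
  expect_true(all(diff(rec) >= 0))
})

test_that("ploidy agreement computes PCC and RMSE", {
  expect_equal(unname(ploidy_agreement(c(2, 2, 4), c(2, 2, 4))), c(1, 0))
  expect_equal(unname(ploidy_agreement(c(2, 3, 4), c(3, 4, 5))), c(1, 1))
  r <- ploidy_agreement(c(2, 2, 4, 4), c(2, 2, 4, 2))
  expect_equal(unname(r["rmse"]), 1)
  expect_equal(unname(r["pcc"]), cor(c(2, 2, 4, 4), c(2, 2, 4, 2)))
  # zero-variance truth: PCC undefined
  expect_true(is.na(ploidy_agreement(c(2, 2), c(2, 3))["pcc"]))
})
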