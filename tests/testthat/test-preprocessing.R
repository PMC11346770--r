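test_that("bin masking applies strict GC and mappability thresholds", {
  bt <- bin_table(rep("chr1", 5), (0:4) * 1e6, (1:5) * 1e6,
                  gc = c(0.5, 0.19, 0.5, 0.2, 0.81),
                  mappability = c(0.95, 1, 0.89, 0.9, 1))
  bt <- mask_bins(bt)
  expect_equal(bt$masked, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  allbad <- bin_table("chr1", 0, 1e6, gc = 0.1, mappability = 1)
  expect_error(mask_bins(allbad), class = "scacn_all_masked_error")
})

test_that("gini coefficient matches the pairwise-difference formula", {
  expect_equal(gini_coefficient(c(5, 5, 5, 5)), 0)
  expect_equal(gini_coefficient(c(1, 3)), 0.25)
  expect_equal(gini_coefficient(c(0, 0, 0, 1)), 0.75)
  expect_error(gini_coefficient(c(0, 0)))
  # scale invariance
  set.seed(1)
  x <- rpois(50, 30)
  expect_equal(gini_coefficient(x), gini_coefficient(17.3 * x))
})

test_that("normal cells are identified by low count inequality", {
  flat1 <- rep(c(45, 55), 30)             # gini 0.05
  flat2 <- rep(c(48, 52), 30)
  bumpy <- c(rep(25, 20), rep(50, 20), rep(100, 20))
  R <- rbind(flat1, flat2, bumpy)
  expect_gt(gini_coefficient(bumpy), 0.12)
  expect_equal(identify_normal_cells(R, 0.12), c(1L, 2L))

  set.seed(2)
  noisy <- matrix(rpois(3 * 60, 40), 3, 60)
  expect_length(identify_normal_cells(noisy, 0), 0)

  same <- matrix(50, 4, 10)
  expect_equal(identify_normal_cells(same, 0.12), 1:4)
})

test_that("normalization factors average normal-cell count ratios", {
  bt <- make_bt(2)
  R <- rbind(c(2, 4), c(4, 8))
  nf <- normalization_factors(R, 1:2, bt)
  expect_equal(nf$factors, c(2 / 3, 4 / 3))

  # a single flat normal cell gives unit factors
  nf1 <- normalization_factors(matrix(c(5, 5), 1), 1, bt)
  expect_equal(nf1$factors, c(1, 1))

  # duplicating an identical cell changes nothing
  nf2 <- normalization_factors(rbind(c(2, 4), c(2, 4)), 1:2, bt)
  expect_equal(nf2$factors, normalization_factors(matrix(c(2, 4), 1), 1, bt)$factors)

  # invariance to per-cell total-coverage rescaling
  nf3 <- normalization_factors(rbind(c(2, 4), c(40, 80)), 1:2, bt)
  expect_equal(nf3$factors, c(2 / 3, 4 / 3))
})

test_that("GC fallback produces positive unit-mean factors", {
  set.seed(3)
  m <- 60
  gc <- runif(m, 0.3, 0.6)
  bias <- 1 + (gc - 0.45)            # linear GC bias
  bt <- make_bt(m, gc = gc)
  R <- t(replicate(8, rpois(m, 80 * bias)))
  nf <- normalization_factors(R, integer(0), bt)
  expect_true(all(nf$factors > 0))
  expect_equal(mean(nf$factors), 1, tolerance = 0.05)
  # factors track the imposed bias
  expect_gt(cor(nf$factors, bias), 0.8)
})

test_that("flat normals plus a flat tumor cell yield rdr identically 1", {
  bt <- make_bt(10)
  R <- rbind(rep(40, 10), rep(40, 10), rep(90, 10))
  pre <- preprocess(R, matrix(0.5, 3, 10), bt)
  expect_equal(unname(pre$features$rdr), matrix(1, 3, 10))
})
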