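test_that("simulated truth honors the normal fraction and determinism", {
  tr <- simulate_truth(100, 50, n_chroms = 2, normal_fraction = 0.25, seed = 4)
  expect_equal(length(tr$normal_cells), 25)
  nm <- tr$normal_cells
  expect_true(all(tr$c_minor[nm, ] == 1 & tr$c_major[nm, ] == 1))
  expect_equal(tr$ploidy[nm], rep(2, 25))

  tr2 <- simulate_truth(100, 50, n_chroms = 2, normal_fraction = 0.25, seed = 4)
  expect_identical(tr, tr2)
})

test_that("zero events leave the mode's base genome untouched", {
  for (mode in c("diploid", "triploid", "tetraploid")) {
    tr <- simulate_truth(12, 30, n_clones = 2, cna_events_per_clone = 0,
                         truncal_events = 0, ploidy_mode = mode,
                         normal_fraction = 0, seed = 2)
    base <- switch(mode, diploid = c(1, 1), triploid = c(1, 2),
                   tetraploid = c(2, 2))
    expect_true(all(tr$c_minor == base[1]))
    expect_true(all(tr$c_major == base[2]))
    expect_equal(tr$ploidy, rep(sum(base), 12))
  }
  hypo <- simulate_truth(8, 30, n_clones = 2, cna_events_per_clone = 0,
                         truncal_events = 0, ploidy_mode = "hypodiploid",
                         normal_fraction = 0, seed = 2)
  expect_lt(mean(hypo$ploidy), 2)
})

test_that("true breakpoints are exactly the state-change boundaries", {
  tr <- simulate_truth(30, 40, n_chroms = 2, seed = 9)
  tot <- tr$c_minor + tr$c_major
  for (i in c(1, 15, 30)) {
    manual <- integer(0)
    for (ch in c(0, 40)) {
      for (j in 1:39) {
        a <- ch + j; b <- ch + j + 1
        if (tr$c_minor[i, a] != tr$c_minor[i, b] ||
            tr$c_major[i, a] != tr$c_major[i, b]) {
          manual <- c(manual, a - 1L)
        }
      }
    }
    expect_equal(tr$breakpoints$bps[[i]], manual)
  }
})

test_that("exact matrices reproduce the expected features without noise", {
  tr <- simulate_truth(20, 40, n_chroms = 2, ploidy_mode = "diploid",
                       normal_fraction = 0.5, seed = 6)
  mats <- simulate_matrices(tr, coverage_scale = 50, count_model = "exact",
                            seed = 6)
  f <- compute_features(mats$R, mats$baf, tr$bin_table)
  nm <- tr$normal_cells
  expect_true(all(abs(f$rdr[nm, ] - 1) < 1e-12))
  expect_true(all(abs(f$mbaf[nm, ] - 0.5) < 1e-12))
  # LOH bins show mBAF 0, and rdr tracks total/ploidy everywhere
  tot <- tr$c_minor + tr$c_major
  loh <- tr$c_minor == 0 & tot > 0
  expect_true(all(f$mbaf[loh] == 0))
  expect_equal(f$rdr, tot / tr$ploidy, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("poisson counts have the configured mean", {
  tr <- simulate_truth(100, 100, n_chroms = 1, n_clones = 1,
                       cna_events_per_clone = 0, truncal_events = 0,
                       normal_fraction = 0, seed = 3)
  mats <- simulate_matrices(tr, coverage_scale = 50, count_model = "poisson",
                            seed = 3)
  n <- length(mats$R)
  expect_equal(mean(mats$R), 50, tolerance = 3 * sqrt(50 / n) / 50 * 3)
  expect_lt(abs(mean(mats$R) - 50), 3 * sqrt(50 / n))
})

test_that("matrices are reproducible under a fixed seed", {
  tr <- simulate_truth(10, 30, seed = 5)
  a <- simulate_matrices(tr, rdr_noise_sd = 0.1, baf_noise_sd = 0.05, seed = 8)
  b <- simulate_matrices(tr, rdr_noise_sd = 0.1, baf_noise_sd = 0.05, seed = 8)
  expect_identical(a, b)
})
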