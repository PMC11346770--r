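make_cluster_features <- function(n_per, means, sd, seed = 1) {
  set.seed(seed)
  K <- nrow(means)
  rdr <- mbaf <- NULL
  for (k in seq_len(K)) {
    rdr <- c(rdr, rnorm(n_per, means[k, 1], sd))
    mbaf <- c(mbaf, pmin(0.5, pmax(0, rnorm(n_per, means[k, 2], sd))))
  }
  m <- length(rdr)
  bt <- make_bt(m)
  make_features(matrix(rdr, 1), matrix(mbaf, 1), bt)
}

test_that("BIC selects the generating component count on separated data", {
  mu <- rbind(c(0.5, 0.1), c(1.0, 0.42), c(1.6, 0.3))
  f <- make_cluster_features(120, mu, sd = 0.03, seed = 5)
  fit <- fit_gmm(f, k_min = 1, k_max = 6, seed = 5)
  expect_equal(fit$K, 3)
  got <- fit$means[order(fit$means[, 1]), ]
  expect_equal(unname(got), unname(mu), tolerance = 0.02)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood trace is non-decreasing", {
  mu <- rbind(c(0.6, 0.2), c(1.2, 0.45))
  f <- make_cluster_features(80, mu, sd = 0.05, seed = 9)
  fit <- fit_gmm(f, k_min = 2, k_max = 2, seed = 9)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-1]))))
})

test_that("a single repeated point collapses to one exact component", {
  bt <- make_bt(10)
  f <- make_features(matrix(1.25, 1, 10), matrix(0.4, 1, 10), bt)
  fit <- fit_gmm(f, k_min = 1, k_max = 1, seed = 1)
  expect_equal(fit$K, 1)
  expect_equal(unname(fit$means[1, ]), c(1.25, 0.4), tolerance = 1e-6)
  expect_equal(fit$weights, 1)
  expect_true(all(fit$assignments == 1))
})

test_that("component merging pools weights, means and covariances", {
  bt <- make_bt(4)
  A <- matrix(c(1L, 1L, 2L, 2L), 1)
  mod <- make_model(rbind(c(1.00, 0.40), c(1.05, 0.42)),
                    rbind(c(0.01, 0.01), c(0.01, 0.01)),
                    weights = c(0.6, 0.4), bt = bt, assignments = A)
  mod$data <- cbind(c(1, 1, 1.05, 1.05), c(0.4, 0.4, 0.42, 0.42))
  mod$cells <- rep(1L, 4)
  mod$bins <- 1:4
  merged <- merge_components(mod, delta = 0.1, baf_weight = 1)
  expect_equal(merged$K, 1)
  expect_equal(unname(merged$means[1, ]), c(1.02, 0.408))
  expect_equal(sum(merged$weights), 1, tolerance = 1e-9)

  # delta = 0 is the identity
  expect_identical(merge_components(mod, delta = 0), mod)

  # distance 0.2 with threshold 0.1: no merge
  far <- make_model(rbind(c(1.0, 0.4), c(1.2, 0.4)),
                    rbind(c(0.01, 0.01), c(0.01, 0.01)),
                    weights = c(0.5, 0.5), bt = bt, assignments = A)
  far$data <- mod$data; far$cells <- mod$cells; far$bins <- mod$bins
  expect_equal(merge_components(far, delta = 0.1, baf_weight = 1)$K, 2)
})

test_that("merging never increases K and conserves weight on fitted models", {
  mu <- rbind(c(0.5, 0.1), c(0.56, 0.12), c(1.2, 0.45), c(1.7, 0.2))
  f <- make_cluster_features(60, mu, sd = 0.02, seed = 3)
  fit <- fit_gmm(f, k_min = 4, k_max = 4, seed = 3)
  merged <- merge_components(fit, delta = 0.1, baf_weight = 0.5)
  expect_lte(merged$K, fit$K)
  expect_equal(sum(merged$weights), 1, tolerance = 1e-9)
  expect_lt(merged$K, fit$K)  # the two close components pool
})

test_that("candidate breakpoints mark assignment changes within chromosomes", {
  bt <- make_bt(10, n_chroms = 2)
  A <- rbind(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3),
             c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
             c(1, 2, 1, 1, 1, 2, 2, 2, 2, 2))
  mod <- list(assignments = A, bin_table = bt)
  cb <- candidate_breakpoints(mod, bt)
  expect_equal(cb$bps[[1]], 1L)          # change inside chr1 only
  expect_equal(cb$bps[[2]], integer(0))  # constant; chr boundary is silent
  expect_equal(cb$bps[[3]], c(0L, 1L))   # both flanks of the flip

  # a change across a masked gap lands on the left unmasked bin
  bt2 <- make_bt(5)
  bt2$masked[3] <- TRUE
  A2 <- matrix(c(1, 1, 9, 2, 2), 1)
  A2[1, 3] <- NA
  cb2 <- candidate_breakpoints(list(assignments = A2, bin_table = bt2), bt2)
  expect_equal(cb2$bps[[1]], 1L)
})

test_that("breakpoints are independent across cells", {
  set.seed(11)
  bt <- make_bt(30)
  A <- matrix(sample(1:3, 5 * 30, replace = TRUE), 5, 30)
  mod <- list(assignments = A, bin_table = bt)
  all_at_once <- candidate_breakpoints(mod, bt)
  for (i in 1:5) {
    solo <- candidate_breakpoints(list(assignments = A[i, , drop = FALSE],
                                       bin_table = bt), bt)
    expect_equal(all_at_once$bps[[i]], solo$bps[[1]])
  }
})

test_that("ambiguous isolated flips are smoothed, decisive ones kept", {
  bt <- make_bt(9)
  # two tight far-apart components; a lone middle-bin flip between them
  mod <- make_model(rbind(c(1.0, 0.5), c(1.5, 0.3)),
                    rbind(c(0.05, 0.03), c(0.05, 0.03)),
                    weights = c(0.5, 0.5), bt = bt)
  A <- matrix(1L, 1, 9)
  A[1, 5] <- 2L
  mod$assignments <- A
  # ambiguous: the flipped bin's value sits at component 1's mean
  mod$data <- cbind(rep(1.0, 9), rep(0.5, 9))
  mod$cells <- rep(1L, 9); mod$bins <- 1:9
  sm <- smooth_assignments(mod)
  expect_equal(as.integer(sm$assignments[1, ]), rep(1L, 9))
  # decisive: the flipped bin genuinely sits at component 2's mean
  mod$data[5, ] <- c(1.5, 0.3)
  sm2 <- smooth_assignments(mod)
  expect_equal(as.integer(sm2$assignments[1, 5]), 2L)
})
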