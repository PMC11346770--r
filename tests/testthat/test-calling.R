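two_comp_model <- function(bt) {
  make_model(rbind(c(1.0, 0.5), c(2.0, 0.25)),
             rbind(c(0.05, 0.03), c(0.05, 0.03)),
             weights = c(0.6, 0.4), bt = bt)
}

test_that("segments go to the nearest component, ties to higher weight", {
  bt <- make_bt(10)
  mod <- two_comp_model(bt)
  segs <- rbind(seg_row("chr1", 1, 5, 5, 1.0, 0.5),
                seg_row("chr1", 6, 10, 5, 1.5, 0.375))
  a <- assign_segments(segs, mod)
  expect_equal(a[1], 1L)
  expect_equal(a[2], 1L)  # equidistant: the higher-weight component wins

  mod2 <- make_model(rbind(c(1.0, 0.5), c(1.5, 0.33)),
                     rbind(c(0.05, 0.03), c(0.05, 0.03)),
                     weights = c(0.5, 0.5), bt = bt)
  segs2 <- seg_row("chr1", 1, 5, 5, 1.4, 0.33)
  expect_equal(assign_segments(segs2, mod2), 2L)
})

test_that("candidate ploidies double from the balanced component", {
  bt <- make_bt(10)
  mod <- make_model(rbind(c(1.0, 0.49), c(1.5, 0.33)),
                    rbind(c(0.05, 0.03), c(0.05, 0.03)),
                    weights = c(0.7, 0.3), bt = bt)
  expect_equal(candidate_ploidies(mod, max_wgd = 2), c(2, 4, 8))
  expect_equal(candidate_ploidies(mod, max_wgd = 0), 2)

  mod$means[1, 1] <- 0.5   # tetraploid-style balanced component
  expect_equal(candidate_ploidies(mod, max_wgd = 2), c(4, 8, 16))

  mod$means[, 2] <- c(0.3, 0.33)  # nothing balanced
  expect_warning(candidate_ploidies(mod), "balanced")
})

test_that("state likelihood recovers exact states and matches an oracle", {
  bt <- make_bt(12)
  om <- state_space(6)
  mod <- make_model(rbind(c(1.0, 0.5), c(1.5, 0.0), c(1.5, 1 / 3)),
                    matrix(0.02, 3, 2), weights = rep(1 / 3, 3), bt = bt)
  rdr <- c(rep(1, 4), rep(1.5, 4), rep(1.5, 4))
  mbaf <- c(rep(0.5, 4), rep(0, 4), rep(1 / 3, 4))
  segs <- rbind(seg_row("chr1", 1, 4, 4, 1.0, 0.5),
                seg_row("chr1", 5, 8, 4, 1.5, 0.0),
                seg_row("chr1", 9, 12, 4, 1.5, 1 / 3))
  a <- 1:3
  sl <- state_likelihood(2, segs, a, mod, om, rdr, mbaf)
  st <- sl$states[order(sl$states$component), ]
  expect_equal(st$c_minor, c(1, 0, 1))
  expect_equal(st$c_major, c(1, 3, 2))

  # independently coded enumeration over the state space
  sig <- scacn:::noise_floor(mod)
  oracle_best <- function(x, y) {
    best <- -Inf; arg <- NULL
    for (r in seq_len(nrow(om))) {
      em <- expected_state_mean(om$c_minor[r], om$c_major[r], 2)
      my <- scacn:::folded_mbaf_mean(em$mbaf, sig[2] / sqrt(1 - 2 / pi))
      ll <- sum(dnorm(x, em$rdr, sig[1], log = TRUE)) +
            sum(dnorm(y, my, sig[2], log = TRUE))
      if (ll > best) { best <- ll; arg <- c(om$c_minor[r], om$c_major[r]) }
    }
    list(ll = best, state = arg)
  }
  tot <- 0
  for (k in 1:3) {
    cols <- segs$start_bin[k]:segs$end_bin[k]
    o <- oracle_best(rdr[cols], mbaf[cols])
    expect_equal(unname(c(st$c_minor[k], st$c_major[k])), o$state)
    tot <- tot + o$ll
  }
  expect_equal(sl$loglik, tot, tolerance = 1e-8)
})

test_that("intermediate states beat the flanking ones at matching bins", {
  bt <- make_bt(6)
  om <- state_space(6)
  mod <- make_model(matrix(c(1.5, 0.33), 1, 2), matrix(0.03, 1, 2),
                    weights = 1, bt = bt)
  rdr <- rep(1.5, 6); mbaf <- rep(1 / 3, 6)
  segs <- seg_row("chr1", 1, 6, 6, 1.5, 1 / 3)
  sl <- state_likelihood(2, segs, 1L, mod, om, rdr, mbaf)
  expect_equal(c(sl$states$c_minor, sl$states$c_major), c(1, 2))
})

test_that("rounding SSE is zero exactly at integral scalings", {
  rdr <- c(0.5, 1, 1.5, 2)
  expect_equal(ploidy_sse(2, rdr), 0)
  expect_gt(ploidy_sse(1.9, rdr), 0)
  expect_equal(ploidy_sse(4, rdr), 0)
})

test_that("weighted BIC keeps clean diploids diploid (scale parsimony)", {
  bt <- make_bt(90)
  om <- state_space(10)
  mod <- make_model(rbind(c(0.5, 0.0), c(1.0, 0.5), c(1.5, 1 / 3)),
                    matrix(0.02, 3, 2), weights = c(0.2, 0.6, 0.2), bt = bt)
  rdr <- c(rep(0.5, 20), rep(1, 50), rep(1.5, 20))
  mbaf <- c(rep(0, 20), rep(0.5, 50), rep(1 / 3, 20))
  segs <- rbind(seg_row("chr1", 1, 20, 20, 0.5, 0),
                seg_row("chr1", 21, 70, 50, 1.0, 0.5),
                seg_row("chr1", 71, 90, 20, 1.5, 1 / 3))
  sel <- select_ploidy(c(2, 4, 8), segs, 1:3, mod, om, rdr, mbaf)
  expect_equal(sel$ploidy, 2)

  # a single perfectly balanced segment: smallest candidate wins the tie
  segs1 <- seg_row("chr1", 1, 90, 90, 1.0, 0.5)
  sel1 <- select_ploidy(c(2, 4, 8), segs1, 1L,
                        make_model(matrix(c(1, 0.5), 1, 2),
                                   matrix(0.02, 1, 2), 1, bt),
                        om, rep(1, 90), rep(0.5, 90))
  expect_equal(sel1$ploidy, 2)
})

test_that("genuine allelic imbalance forces the doubled scale", {
  bt <- make_bt(160)
  om <- state_space(10)
  mod <- make_model(rbind(c(1.0, 0.5), c(1.25, 0.4)),
                    matrix(0.03, 2, 2), weights = c(0.75, 0.25), bt = bt)
  rdr <- c(rep(1, 120), rep(1.25, 40))
  mbaf <- c(rep(0.5, 120), rep(0.4, 40))
  segs <- rbind(seg_row("chr1", 1, 120, 120, 1.0, 0.5),
                seg_row("chr1", 121, 160, 40, 1.25, 0.4))
  sel <- select_ploidy(c(2, 4), segs, 1:2, mod, om, rdr, mbaf)
  expect_equal(sel$ploidy, 4)
  st <- sel$states[order(sel$states$component), ]
  expect_equal(st$c_minor, c(2, 2))
  expect_equal(st$c_major, c(2, 3))
})

test_that("called states are invariant under BAF mirroring", {
  sim <- simulate_dataset(n_cells = 20, bins_per_chrom = 50, n_chroms = 2,
    n_clones = 2, normal_fraction = 0.25, rdr_noise_sd = 0.05,
    baf_noise_sd = 0.03, seed = 77)
  cfg <- acn_config(seed = 77, cbs_n_perm = 200)
  r1 <- run_pipeline(sim$R, sim$baf, sim$bin_table, cfg)
  r2 <- run_pipeline(sim$R, 1 - sim$baf, sim$bin_table, cfg)
  expect_identical(r1$calls$c_minor, r2$calls$c_minor)
  expect_identical(r1$calls$c_major, r2$calls$c_major)
  expect_identical(r1$calls$ploidy, r2$calls$ploidy)
})
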