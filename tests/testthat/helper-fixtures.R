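# small programmatic fixtures shared across tests

make_bt <- function(m, n_chroms = 1, gc = 0.45, map = 1, width = 1e6) {
  per <- m %/% n_chroms
  chrom <- rep(paste0("chr", seq_len(n_chroms)), each = per)
  start <- rep((seq_len(per) - 1) * width, n_chroms)
  bin_table(chrom, start, start + width,
            gc = rep_len(gc, m), mappability = rep_len(map, m))
}

# minimal cellbin_features carrying given rdr/mbaf matrices
make_features <- function(rdr, mbaf, bt) {
  structure(list(R = rdr, X = rdr, X_bar = rowMeans(rdr, na.rm = TRUE),
                 rdr = rdr, baf = mbaf, mbaf = mbaf, bin_table = bt),
            class = "cellbin_features")
}

# hand-built mixture model for calling tests
make_model <- function(means, sds, weights, bt, assignments = NULL) {
  K <- nrow(means)
  covs <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) covs[, , k] <- diag(sds[k, ]^2)
  structure(list(K = K, weights = weights, means = means,
                 covariances = covs, loglik = NA_real_,
                 assignments = assignments, bin_table = bt),
            class = "mixture_model")
}

seg_row <- function(chrom, s, e, n, x, y) {
  data.frame(chrom = chrom, start_bin = s, end_bin = e, n_unmasked = n,
             rdr_mean = x, mbaf_mean = y, stringsAsFactors = FALSE)
}

bps_set <- function(bps, n_bins) {
  structure(list(bps = bps, n_bins = n_bins), class = "breakpoint_sets")
}

# exhaustive-search oracle for the CBS split: naive loops, no prefix sums
oracle_max_arc <- function(x, min_width = 2) {
  n <- length(x)
  best <- list(t = -1, i = NA, j = NA)
  for (i in seq_len(n) - 1) {
    for (j in i:(n - 1)) {
      wa <- j - i + 1
      wc <- n - wa
      if (wa < min_width || wc < min_width) next
      if (i != 0 && i < min_width) next
      if (j != n - 1 && (n - 1 - j) < min_width) next
      arc <- x[(i + 1):(j + 1)]
      comp <- x[-((i + 1):(j + 1))]
      sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) / (n - 2)
      d <- abs(mean(arc) - mean(comp))
      t <- if (sp2 <= 1e-10 * mean(x^2 - mean(x)^2 + 1e-300) + 1e-300) {
        if (d > 1e-9) Inf else 0
      } else {
        d / sqrt(sp2 * (1 / wa + 1 / wc))
      }
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# brute-force maximum bipartite matching by recursion over true breakpoints
oracle_matching <- function(true_bps, pred_bps, l) {
  true_bps <- unique(true_bps)
  pred_bps <- unique(pred_bps)
  recur <- function(ti, used) {
    if (ti > length(true_bps)) return(0)
    best <- recur(ti + 1, used)  # leave this true breakpoint unmatched
    for (pj in seq_along(pred_bps)) {
      if (!used[pj] && abs(true_bps[ti] - pred_bps[pj]) <= l) {
        used[pj] <- TRUE
        best <- max(best, 1 + recur(ti + 1, used))
        used[pj] <- FALSE
      }
    }
    best
  }
  if (length(true_bps) == 0 || length(pred_bps) == 0) return(0)
  recur(1, rep(FALSE, length(pred_bps)))
}
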