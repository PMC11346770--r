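#' Circular binary segmentation of a single signal
#'
#' Recursively splits the signal into segments: at each step the circular
#' arc maximizing the absolute pooled-variance two-sample t statistic
#' between the arc and its complement is located by exhaustive enumeration,
#' and its significance assessed by a permutation test (`n_perm` seeded
#' shuffles, strict exceedances). Significant splits are applied and both
#' resulting pieces are recursed on; the accepted change points are returned
#' as 0-based left-bin indices relative to the input vector. Arcs and the
#' fragments a split would create must span at least `min_width` bins, which
#' avoids degenerate t statistics. A constant signal yields no breakpoints.
#'
#' Each recursion node re-seeds the permutation stream deterministically
#' from `seed` and the node's boundaries, so results at a given node do not
#' depend on how many permutations other nodes consumed (and pruning is
#' monotone in `alpha`).
#'
#' @param x numeric signal (e.g. one chromosome's RDR of one cell),
#'   `NA`-free.
#' @param alpha significance level for a split (default 0.05).
#' @param n_perm permutations per test (default 1000).
#' @param min_width minimum segment width in bins (default 2).
#' @param seed integer seed.
#' @return sorted integer vector of 0-based breakpoint indices (left bin of
#'   each changed pair).
#' @export
cbs_segment <- function(x, alpha = 0.05, n_perm = 1000, min_width = 2,
                        seed = 1) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 1)
  x <- as.numeric(x)
  if (length(x) < 2 || any(is.na(x))) {
    if (any(is.na(x))) stop("NA in CBS input; mask upstream")
    return(integer(0))
  }
  bps <- cbs_recurse(x, 0L, alpha, n_perm, min_width, seed)
  sort(unique(as.integer(bps)))
}

cbs_recurse <- function(x, offset, alpha, n_perm, min_width, seed) {
  n <- length(x)
  if (n < 2 * min_width) return(integer(0))
  if (max(x) - min(x) == 0) return(integer(0))
  sp <- cbs_max_arc_cpp(x, min_width)
  if (sp$i < 0 || sp$t <= 0) return(integer(0))
  set.seed((seed + 131L * (offset + sp$i) + 7L * (offset + sp$j)) %% .Machine$integer.max)
  pt <- cbs_perm_test_cpp(x, sp$t, n_perm, min_width, alpha)
  if (!pt$significant) return(integer(0))

  i <- sp$i; j <- sp$j  # 0-based arc [i..j] within x
  cuts <- integer(0)
  if (i > 0) cuts <- c(cuts, i - 1L)       # left bin before arc start
  if (j < n - 1) cuts <- c(cuts, j)        # arc's last bin
  pieces_start <- c(0L, cuts + 1L)
  pieces_end <- c(cuts, n - 1L)
  out <- offset + cuts
  for (p in seq_along(pieces_start)) {
    s <- pieces_start[p]; e <- pieces_end[p]
    out <- c(out, cbs_recurse(x[(s + 1):(e + 1)], offset + s,
                              alpha, n_perm, min_width, seed))
  }
  out
}

#' Per-cell, per-chromosome CBS on the RDR signal
#'
#' Runs [cbs_segment()] independently on every cell's unmasked RDR within
#' each chromosome and maps the breakpoints back to 0-based genome-wide
#' left-bin indices. A change across a masked gap is reported at the left
#' unmasked bin, matching the convention of [candidate_breakpoints()].
#' Local segmentation runs on RDR only; allelic imbalance enters the
#' pipeline through the global mixture model.
#'
#' @param features a `cellbin_features`.
#' @param alpha,n_perm,min_width,seed see [cbs_segment()].
#' @return list of class `breakpoint_sets`.
#' @export
cbs_all_cells <- function(features, alpha = 0.05, n_perm = 1000,
                          min_width = 2, seed = 1) {
  bt <- features$bin_table
  n <- nrow(features$rdr)
  out <- replicate(n, integer(0), simplify = FALSE)
  chroms <- unique(bt$chrom)
  for (ci in seq_along(chroms)) {
    cols <- which(bt$chrom == chroms[ci] & !bt$masked)
    if (length(cols) < 2) next
    for (i in seq_len(n)) {
      b <- cbs_segment(features$rdr[i, cols], alpha, n_perm, min_width,
                       seed = seed + 100003L * ci)
      if (length(b) > 0) out[[i]] <- c(out[[i]], cols[b + 1L] - 1L)
    }
  }
  structure(list(bps = lapply(out, function(b) sort(as.integer(b))),
                 n_bins = nrow(bt)),
            class = "breakpoint_sets")
}
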