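#' Mask bins with extreme GC content or poor mappability
#'
#' Marks as masked every bin with GC strictly below `gc_low`, strictly above
#' `gc_high`, or mappability strictly below `map_min`; boundary values are
#' kept. Masked bins are excluded (not imputed) from all downstream means,
#' fits and likelihoods.
#'
#' @param bt a `bin_table`.
#' @param gc_low,gc_high GC fraction bounds (defaults 0.2 and 0.8).
#' @param map_min minimum mappability (default 0.9).
#' @return the `bin_table` with an updated `masked` column.
#' @export
mask_bins <- function(bt, gc_low = 0.2, gc_high = 0.8, map_min = 0.9) {
  stopifnot(gc_low >= 0, gc_low < gc_high, gc_high <= 1)
  bt$masked <- bt$gc < gc_low | bt$gc > gc_high | bt$mappability < map_min
  if (all(bt$masked))
    stop(errorCondition("all bins masked by GC/mappability filter",
                        class = c("scacn_all_masked_error", "error")))
  bt
}

#' Gini coefficient of a non-negative count vector
#'
#' Inequality of a cell's bin counts: 0 for a perfectly flat profile,
#' approaching 1 as counts concentrate in few bins. Flat (near-diploid)
#' cells score low, aneuploid multi-state profiles score high.
#' G = sum_ij |x_i - x_j| / (2 n^2 mean(x)); scale-invariant.
#'
#' @param x non-negative numeric vector with positive sum.
#' @return Gini coefficient in \[0, 1).
#' @export
gini_coefficient <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0 || sum(x) <= 0) stop("gini undefined: empty or all-zero vector")
  n <- length(x)
  xs <- sort(x)
  # sum_ij |xi - xj| = 2 * sum_i (2i - n - 1) * x_(i), so the pairwise
  # definition reduces to:
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(x))
}

#' Identify normal (diploid baseline) cells by count flatness
#'
#' Cells whose Gini coefficient over raw bin counts (unmasked bins) is low
#' are taken as normal. Two rules are available. `"absolute"` keeps every
#' cell with Gini at most `gini_threshold`. `"cluster"` anchors on the
#' flattest cell in the sample: cells within `margin` of the minimum Gini
#' (and still under the absolute cap) are kept, which adapts to the
#' coverage-dependent Gini floor — Poisson noise alone lifts every cell's
#' Gini, so a fixed cutoff that separates flat from aneuploid profiles at
#' one coverage fails at another. Returns an empty set, not an error, when
#' no cell qualifies.
#'
#' @param R raw count matrix (cells x bins).
#' @param gini_threshold absolute threshold (default 0.12).
#' @param bt optional `bin_table`; masked bins are ignored.
#' @param method `"absolute"` (default) or `"cluster"`.
#' @param margin Gini distance from the sample minimum tolerated under
#'   `"cluster"` (default 0.02).
#' @return integer vector of normal-cell row indices (possibly empty).
#' @export
identify_normal_cells <- function(R, gini_threshold = 0.12, bt = NULL,
                                  method = c("absolute", "cluster"),
                                  margin = 0.02) {
  method <- match.arg(method)
  keep <- if (!is.null(bt)) !bt$masked else rep(TRUE, ncol(R))
  g <- unname(apply(R[, keep, drop = FALSE], 1, gini_coefficient))
  if (method == "absolute") return(which(g <= gini_threshold))
  which(g <= min(g) + margin & g <= gini_threshold)
}

#' Per-bin normalization factors from normal cells
#'
#' Each factor lambda_j is the mean over normal cells d of R_dj / Rbar_d,
#' the bin's expected deviation in read count relative to the cell's mean
#' coverage. When no normal cells are available, lambda is predicted from a
#' smooth (lowess) fit of the cross-cell median count ratio on GC content,
#' multiplied by mappability and rescaled to mean 1 over unmasked bins.
#' Non-positive factors at unmasked bins cause those bins to be masked with
#' a warning.
#'
#' @param R raw count matrix (cells x bins).
#' @param normal_cells integer indices of normal cells (possibly empty).
#' @param bt a `bin_table`.
#' @param lowess_f lowess smoother span for the GC fallback (default 0.3).
#' @param robust if `TRUE`, lambda is the per-bin median (not mean) of the
#'   normal cells' count ratios; identical to the mean when the normal set
#'   is clean, but resistant to a minority of misidentified aneuploid cells
#'   whose CNAs would otherwise imprint on the factors.
#' @return list with `factors` (per-bin lambda, `NA` at masked bins),
#'   `bin_table` (possibly with extra masked bins), `normal_cells`, `gini`.
#' @export
normalization_factors <- function(R, normal_cells, bt, lowess_f = 0.3,
                                  robust = FALSE) {
  m <- ncol(R)
  unmasked <- !bt$masked
  if (length(normal_cells) > 0) {
    Rn <- R[normal_cells, , drop = FALSE]
    Rbar <- rowMeans(Rn[, unmasked, drop = FALSE])
    if (any(Rbar <= 0)) stop("normal cell with zero mean count")
    ratios <- sweep(Rn, 1, Rbar, "/")
    lam <- if (robust) apply(ratios, 2, median) else colMeans(ratios)
  } else {
    # GC/mappability fallback: smooth of median per-cell count ratio on GC
    Rbar_all <- rowMeans(R[, unmasked, drop = FALSE])
    ok <- Rbar_all > 0
    ratio <- sweep(R[ok, , drop = FALSE], 1, Rbar_all[ok], "/")
    med <- apply(ratio, 2, median)
    fit <- lowess(bt$gc[unmasked], med[unmasked], f = lowess_f)
    pred <- approx_rule2(fit$x, fit$y, bt$gc)
    lam <- pred * bt$mappability
    lam <- lam / mean(lam[unmasked])
  }
  bad <- unmasked & (is.na(lam) | lam <= 0)
  if (any(bad)) {
    warning(sum(bad), " unmasked bin(s) with non-positive normalization factor; masking them")
    bt$masked[bad] <- TRUE
  }
  lam[bt$masked] <- NA_real_
  list(factors = lam, bin_table = bt, normal_cells = normal_cells)
}

# linear interpolation with constant extrapolation, tolerant of ties
approx_rule2 <- function(x, y, xout) {
  ux <- !duplicated(x)
  stats::approx(x[ux], y[ux], xout = xout, rule = 2)$y
}

#' Full preprocessing step: mask, find normals, normalize, build features
#'
#' @param R raw counts, `baf` BAF matrix, `bt` bin annotations.
#' @param baf BAF matrix.
#' @param bt a `bin_table`.
#' @param gc_low,gc_high,map_min masking thresholds (see [mask_bins()]).
#' @param gini_threshold normal-cell Gini cutoff (see [identify_normal_cells()]).
#' @param gini_method,gini_margin normal-cell rule (see
#'   [identify_normal_cells()]); the pipeline defaults to the
#'   coverage-adaptive `"cluster"` rule.
#' @param norm_robust median-based lambda (see [normalization_factors()]).
#' @return list: `features` (a `cellbin_features`), `norm` (output of
#'   [normalization_factors()]), `normal_cells`.
#' @export
preprocess <- function(R, baf, bt, gc_low = 0.2, gc_high = 0.8,
                       map_min = 0.9, gini_threshold = 0.12,
                       gini_method = "cluster", gini_margin = 0.02,
                       norm_robust = TRUE) {
  bt <- mask_bins(bt, gc_low, gc_high, map_min)
  normals <- identify_normal_cells(R, gini_threshold, bt,
                                   method = gini_method,
                                   margin = gini_margin)
  norm <- normalization_factors(R, normals, bt, robust = norm_robust)
  feats <- compute_features(R, baf, norm$bin_table, norm$factors)
  list(features = feats, norm = norm, normal_cells = normals)
}
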