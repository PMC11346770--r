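#' Log-scaled sum-of-squares error between copy-number profiles
#'
#' Per cell, `ln(1 + sum_j (true_j - est_j)^2)` over the bins where both
#' profiles are non-missing: 0 for a perfect call, ln(2) for a single bin
#' off by one. The log keeps cells with catastrophic ploidy errors from
#' dominating dataset means.
#'
#' @param true_cn,est_cn cell x bin integer matrices of total copy numbers
#'   (`NA` allowed, e.g. masked bins).
#' @return numeric vector, one value per cell.
#' @export
lsse <- function(true_cn, est_cn) {
  stopifnot(all(dim(true_cn) == dim(est_cn)))
  vapply(seq_len(nrow(true_cn)), function(i) {
    ok <- is.finite(true_cn[i, ]) & is.finite(est_cn[i, ])
    if (!any(ok)) stop("no shared bins for cell ", i)
    log1p(sum((true_cn[i, ok] - est_cn[i, ok])^2))
  }, numeric(1))
}

#' Allele-specific LSSE over mirrored state pairs
#'
#' States are compared in the unordered representation: minor against minor
#' and major against major after sorting each pair, then the squared errors
#' of both alleles are summed and log-scaled as in [lsse()]. Truth \{1,2\}
#' against estimate \{2,1\} scores 0.
#'
#' @param true_minor,true_major,est_minor,est_major cell x bin matrices.
#' @return numeric vector, one value per cell.
#' @export
allele_lsse <- function(true_minor, true_major, est_minor, est_major) {
  t_lo <- pmin(true_minor, true_major); t_hi <- pmax(true_minor, true_major)
  e_lo <- pmin(est_minor, est_major); e_hi <- pmax(est_minor, est_major)
  vapply(seq_len(nrow(t_lo)), function(i) {
    ok <- is.finite(t_lo[i, ]) & is.finite(e_lo[i, ])
    if (!any(ok)) stop("no shared bins for cell ", i)
    log1p(sum((t_lo[i, ok] - e_lo[i, ok])^2 + (t_hi[i, ok] - e_hi[i, ok])^2))
  }, numeric(1))
}

#' Ploidy-adjusted LSSE
#'
#' Rescales each cell's estimated total copy numbers by
#' `true_ploidy / est_ploidy`, rounds to integers, and computes [lsse()]:
#' a pure ploidy-scale error (e.g. a diploid call of a tetraploid cell with
#' exactly halved states) vanishes, isolating segmentation error from
#' ploidy error.
#'
#' @param true_cn,est_cn cell x bin total copy-number matrices.
#' @param true_ploidy,est_ploidy per-cell ploidies (`est_ploidy > 0`).
#' @return numeric vector, one value per cell.
#' @export
adjusted_lsse <- function(true_cn, est_cn, true_ploidy, est_ploidy) {
  stopifnot(all(est_ploidy > 0))
  scaled <- round(est_cn * (true_ploidy / est_ploidy))
  lsse(true_cn, scaled)
}

#' Breakpoint precision / recall / F1 under a bin tolerance
#'
#' A predicted breakpoint is validated if it lies within `l` bins of a true
#' breakpoint, but each true breakpoint may validate at most one prediction:
#' the validated count is the maximum-cardinality matching of the bipartite
#' graph with edges |true - pred| <= l. Precision = matched / |pred|,
#' recall = matched / |true| (1 when the respective set is empty), F1 the
#' harmonic mean (0 when either is 0).
#'
#' @param true_bps,pred_bps integer vectors of breakpoint indices.
#' @param l non-negative tolerance in bins (default 1).
#' @return named numeric vector: precision, recall, f1, matched.
#' @export
breakpoint_prf <- function(true_bps, pred_bps, l = 1) {
  stopifnot(l >= 0)
  true_bps <- unique(as.integer(true_bps))
  pred_bps <- unique(as.integer(pred_bps))
  nt <- length(true_bps); np <- length(pred_bps)
  if (nt == 0 || np == 0) {
    matched <- 0
  } else {
    edges <- do.call(rbind, lapply(seq_len(nt), function(a) {
      b <- which(abs(pred_bps - true_bps[a]) <= l)
      if (length(b)) cbind(a, nt + b) else NULL
    }))
    if (is.null(edges)) {
      matched <- 0
    } else {
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      g <- igraph::add_vertices(g, max(0, nt + np - igraph::vcount(g)))
      igraph::V(g)$type <- seq_len(nt + np) > nt
      matched <- igraph::max_bipartite_match(g)$matching_size
    }
  }
  precision <- if (np == 0) 1 else matched / np
  recall <- if (nt == 0) 1 else matched / nt
  f1 <- if (precision == 0 || recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1, matched = matched)
}

#' Agreement between true and estimated cell ploidies
#'
#' @param true_ploidies,est_ploidies numeric vectors of equal length
#'   (n >= 2 for the correlation).
#' @return named numeric vector: `pcc` (Pearson correlation, `NA` when
#'   either vector has zero variance) and `rmse`.
#' @export
ploidy_agreement <- function(true_ploidies, est_ploidies) {
  stopifnot(length(true_ploidies) == length(est_ploidies))
  rmse <- sqrt(mean((true_ploidies - est_ploidies)^2))
  pcc <- if (length(true_ploidies) >= 2 && sd(true_ploidies) > 0 &&
             sd(est_ploidies) > 0) {
    cor(true_ploidies, est_ploidies)
  } else NA_real_
  c(pcc = pcc, rmse = rmse)
}

#' Evaluate calls against a simulated truth
#'
#' Computes per-cell total/allele/adjusted LSSE, breakpoint precision,
#' recall and F1 at tolerance `l` (tumor cells; final breakpoints come from
#' the call's segment boundaries), ploidy agreement, and the fraction of
#' unmasked bins with exactly correct allele-specific state.
#'
#' @param calls an `acn_calls`.
#' @param truth a `sim_truth`.
#' @param final_bps optional `breakpoint_sets` of the final per-cell
#'   breakpoints used for the calls (for the P/R/F1 block).
#' @param l breakpoint matching tolerance in bins (default 1).
#' @return list of class `acn_eval`: `per_cell` data.frame and `summary`
#'   named vector of dataset means.
#' @export
evaluate_calls <- function(calls, truth, final_bps = NULL, l = 1) {
  true_total <- truth$c_minor + truth$c_major
  est_total <- calls$c_minor + calls$c_major
  tot <- lsse(true_total, est_total)
  all_l <- allele_lsse(truth$c_minor, truth$c_major,
                       calls$c_minor, calls$c_major)
  adj <- adjusted_lsse(true_total, est_total, truth$ploidy, calls$ploidy)

  n <- length(calls$ploidy)
  prf <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("precision", "recall", "f1")))
  if (!is.null(final_bps)) {
    for (i in seq_len(n)) {
      prf[i, ] <- breakpoint_prf(truth$breakpoints$bps[[i]],
                                 final_bps$bps[[i]], l)[1:3]
    }
  }
  ok <- is.finite(truth$c_minor) & is.finite(calls$c_minor)
  state_acc <- mean((truth$c_minor == calls$c_minor &
                     truth$c_major == calls$c_major)[ok])
  pa <- ploidy_agreement(truth$ploidy, calls$ploidy)

  per_cell <- data.frame(cell = seq_len(n), clone = truth$cell_clone,
                         true_ploidy = truth$ploidy,
                         est_ploidy = calls$ploidy,
                         total_lsse = tot, allele_lsse = all_l,
                         adjusted_lsse = adj, prf)
  summary <- c(total_lsse = mean(tot), allele_lsse = mean(all_l),
               adjusted_lsse = mean(adj),
               precision = mean(prf[, 1]), recall = mean(prf[, 2]),
               f1 = mean(prf[, 3]), state_accuracy = state_acc,
               ploidy_pcc = unname(pa["pcc"]), ploidy_rmse = unname(pa["rmse"]))
  structure(list(per_cell = per_cell, summary = summary), class = "acn_eval")
}

#' @export
print.acn_eval <- function(x, ...) {
  cat("acn_eval summary (dataset means):\n")
  print(round(x$summary, 4))
  invisible(x)
}
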