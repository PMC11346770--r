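#' Fit the global Gaussian mixture over the (RDR, mBAF) feature space
#'
#' All unmasked bins of all cells are pooled as 2D points V = (RDR, mBAF)
#' and modeled as a K-component full-covariance Gaussian mixture: bins
#' sharing a latent allele-specific copy-number state share a component.
#' For each K in `[k_min, k_max]` the mixture is fit by EM with `n_restarts`
#' seeded restarts (restart 1 initialized from k-means centers, the rest
#' from randomly sampled distinct points); the model minimizing
#' BIC = P ln(N) - 2 loglik is returned, with P = 6K - 1 free parameters
#' (K-1 weights, 2K means, 3K covariance terms). Covariances are kept
#' positive-definite with a diagonal ridge.
#'
#' K values exceeding the number of distinct data points are skipped (EM
#' cannot populate more point-mass components than there are locations); if
#' none remain, a single fit at K = number of distinct points is used.
#'
#' @param features a `cellbin_features`.
#' @param k_min,k_max component-count search range (defaults 8 and 25).
#' @param seed integer seed controlling k-means and restart initializations.
#' @param n_restarts EM restarts per K (default 5).
#' @param k_extend if `TRUE` (default), a BIC minimum sitting exactly at
#'   `k_max` triggers extension of the scan (standard model-selection
#'   hygiene: a boundary optimum means the range was too small), in steps
#'   of 5 components, until the optimum is interior or the number of
#'   distinct points is reached.
#' @param k_patience abandon the scan after this many consecutive K values
#'   without a BIC improvement (default 5; `Inf` scans the full range).
#' @param fit_cap when the data exceed this many weighted points, the
#'   K scan runs on a seeded random subsample of this size and only the
#'   selected K is refit on the full data (warm-started from the subsample
#'   solution); default 8000.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param ridge diagonal covariance regularizer (default 1e-6).
#' @return list of class `mixture_model`: `K`, `weights`, `means` (K x 2,
#'   columns rdr/mbaf), `covariances` (2 x 2 x K), `loglik`, `loglik_trace`,
#'   `assignments` (n x m matrix, `NA` at masked bins), `bic_table`, plus
#'   the pooled `data` points and their `cells`/`bins` indices.
#' @export
fit_gmm <- function(features, k_min = 8, k_max = 25, seed = 1,
                    n_restarts = 5, max_iter = 150, tol = 1e-6,
                    ridge = 1e-6, k_extend = TRUE, k_patience = 5,
                    fit_cap = 8000) {
  stopifnot(k_min >= 1, k_max >= k_min)
  pts <- gmm_points(features)
  V <- pts$V
  N <- nrow(V)
  if (N < k_max) stop("fewer unmasked points than k_max")

  # collapse duplicate feature values into weighted points: exact for the
  # mixture likelihood, and it conditions EM well when many bins share a
  # feature location (the no-noise limit)
  key <- paste(V[, 1], V[, 2])
  first <- !duplicated(key)
  U <- V[first, , drop = FALSE]
  cnt <- as.numeric(table(factor(key, levels = key[first])))
  map <- match(key, key[first])

  n_distinct <- nrow(U)
  ks <- seq(k_min, k_max)
  ks <- ks[ks <= n_distinct]
  if (length(ks) == 0) ks <- n_distinct

  # the K scan may run on a subsample; the selected K is refit on the
  # full weighted data afterwards
  if (nrow(U) > fit_cap) {
    set.seed(seed)
    sub <- sample.int(nrow(U), fit_cap, prob = cnt)
    Uf <- U[sub, , drop = FALSE]
    cf <- rep(1, fit_cap)
  } else {
    Uf <- U
    cf <- cnt
  }
  Nf <- sum(cf)

  best <- NULL
  prev_fit <- NULL
  stale <- 0
  bic_table <- data.frame(K = integer(), loglik = numeric(), bic = numeric())
  repeat {
    for (K in ks) {
      # inits per K: warm starts from the previous K with each of its two
      # widest components bisected in turn (resolves heavy pooled
      # components that k-means and random starts miss), then k-means,
      # then random distinct points, n_restarts EM runs in total
      inits <- list()
      if (!is.null(prev_fit) && nrow(prev_fit$means) == K - 1) {
        inits <- lapply(seq_len(min(2, K - 1, n_restarts - 1)),
                        function(rank) split_init(prev_fit, rank))
      }
      fit_k <- NULL
      for (r in seq_len(max(1, n_restarts - length(inits)))) {
        set.seed(seed + 1009L * K + r)
        inits[[length(inits) + 1L]] <-
          list(means = gmm_init_means(Uf, K, kmeans_init = (r == 1)),
               weights = numeric(0), covs = numeric(0))
      }
      for (ini in inits) {
        fit <- em_gmm_cpp(Uf, cf, ini$means, ini$weights, ini$covs,
                          max_iter, tol, ridge)
        if (is.null(fit_k) || fit$loglik > fit_k$loglik) fit_k <- fit
      }
      prev_fit <- fit_k
      bic <- (6 * K - 1) * log(Nf) - 2 * fit_k$loglik
      bic_table <- rbind(bic_table,
                         data.frame(K = K, loglik = fit_k$loglik, bic = bic))
      if (is.null(best) || bic < best$bic) {
        best <- list(K = K, fit = fit_k, bic = bic)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= k_patience) break
      }
    }
    top <- max(bic_table$K)
    if (stale >= k_patience || !k_extend || best$K < top ||
        top >= n_distinct) break
    ks <- seq(top + 1L, min(top + 5L, n_distinct))
  }

  fit <- best$fit
  if (nrow(Uf) < nrow(U)) {
    fit <- em_gmm_cpp(U, cnt, as.matrix(fit$means), as.numeric(fit$weights),
                      as.numeric(fit$covariances), max_iter, tol, ridge)
  }
  fit$assignments <- fit$assignments[map]
  build_mixture_model(fit, pts, features, bic_table)
}

# pooled unmasked (rdr, mbaf) points with their (cell, bin) provenance
gmm_points <- function(features) {
  ok <- is.finite(features$rdr) & is.finite(features$mbaf)
  idx <- which(ok, arr.ind = TRUE)
  V <- cbind(features$rdr[ok], features$mbaf[ok])
  colnames(V) <- c("rdr", "mbaf")
  list(V = V, cells = idx[, 1], bins = idx[, 2],
       dim = dim(features$rdr))
}

# warm start for K components from a (K-1)-component fit: the rank-th
# highest-spread component (weight times covariance trace) is bisected
# along its principal axis, keeping all other parameters
split_init <- function(fit, rank = 1) {
  mu <- as.matrix(fit$means)
  K1 <- nrow(mu)
  covs <- array(fit$covariances, dim = c(2, 2, K1))
  w <- as.numeric(fit$weights)
  spread <- vapply(seq_len(K1), function(k) {
    w[k] * (covs[1, 1, k] + covs[2, 2, k])
  }, numeric(1))
  k <- order(spread, decreasing = TRUE)[min(rank, K1)]
  eg <- eigen(covs[, , k], symmetric = TRUE)
  dir <- eg$vectors[, 1] * sqrt(max(eg$values[1], 1e-12))
  child_cov <- covs[, , k] / 4

  means <- rbind(mu[-k, , drop = FALSE], mu[k, ] + dir, mu[k, ] - dir,
                 deparse.level = 0)
  weights <- c(w[-k], w[k] / 2, w[k] / 2)
  covs_new <- array(0, dim = c(2, 2, K1 + 1))
  covs_new[, , seq_len(K1 - 1)] <- covs[, , -k, drop = FALSE]
  covs_new[, , K1] <- child_cov
  covs_new[, , K1 + 1] <- child_cov
  list(means = means, weights = weights, covs = as.numeric(covs_new))
}

gmm_init_means <- function(V, K, kmeans_init = FALSE) {
  if (kmeans_init) {
    km <- tryCatch(
      suppressWarnings(kmeans(V, centers = K, iter.max = 30, nstart = 1)),
      error = function(e) NULL)
    if (!is.null(km)) return(unname(km$centers))
  }
  uv <- unique(V)
  uv[sample(nrow(uv), K), , drop = FALSE]
}

build_mixture_model <- function(fit, pts, features, bic_table = NULL) {
  A <- matrix(NA_integer_, pts$dim[1], pts$dim[2])
  A[cbind(pts$cells, pts$bins)] <- fit$assignments
  structure(list(
    K = nrow(fit$means), weights = as.numeric(fit$weights),
    means = `colnames<-`(as.matrix(fit$means), c("rdr", "mbaf")),
    covariances = array(fit$covariances, dim = c(2, 2, nrow(fit$means))),
    loglik = fit$loglik,
    loglik_trace = as.numeric(fit$loglik_trace %||% fit$loglik),
    assignments = A, bic_table = bic_table,
    data = pts$V, cells = pts$cells, bins = pts$bins,
    bin_table = features$bin_table
  ), class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: K = %d components on %d points, loglik = %.2f\n",
              x$K, nrow(x$data), x$loglik))
  invisible(x)
}

#' Merge near-duplicate mixture components
#'
#' Over-clustering from noisy, unevenly populated copy-number states is
#' corrected by iteratively merging the closest groups of components under
#' the weighted distance `sqrt((d rdr)^2 + baf_weight * (d mbaf)^2)`, with
#' complete linkage: a group is merged only while ALL its members lie
#' strictly within `delta` of one another. Bounding the merged diameter by
#' `delta` stops chains from fusing distinct copy-number states whose
#' cross-clone ladders interleave at spacings below `delta` (single-link
#' chaining would, and one merged component can only carry one state per
#' cell downstream). Merged weight is the sum, the merged mean the
#' weight-proportional average, and the merged covariance the
#' moment-matched mixture covariance. The mBAF axis is down-weighted by
#' default because BAF is the noisier feature at low coverage. Points are
#' reassigned to the merged components afterwards.
#'
#' @param model a `mixture_model`.
#' @param delta merge distance threshold (default 0.1); `delta = 0` returns
#'   the model unchanged.
#' @param baf_weight weight of the mBAF axis in the distance, in \[0, 1\]
#'   (default 0.5).
#' @return a `mixture_model` with `K` less than or equal to the input's.
#' @export
merge_components <- function(model, delta = 0.1, baf_weight = 0.5) {
  stopifnot(delta >= 0, baf_weight >= 0, baf_weight <= 1)
  if (delta == 0 || model$K == 1) return(model)
  w0 <- model$weights
  mu0 <- model$means
  S0 <- model$covariances
  K0 <- model$K

  dx <- outer(mu0[, 1], mu0[, 1], "-")
  dy <- outer(mu0[, 2], mu0[, 2], "-")
  D <- sqrt(dx^2 + baf_weight * dy^2)
  grp <- if (min(D[upper.tri(D)]) < delta) {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    stats::cutree(hc, h = delta * (1 - 1e-12))  # strict '< delta' semantics
  } else {
    seq_len(K0)
  }

  G <- max(grp)
  w <- numeric(G)
  mu <- matrix(0, G, 2)
  S <- array(0, dim = c(2, 2, G))
  for (g in seq_len(G)) {
    mem <- which(grp == g)
    wg <- w0[mem]
    w[g] <- sum(wg)
    mu[g, ] <- colSums(wg * mu0[mem, , drop = FALSE]) / w[g]
    Sm <- matrix(0, 2, 2)
    for (k in mem) {
      dk <- mu0[k, ] - mu[g, ]
      Sm <- Sm + w0[k] * (S0[, , k] + tcrossprod(dk))
    }
    S[, , g] <- Sm / w[g]
  }

  re <- gmm_assign_cpp(model$data, w, mu, as.numeric(S))
  out <- model
  out$K <- length(w)
  out$weights <- w
  out$means <- `colnames<-`(as.matrix(mu), c("rdr", "mbaf"))
  out$covariances <- S
  out$loglik <- re$loglik
  A <- matrix(NA_integer_, nrow(model$assignments), ncol(model$assignments))
  A[cbind(model$cells, model$bins)] <- re$assignments
  out$assignments <- A
  out
}

#' Remove isolated assignment flips along the genome
#'
#' The mixture model treats bins as exchangeable, so at realistic noise a
#' bin lying between two overlapping components flips assignment
#' independently of its neighbours, fragmenting the downstream
#' segmentation. This filter restores the spatial structure minimally: a
#' single bin whose two same-chromosome unmasked neighbours agree with
#' each other but not with it takes their assignment, provided its own
#' component explains it only weakly — the bin's log-density under its own
#' component must exceed that under the neighbours' component by less than
#' `margin` nats. Decisively assigned single-bin segments (real focal
#' events, or any bin in noiseless data) are never altered, and runs of
#' two or more bins are never altered.
#'
#' @param model a `mixture_model`.
#' @param window smoothing window; 3 (default) applies the single-bin
#'   rule, 1 disables smoothing.
#' @param margin maximum own-vs-neighbour log-density advantage for a bin
#'   to count as ambiguous (default 6, roughly 400:1 evidence).
#' @return the `mixture_model` with smoothed `assignments`.
#' @export
smooth_assignments <- function(model, window = 3, margin = 6) {
  stopifnot(window %in% c(1, 3))
  if (window == 1) return(model)
  bt <- model$bin_table
  A <- model$assignments
  Vr <- Vy <- matrix(NA_real_, nrow(A), ncol(A))
  Vr[cbind(model$cells, model$bins)] <- model$data[, 1]
  Vy[cbind(model$cells, model$bins)] <- model$data[, 2]
  dens <- function(comp, i, j) {
    vapply(seq_along(comp), function(q) {
      k <- comp[q]
      ldbvn_r(Vr[i[q], j[q]], Vy[i[q], j[q]],
              model$means[k, 1], model$means[k, 2],
              model$covariances[, , k])
    }, numeric(1))
  }
  for (ch in unique(bt$chrom)) {
    cols <- which(bt$chrom == ch & !bt$masked)
    L <- length(cols)
    if (L < 3) next
    mid <- cols[2:(L - 1)]
    lef <- cols[1:(L - 2)]
    rig <- cols[3:L]
    flip <- A[, lef, drop = FALSE] == A[, rig, drop = FALSE] &
            A[, mid, drop = FALSE] != A[, lef, drop = FALSE]
    idx <- which(flip, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i <- idx[, 1]
    jm <- mid[idx[, 2]]
    own <- A[cbind(i, jm)]
    nb <- A[cbind(i, lef[idx[, 2]])]
    ambiguous <- dens(own, i, jm) - dens(nb, i, jm) < margin
    take <- idx[ambiguous, , drop = FALSE]
    if (nrow(take) > 0) {
      A[cbind(take[, 1], mid[take[, 2]])] <-
        A[cbind(take[, 1], lef[take[, 2]])]
    }
  }
  model$assignments <- A
  model
}

#' Per-cell candidate breakpoints from component assignments
#'
#' A breakpoint is recorded wherever two consecutive unmasked bins on the
#' same chromosome carry different component assignments, reported as the
#' 0-based genome-wide index of the LEFT bin of the changed pair (the
#' package-wide breakpoint convention). A change across a masked gap yields
#' one breakpoint at the left unmasked bin; chromosome boundaries never
#' produce breakpoints.
#'
#' @param model a `mixture_model` with assignments.
#' @param bt a `bin_table` (defaults to the one stored in the model).
#' @return list of class `breakpoint_sets`: `bps` (per-cell sorted integer
#'   vectors of 0-based left-bin indices) and `n_bins`.
#' @export
candidate_breakpoints <- function(model, bt = model$bin_table) {
  A <- model$assignments
  n <- nrow(A)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- integer(0)
  for (ch in unique(bt$chrom)) {
    cols <- which(bt$chrom == ch & !bt$masked)
    if (length(cols) < 2) next
    left <- cols[-length(cols)]
    right <- cols[-1]
    D <- A[, left, drop = FALSE] != A[, right, drop = FALSE]
    for (i in seq_len(n)) {
      hit <- which(D[i, ])
      if (length(hit) > 0) out[[i]] <- c(out[[i]], left[hit] - 1L)
    }
  }
  structure(list(bps = lapply(out, function(b) sort(as.integer(b))),
                 n_bins = nrow(bt)),
            class = "breakpoint_sets")
}
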