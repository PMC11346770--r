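#' Assign segments to mixture components
#'
#' Each segment goes to the component at minimum Euclidean distance from
#' its (RDR mean, mBAF mean) in the feature space; ties are broken toward
#' the larger-weight component, then the lower component index.
#'
#' @param segments a `segment_sets`, or a single cell's segment data.frame.
#' @param model a `mixture_model`.
#' @return integer vector (single cell) or list of integer vectors:
#'   component index per segment (`NA` for segments with no unmasked bins).
#' @export
assign_segments <- function(segments, model) {
  if (inherits(segments, "segment_sets"))
    return(lapply(segments$segments, assign_segments, model = model))
  mu <- model$means
  w <- model$weights
  vapply(seq_len(nrow(segments)), function(z) {
    if (!is.finite(segments$rdr_mean[z])) return(NA_integer_)
    d <- sqrt((segments$rdr_mean[z] - mu[, 1])^2 +
              (segments$mbaf_mean[z] - mu[, 2])^2)
    cand <- which(d - min(d) < 1e-12)
    if (length(cand) > 1) cand <- cand[order(-w[cand], cand)]
    as.integer(cand[1])
  }, integer(1))
}

#' WGD-aware candidate ploidies from a balanced component
#'
#' Identifies the highest-weight component whose mean mBAF lies within
#' `balanced_tol` of 0.5 (a "balanced" state, with equal allele copies) and
#' derives candidate ploidies `2^(w+1) / rdr_k` for whole-genome-duplication
#' counts `w = 0..max_wgd`: if the balanced state is \{1,1\}, its RDR is
#' 2/ploidy, so the w = 0 candidate recovers the ploidy exactly, and each
#' further WGD doubles it. When no balanced component exists the
#' highest-weight component is used, with a warning.
#'
#' @param model a `mixture_model`.
#' @param max_wgd maximum number of whole-genome duplications (default 2).
#' @param balanced_tol tolerance on |mBAF - 0.5| (default 0.05).
#' @return numeric vector of candidate ploidies, increasing.
#' @export
candidate_ploidies <- function(model, max_wgd = 2, balanced_tol = 0.05) {
  stopifnot(max_wgd >= 0)
  bal <- which(abs(model$means[, 2] - 0.5) <= balanced_tol &
               model$means[, 1] > 0.1)
  if (length(bal) == 0) {
    warning("no balanced component within tolerance; using highest-weight component")
    bal <- seq_len(model$K)
  }
  k <- bal[which.max(model$weights[bal])]
  ploidies_from_balanced_rdr(model$means[k, 1], max_wgd)
}

ploidies_from_balanced_rdr <- function(rdr_k, max_wgd) {
  stopifnot(rdr_k > 0)
  2^(seq_len(max_wgd + 1)) / rdr_k
}

#' Best copy-number states and likelihood at a given ploidy
#'
#' For each mixture component holding at least one of the cell's segments,
#' enumerates the bounded state space and picks the state maximizing the
#' summed log-density of the component's bins under a Gaussian centered at
#' the state's expected (RDR, mBAF) for ploidy `p`, with the component's
#' covariance. Returns the per-component best states and the total
#' log-likelihood.
#'
#' The expected mBAF of each state is folded: mirroring maps BAF noise
#' around 0.5 downward, so observed mBAF of a balanced state concentrates
#' at `0.5 - sigma * sqrt(2/pi)`, not 0.5. Each state's expectation is
#' therefore the folded-normal mean at the component's mBAF standard
#' deviation. Without this, states with expected mBAF slightly below 0.5
#' (odd totals at a doubled ploidy, e.g. \{4,5\}) systematically out-fit
#' the true balanced state on noisy data, biasing ploidy selection toward
#' spurious whole-genome doublings. The adjustment vanishes as the
#' component variance goes to zero.
#'
#' Discrimination between states uses a single diagonal noise scale for
#' all components — per axis, the smallest standard deviation among
#' components carrying at least 2% of the weight. Components that absorbed
#' several neighbouring clusters (by merging or a tight BIC budget) have
#' inflated, correlated covariances; taken at face value these both flatten
#' the RDR axis (hiding one-copy differences) and let distant states
#' "explain" data through the spurious off-diagonal term. The sharpest
#' well-supported component is the cleanest available estimate of the
#' actual measurement noise. The mBAF standard deviation entering the fold
#' correction is first unfolded by 1/sqrt(1 - 2/pi), since near-balanced
#' mirroring also compresses the fitted spread.
#'
#' @param p candidate ploidy.
#' @param segments one cell's segment data.frame (from [build_segments()]).
#' @param assignment integer component per segment (from [assign_segments()]).
#' @param model a `mixture_model`.
#' @param omega state space data.frame (from [state_space()]).
#' @param rdr,mbaf the cell's per-bin feature vectors (length = total bins).
#' @return list: `states` (data.frame component, c_minor, c_major),
#'   `loglik`.
#' @export
state_likelihood <- function(p, segments, assignment, model, omega,
                             rdr, mbaf) {
  stopifnot(p > 0)
  bt <- model$bin_table
  exp_mean <- expected_state_mean(omega$c_minor, omega$c_major, p)
  sig <- noise_floor(model)
  S <- diag(sig^2)
  mbaf_exp <- folded_mbaf_mean(exp_mean$mbaf, sig[2] / sqrt(1 - 2 / pi))
  comps <- sort(unique(assignment[!is.na(assignment)]))
  total_ll <- 0
  states <- data.frame(component = integer(), c_minor = integer(),
                       c_major = integer())
  for (k in comps) {
    cols <- unlist(lapply(which(assignment == k), function(z) {
      segments$start_bin[z]:segments$end_bin[z]
    }))
    cols <- cols[!bt$masked[cols]]
    x <- rdr[cols]; y <- mbaf[cols]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    ll_states <- vapply(seq_len(nrow(omega)), function(s) {
      sum(ldbvn_r(x, y, exp_mean$rdr[s], mbaf_exp[s], S))
    }, numeric(1))
    best <- which.max(ll_states)
    total_ll <- total_ll + ll_states[best]
    states <- rbind(states, data.frame(component = k,
                                       c_minor = omega$c_minor[best],
                                       c_major = omega$c_major[best]))
  }
  list(states = states, loglik = total_ll)
}

# per-axis measurement noise: weight-weighted lower quartile of the
# component sds (wide components are pooling artifacts rather than noise;
# the single tightest component can undershoot by luck)
noise_floor <- function(model) {
  wq <- function(v, w, q) {
    o <- order(v)
    v <- v[o]; w <- w[o] / sum(w)
    v[which(cumsum(w) >= q)[1]]
  }
  sx <- wq(sqrt(model$covariances[1, 1, ]), model$weights, 0.25)
  sy <- wq(sqrt(model$covariances[2, 2, ]), model$weights, 0.25)
  c(max(sx, 1e-4), max(sy, 1e-4))
}

# expected observed mBAF for a true allelic fraction b <= 0.5 under
# Gaussian noise of sd sigma followed by mirroring: 0.5 - E|N(0.5-b, sigma)|
# (folded-normal mean); reduces to b as sigma -> 0
folded_mbaf_mean <- function(b, sigma) {
  if (sigma <= 0) return(b)
  mu <- 0.5 - b
  r <- mu / sigma
  e_abs <- mu * (2 * stats::pnorm(r) - 1) + 2 * sigma * stats::dnorm(r)
  0.5 - e_abs
}

# vectorized bivariate normal log-density, covariance S (2x2)
ldbvn_r <- function(x, y, mx, my, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  e0 <- x - mx; e1 <- y - my
  q <- (S[2, 2] * e0^2 - 2 * S[1, 2] * e0 * e1 + S[1, 1] * e1^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Ploidy rounding residual (sum-of-squares error)
#'
#' `phi(p)` is the summed squared distance between each scaled copy-number
#' estimate `p * rdr_j` and its nearest integer, over the cell's unmasked
#' bins: zero exactly when every scaled estimate is integral.
#'
#' @param p ploidy.
#' @param rdr the cell's RDR values (NA entries dropped).
#' @return non-negative scalar.
#' @export
ploidy_sse <- function(p, rdr) {
  x <- p * rdr[is.finite(rdr)]
  sum((x - round(x))^2)
}

#' Select a cell's ploidy by weighted BIC and materialize its states
#'
#' Evaluates, for every candidate ploidy p, the weighted BIC
#' `phi(p) * ln(m) * |Omega| - 2 L(p)` where `m` is the number of the
#' cell's unmasked bins and `L` the state likelihood of
#' [state_likelihood()] (states re-optimized per candidate). `phi` is the
#' rounding sum-of-squares on segment mean RDR, weighted by segment bin
#' counts: `sum_z n_z (p * rdr_z - round(p * rdr_z))^2`, restricted to
#' supported segments (at least 5 bins; all segments if none qualify).
#' When a separate `phi_segments` table is supplied (the pipeline passes
#' the cell's CBS segmentation), `phi` is evaluated on it instead of on
#' the ensemble segments: the per-cell CBS segments are calibrated against
#' the cell's own noise by the permutation test, so their means stay pure
#' even where the global mixture under-resolves neighbouring states.
#' Segment means concentrate near integer multiples of `1/p` at the true
#' scale, land on half-integers at half the scale wherever the total is
#' odd, and pick up four times the squared residual at doubled scale, so
#' `phi` retains its scale signal at noise levels where raw per-bin
#' residuals are already uniform (the per-bin form is available as
#' [ploidy_sse()]). Support matters: segment membership of long segments
#' is spatial, so their means carry no bias, whereas short segments born
#' of noise-driven assignment flips collect bins selected for sitting
#' between states — their means anti-align with the true grid and align
#' with its half-spacing refinement, actively inverting the scale signal.
#'
#' Scale selection is guarded against spurious whole-genome doublings,
#' which the likelihood alone cannot resist: the state space at a doubled
#' ploidy contains every state of the original scale (doubled) plus the
#' odd-total refinements, so `L` never decreases under doubling.
#' Candidates are therefore scanned in increasing order and a larger
#' candidate replaces the current choice only when it clears two hurdles:
#' its state map must not be a plain integer multiple of the current one
#' (a multiple describes the same profile at another scale — parsimony
#' keeps the smaller), and its log-likelihood gain must exceed
#' `ln(m) |Omega| / 2`, a BIC-type charge of half the weighted-BIC penalty
#' unit for unlocking the refined state grid. Genuine duplications clear
#' this easily — segments with odd totals fit the halved scale miserably —
#' while noise- and segmentation-artifact gains fall short. Among
#' candidates clearing the hurdles, the weighted BIC decides; exact ties
#' go to the smaller ploidy.
#'
#' @param candidates numeric vector of candidate ploidies.
#' @param segments,assignment,model,omega,rdr,mbaf see [state_likelihood()].
#' @param phi_segments optional segment table used for `phi` (defaults to
#'   `segments`).
#' @return list: `ploidy`, `wgd` (index of winning candidate minus 1),
#'   `states`, `loglik`, `bic_trace` (data.frame candidate/phi/loglik/wbic).
#' @export
select_ploidy <- function(candidates, segments, assignment, model, omega,
                          rdr, mbaf, phi_segments = NULL) {
  stopifnot(length(candidates) > 0)
  m_unmasked <- sum(is.finite(rdr))
  if (is.null(phi_segments)) phi_segments <- segments
  seg_ok <- is.finite(phi_segments$rdr_mean) & phi_segments$n_unmasked >= 5
  if (!any(seg_ok)) seg_ok <- is.finite(phi_segments$rdr_mean)
  ord <- order(candidates)
  best <- NULL
  trace <- data.frame(candidate = numeric(), phi = numeric(),
                      loglik = numeric(), wbic = numeric())
  for (ci in ord) {
    p <- candidates[ci]
    sl <- state_likelihood(p, segments, assignment, model, omega, rdr, mbaf)
    sx <- p * phi_segments$rdr_mean[seg_ok]
    phi <- sum(phi_segments$n_unmasked[seg_ok] * (sx - round(sx))^2)
    wbic <- phi * log(m_unmasked) * nrow(omega) - 2 * sl$loglik
    trace <- rbind(trace, data.frame(candidate = p, phi = phi,
                                     loglik = sl$loglik, wbic = wbic))
    if (is.null(best)) {
      best <- list(ploidy = p, wgd = ci - 1L, states = sl$states,
                   loglik = sl$loglik, wbic = wbic)
      next
    }
    redundant <- states_are_multiple(best$states, sl$states, best$ploidy, p)
    gain <- sl$loglik - best$loglik
    if (!redundant && gain > log(m_unmasked) * nrow(omega) / 2) {
      best <- list(ploidy = p, wgd = ci - 1L, states = sl$states,
                   loglik = sl$loglik, wbic = wbic)
    }
  }
  best$bic_trace <- trace
  best
}

# TRUE when the state map at the larger ploidy is the state map at the
# smaller ploidy with every allele multiplied by the (integer) ploidy
# ratio — i.e. the same profile re-expressed at another scale
states_are_multiple <- function(small, big, p_small, p_big) {
  r <- p_big / p_small
  if (abs(r - round(r)) > 0.01 || round(r) < 2) return(FALSE)
  r <- round(r)
  if (nrow(small) != nrow(big)) return(FALSE)
  small <- small[order(small$component), ]
  big <- big[order(big$component), ]
  all(small$component == big$component) &&
    all(big$c_minor == r * small$c_minor) &&
    all(big$c_major == r * small$c_major)
}

#' Call ploidy and allele-specific copy numbers for all cells
#'
#' Runs segment-to-component assignment, per-cell candidate-ploidy
#' enumeration, and weighted-BIC ploidy selection, then materializes per-bin
#' allele-specific states (each bin inherits its segment's component's
#' state). The candidate-ploidy anchor is chosen per cell: among balanced
#' components (|mBAF - 0.5| <= `balanced_tol`) the one holding most of the
#' cell's bins, with the anchor RDR taken as the mean RDR of that cell's
#' own bins in the component — cells from subclones with different ploidies
#' can share a merged component, and the cell-level mean keeps each cell's
#' candidate set centered on its own ploidy.
#'
#' @param features a `cellbin_features`.
#' @param model a (merged) `mixture_model`.
#' @param segments a `segment_sets`.
#' @param max_total state-space bound on total copy number (default 10).
#' @param max_wgd maximum whole-genome duplications (default 2).
#' @param balanced_tol tolerance on |mBAF - 0.5| (default 0.05).
#' @param known_ploidy optional numeric vector of externally measured
#'   ploidies (e.g. FACS); bypasses candidate enumeration, one value per
#'   cell (NA = estimate).
#' @param phi_segments optional `segment_sets` whose per-cell tables feed
#'   the scale statistic `phi` (the pipeline passes the CBS-only
#'   segmentation; see [select_ploidy()]).
#' @param consensus if `TRUE` (default), a final cross-cell pass revisits
#'   each cell whose selected scale is about double or half the median
#'   scale of its profile-correlated peers (RDR correlation at least
#'   `consensus_cor` with at least `consensus_peers` peers) and re-calls it
#'   at the peer scale. Cells of one clone carry near-identical profiles,
#'   so a within-clone minority at twice (or half) the majority scale is
#'   almost always a scale-selection artifact; this extends the cross-cell
#'   ensemble principle from breakpoints to ploidy.
#' @param consensus_cor,consensus_peers consensus parameters (0.8 and 3).
#' @return list of class `acn_calls`: `ploidy` (per cell: the genome-wide
#'   mean of the called total copy numbers, i.e. the ploidy the called
#'   profile implies — more stable than the raw scaling candidate, whose
#'   anchor carries the sampling noise of one component's mean),
#'   `scale_ploidy` (the winning candidate), `wgd`, `c_minor`/`c_major`
#'   (n x m integer matrices, NA at masked bins), `states` (per-cell
#'   component state maps), `assignment` (per-cell segment components),
#'   `bic_traces`, `segments`.
#' @export
call_cells <- function(features, model, segments, max_total = 10,
                       max_wgd = 2, balanced_tol = 0.05,
                       known_ploidy = NULL, phi_segments = NULL,
                       consensus = TRUE, consensus_cor = 0.8,
                       consensus_peers = 3) {
  omega <- state_space(max_total)
  asn <- assign_segments(segments, model)
  n <- nrow(features$rdr)
  m <- ncol(features$rdr)
  bt <- model$bin_table
  # positive-RDR guard: a zero-copy component has BAF 0.5 only for lack of
  # reads and must not anchor the ploidy scale
  balanced <- which(abs(model$means[, 2] - 0.5) <= balanced_tol &
                    model$means[, 1] > 0.1)

  ploidy <- numeric(n); scale_ploidy <- numeric(n); wgd <- integer(n)
  c_minor <- matrix(NA_integer_, n, m)
  c_major <- matrix(NA_integer_, n, m)
  states_list <- vector("list", n)
  traces <- vector("list", n)
  warned <- FALSE

  for (i in seq_len(n)) {
    rdr_i <- features$rdr[i, ]
    mbaf_i <- features$mbaf[i, ]
    segs <- segments$segments[[i]]
    a <- asn[[i]]

    if (!is.null(known_ploidy) && is.finite(known_ploidy[i])) {
      cands <- known_ploidy[i]
    } else {
      bins_in <- tabulate(model$assignments[i, ], nbins = model$K)
      pool <- balanced[bins_in[balanced] > 0]
      if (length(pool) == 0) {
        if (!warned) {
          warning("cell ", i, ": no balanced component; using most populated component")
          warned <- TRUE
        }
        pool <- which(bins_in > 0)
      }
      k <- pool[which.max(bins_in[pool])]
      own <- which(model$assignments[i, ] == k & !bt$masked)
      anchor <- mean(rdr_i[own])
      cands <- ploidies_from_balanced_rdr(anchor, max_wgd)
    }

    sel <- select_ploidy(cands, segs, a, model, omega, rdr_i, mbaf_i,
                         phi_segments = if (!is.null(phi_segments))
                           phi_segments$segments[[i]] else NULL)
    scale_ploidy[i] <- sel$ploidy
    wgd[i] <- sel$wgd
    states_list[[i]] <- sel$states
    traces[[i]] <- sel$bic_trace

    smap_min <- smap_maj <- rep(NA_integer_, model$K)
    smap_min[sel$states$component] <- sel$states$c_minor
    smap_maj[sel$states$component] <- sel$states$c_major
    exp_mean <- expected_state_mean(omega$c_minor, omega$c_major, sel$ploidy)
    sig <- noise_floor(model)
    S <- diag(sig^2)
    mbaf_exp <- folded_mbaf_mean(exp_mean$mbaf, sig[2] / sqrt(1 - 2 / pi))
    for (z in seq_len(nrow(segs))) {
      if (is.na(a[z])) next
      cols <- segs$start_bin[z]:segs$end_bin[z]
      cols <- cols[!bt$masked[cols]]
      if (segs$n_unmasked[z] >= 5) {
        # long segments carry enough evidence to pick their own state,
        # correcting components that pool neighbouring states
        x <- rdr_i[cols]; y <- mbaf_i[cols]
        ok2 <- is.finite(x) & is.finite(y)
        ll <- vapply(seq_len(nrow(omega)), function(st) {
          sum(ldbvn_r(x[ok2], y[ok2], exp_mean$rdr[st], mbaf_exp[st], S))
        }, numeric(1))
        bst <- which.max(ll)
        c_minor[i, cols] <- omega$c_minor[bst]
        c_major[i, cols] <- omega$c_major[bst]
      } else {
        c_minor[i, cols] <- smap_min[a[z]]
        c_major[i, cols] <- smap_maj[a[z]]
      }
    }
    tot_i <- c_minor[i, ] + c_major[i, ]
    ploidy[i] <- mean(tot_i[is.finite(tot_i)])
  }

  if (consensus && is.null(known_ploidy) && n >= consensus_peers + 1) {
    cc <- suppressWarnings(cor(t(features$rdr), use = "pairwise.complete.obs"))
    diag(cc) <- NA
    for (i in seq_len(n)) {
      peers <- which(cc[i, ] >= consensus_cor)
      if (length(peers) < consensus_peers) next
      pm <- median(scale_ploidy[peers])
      ratio <- scale_ploidy[i] / pm
      target <- if (ratio > 1.75 && ratio < 2.3) scale_ploidy[i] / 2
        else if (ratio > 1 / 2.3 && ratio < 1 / 1.75) scale_ploidy[i] * 2
        else next
      redo <- recall_cell(i, target, features, model, segments, omega,
                          c_minor, c_major)
      scale_ploidy[i] <- target
      wgd[i] <- NA_integer_
      c_minor[i, ] <- redo$c_minor
      c_major[i, ] <- redo$c_major
      states_list[[i]] <- redo$states
      tot_i <- redo$c_minor + redo$c_major
      ploidy[i] <- mean(tot_i[is.finite(tot_i)])
    }
  }

  structure(list(ploidy = ploidy, scale_ploidy = scale_ploidy,
                 wgd = wgd, c_minor = c_minor,
                 c_major = c_major, states = states_list,
                 assignment = asn, bic_traces = traces,
                 segments = segments),
            class = "acn_calls")
}

#' @export
print.acn_calls <- function(x, ...) {
  cat(sprintf("acn_calls: %d cells; ploidy range %.2f-%.2f\n",
              length(x$ploidy), min(x$ploidy), max(x$ploidy)))
  invisible(x)
}


# re-materialize one cell's states at a fixed scale (consensus pass)
recall_cell <- function(i, p, features, model, segments, omega,
                        c_minor, c_major) {
  segs <- segments$segments[[i]]
  a <- assign_segments(segs, model)
  rdr_i <- features$rdr[i, ]
  mbaf_i <- features$mbaf[i, ]
  sl <- state_likelihood(p, segs, a, model, omega, rdr_i, mbaf_i)
  bt <- model$bin_table
  cm <- cj <- rep(NA_integer_, ncol(features$rdr))
  smap_min <- smap_maj <- rep(NA_integer_, model$K)
  smap_min[sl$states$component] <- sl$states$c_minor
  smap_maj[sl$states$component] <- sl$states$c_major
  exp_mean <- expected_state_mean(omega$c_minor, omega$c_major, p)
  sig <- noise_floor(model)
  S <- diag(sig^2)
  mbaf_exp <- folded_mbaf_mean(exp_mean$mbaf, sig[2] / sqrt(1 - 2 / pi))
  for (z in seq_len(nrow(segs))) {
    if (is.na(a[z])) next
    cols <- segs$start_bin[z]:segs$end_bin[z]
    cols <- cols[!bt$masked[cols]]
    if (segs$n_unmasked[z] >= 5) {
      x <- rdr_i[cols]; y <- mbaf_i[cols]
      ok2 <- is.finite(x) & is.finite(y)
      ll <- vapply(seq_len(nrow(omega)), function(st) {
        sum(ldbvn_r(x[ok2], y[ok2], exp_mean$rdr[st], mbaf_exp[st], S))
      }, numeric(1))
      bst <- which.max(ll)
      cm[cols] <- omega$c_minor[bst]
      cj[cols] <- omega$c_major[bst]
    } else {
      cm[cols] <- smap_min[a[z]]
      cj[cols] <- smap_maj[a[z]]
    }
  }
  list(c_minor = cm, c_major = cj, states = sl$states)
}
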