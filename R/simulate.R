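#' Simulate a clonal ground truth of allele-specific copy-number profiles
#'
#' Builds a random clone tree (each new clone branches off a uniformly
#' chosen existing clone), evolves an initially diploid \{1,1\} genome along
#' its branches with random CNA events, and assigns cells to clones. A
#' configurable fraction of cells are normal (diploid \{1,1\} everywhere,
#' ploidy 2). The founder branch first applies the ploidy mode: `"diploid"`
#' leaves the base genome, `"tetraploid"` doubles it (one WGD),
#' `"triploid"` adds one copy of one allele genome-wide, and `"hypodiploid"`
#' deletes one allele over two large regions. Each CNA event picks a
#' chromosome, a uniform segment of `event_bins` bins, one allele, a gain or
#' loss of 1-2 copies (single-copy with probability 0.7), clamped at 0
#' copies. The first event on every branch is forced single-copy, so each
#' clone genome contains an odd-total or imbalanced segment; this keeps the
#' whole-genome-duplication scale identifiable (an all-even-total genome is
#' mathematically indistinguishable from its halved version).
#'
#' True cell ploidy is the genome-wide mean total copy number; true
#' breakpoints are the adjacent-bin state changes of each cell's profile
#' (0-based left-bin indices).
#'
#' @param n_cells number of cells.
#' @param bins_per_chrom bins on each chromosome.
#' @param n_chroms number of chromosomes.
#' @param n_clones number of tumor clones.
#' @param cna_events_per_clone CNA events added on each clone's branch.
#' @param truncal_events extra CNA events on the founder branch (default
#'   `2 * cna_events_per_clone`): most copy-number burden in real tumors is
#'   truncal, and the resulting genome-wide aneuploidy is what separates
#'   tumor from normal count profiles.
#' @param ploidy_mode one of "diploid", "tetraploid", "triploid",
#'   "hypodiploid".
#' @param normal_fraction fraction of cells that are normal, in \[0, 1).
#' @param event_bins length-2 range of event sizes in bins.
#' @param bin_width bin width in bp for the generated `bin_table`.
#' @param seed integer seed.
#' @return list of class `sim_truth`: `bin_table`, `clone_parent`,
#'   `clone_minor`/`clone_major` (clone x bin), `cell_clone` (0 = normal),
#'   `ploidy`, `c_minor`/`c_major` (cell x bin), `breakpoints`
#'   (`breakpoint_sets`), `normal_cells`, `ploidy_mode`.
#' @export
simulate_truth <- function(n_cells, bins_per_chrom, n_chroms = 2,
                           n_clones = 4, cna_events_per_clone = 4,
                           truncal_events = 2 * cna_events_per_clone,
                           ploidy_mode = c("diploid", "tetraploid",
                                           "triploid", "hypodiploid"),
                           normal_fraction = 0.25,
                           event_bins = c(5, 25), bin_width = 1e6,
                           seed = 1) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(n_cells >= 1, bins_per_chrom >= 2, n_clones >= 1,
            normal_fraction >= 0, normal_fraction < 1)
  set.seed(seed)
  m <- bins_per_chrom * n_chroms
  chrom <- rep(paste0("chr", seq_len(n_chroms)), each = bins_per_chrom)
  start <- rep((seq_len(bins_per_chrom) - 1) * bin_width, n_chroms)
  bt <- bin_table(chrom, start, start + bin_width,
                  gc = rep(0.45, m), mappability = rep(1, m))

  # clone tree: parent 0 is the (normal) root
  parent <- integer(n_clones)
  if (n_clones > 1) {
    for (cl in 2:n_clones) parent[cl] <- sample.int(cl - 1, 1)
  }

  A <- matrix(1L, n_clones, m)  # allele A copies per clone
  B <- matrix(1L, n_clones, m)
  apply_events <- function(a, b, n_events) {
    for (ev in seq_len(n_events)) {
      ch <- sample.int(n_chroms, 1)
      len <- sample(event_bins[1]:event_bins[2], 1)
      len <- min(len, bins_per_chrom)
      s <- sample.int(bins_per_chrom - len + 1, 1)
      cols <- (ch - 1) * bins_per_chrom + s:(s + len - 1)
      allele <- sample(c("a", "b"), 1)
      mag <- if (ev == 1) 1L else sample(c(1L, 2L), 1, prob = c(0.7, 0.3))
      delta <- mag * sample(c(-1L, 1L), 1)
      if (allele == "a") a[cols] <- pmax(0L, a[cols] + delta)
      else b[cols] <- pmax(0L, b[cols] + delta)
    }
    list(a = a, b = b)
  }

  for (cl in seq_len(n_clones)) {
    if (parent[cl] == 0) {
      a <- rep(1L, m); b <- rep(1L, m)
      if (ploidy_mode == "tetraploid") { a <- a * 2L; b <- b * 2L }
      if (ploidy_mode == "triploid") a <- a + 1L
      if (ploidy_mode == "hypodiploid") {
        for (r in 1:2) {
          ch <- sample.int(n_chroms, 1)
          len <- max(2L, round(bins_per_chrom * 0.3))
          s <- sample.int(bins_per_chrom - len + 1, 1)
          cols <- (ch - 1) * bins_per_chrom + s:(s + len - 1)
          a[cols] <- 0L
        }
      }
    } else {
      a <- A[parent[cl], ]; b <- B[parent[cl], ]
    }
    n_ev <- cna_events_per_clone + if (parent[cl] == 0) truncal_events else 0L
    g <- apply_events(a, b, n_ev)
    A[cl, ] <- g$a; B[cl, ] <- g$b
  }

  n_normal <- round(normal_fraction * n_cells)
  cell_clone <- c(rep(0L, n_normal),
                  sample(rep_len(seq_len(n_clones), n_cells - n_normal)))

  c_minor <- matrix(1L, n_cells, m)
  c_major <- matrix(1L, n_cells, m)
  tumor <- which(cell_clone > 0)
  c_minor[tumor, ] <- pmin(A[cell_clone[tumor], , drop = FALSE],
                           B[cell_clone[tumor], , drop = FALSE])
  c_major[tumor, ] <- pmax(A[cell_clone[tumor], , drop = FALSE],
                           B[cell_clone[tumor], , drop = FALSE])
  total <- c_minor + c_major
  ploidy <- rowMeans(total)

  bps <- true_breakpoints(c_minor, c_major, bt)
  structure(list(bin_table = bt, clone_parent = parent,
                 clone_minor = pmin(A, B), clone_major = pmax(A, B),
                 cell_clone = cell_clone, ploidy = ploidy,
                 c_minor = c_minor, c_major = c_major,
                 breakpoints = bps, normal_cells = seq_len(n_normal),
                 ploidy_mode = ploidy_mode),
            class = "sim_truth")
}

#' True breakpoints of per-cell state profiles
#'
#' 0-based left-bin indices of adjacent same-chromosome bins whose unordered
#' allele-specific state differs.
#'
#' @param c_minor,c_major cell x bin integer state matrices.
#' @param bt a `bin_table`.
#' @return a `breakpoint_sets`.
#' @export
true_breakpoints <- function(c_minor, c_major, bt) {
  n <- nrow(c_minor)
  out <- replicate(n, integer(0), simplify = FALSE)
  for (ch in unique(bt$chrom)) {
    cols <- which(bt$chrom == ch)
    if (length(cols) < 2) next
    left <- cols[-length(cols)]; right <- cols[-1]
    D <- (c_minor[, left, drop = FALSE] != c_minor[, right, drop = FALSE]) |
         (c_major[, left, drop = FALSE] != c_major[, right, drop = FALSE])
    for (i in seq_len(n)) {
      hit <- which(D[i, ])
      if (length(hit)) out[[i]] <- c(out[[i]], left[hit] - 1L)
    }
  }
  structure(list(bps = lapply(out, function(b) sort(as.integer(b))),
                 n_bins = nrow(bt)),
            class = "breakpoint_sets")
}

#' Draw read-count and BAF matrices from a simulated truth
#'
#' Emulates direct matrix-level simulation: per bin, the expected read
#' count is `coverage_scale * total / 2` (so `coverage_scale` is the mean
#' reads per bin of a diploid cell). With `count_model = "poisson"` counts
#' are Poisson draws around that mean, optionally perturbed by a
#' multiplicative Gaussian jitter of sd `rdr_noise_sd` (floored at 0);
#' `count_model = "exact"` emits the rounded expectations themselves, the
#' idealized zero-noise regime used for exact-recovery testing. BAF is the
#' true allelic fraction of a uniformly chosen haplotype (so balanced and
#' mirrored states are indistinguishable, as in real data) plus truncated
#' Gaussian noise of sd `baf_noise_sd`, reflected into \[0, 1\]; bins with
#' total copy number 0 emit BAF 0.5 (no signal).
#'
#' @param truth a `sim_truth`.
#' @param coverage_scale mean reads per bin at total copy 2 (default 1000,
#'   roughly 0.1X short-read coverage on 1 Mb bins or 0.02X on 5 Mb bins;
#'   at this depth counting noise is small and `rdr_noise_sd` is the
#'   effective RDR noise level).
#' @param rdr_noise_sd multiplicative Gaussian jitter on expected counts.
#' @param baf_noise_sd Gaussian noise on BAF.
#' @param count_model `"poisson"` (default) or `"exact"`.
#' @param seed integer seed.
#' @return list: `R` (integer counts), `baf`, both cell x bin with cell ids.
#' @export
simulate_matrices <- function(truth, coverage_scale = 1000, rdr_noise_sd = 0,
                              baf_noise_sd = 0,
                              count_model = c("poisson", "exact"),
                              seed = 1) {
  count_model <- match.arg(count_model)
  stopifnot(rdr_noise_sd >= 0, baf_noise_sd >= 0, coverage_scale > 0)
  set.seed(seed)
  total <- truth$c_minor + truth$c_major
  n <- nrow(total); m <- ncol(total)
  mu <- coverage_scale * total / 2

  if (count_model == "exact") {
    R <- round(mu)
  } else {
    if (rdr_noise_sd > 0) {
      mu <- mu * pmax(0, 1 + matrix(rnorm(n * m, 0, rdr_noise_sd), n, m))
    }
    R <- matrix(rpois(n * m, as.numeric(mu)), n, m)
  }

  # BAF from a uniformly mirrored haplotype fraction
  pick <- matrix(runif(n * m) < 0.5, n, m)
  frac <- ifelse(total == 0, 0.5,
                 ifelse(pick, truth$c_minor / pmax(total, 1),
                        truth$c_major / pmax(total, 1)))
  if (baf_noise_sd > 0) {
    frac <- frac + matrix(rnorm(n * m, 0, baf_noise_sd), n, m)
    frac <- reflect01(frac)
  }
  cells <- sprintf("cell%03d", seq_len(n))
  dimnames(R) <- dimnames(frac) <- list(cells, bin_ids(truth$bin_table))
  list(R = R, baf = frac)
}

reflect01 <- function(x) {
  x <- abs(x)
  x <- ifelse(x > 1, 2 - x, x)
  pmin(pmax(x, 0), 1)  # after one reflection; sd << 1 so one pass suffices
}

#' Simulate a complete ground-truthed dataset
#'
#' Convenience wrapper: [simulate_truth()] then [simulate_matrices()], with
#' derived seeds.
#'
#' @param ... passed to [simulate_truth()].
#' @param coverage_scale,rdr_noise_sd,baf_noise_sd,count_model passed to
#'   [simulate_matrices()].
#' @param seed integer seed (truth uses `seed`, matrices `seed + 1`).
#' @return list: `truth`, `R`, `baf`, `bin_table`.
#' @export
simulate_dataset <- function(..., coverage_scale = 1000, rdr_noise_sd = 0,
                             baf_noise_sd = 0,
                             count_model = c("poisson", "exact"), seed = 1) {
  truth <- simulate_truth(..., seed = seed)
  mats <- simulate_matrices(truth, coverage_scale, rdr_noise_sd,
                            baf_noise_sd, count_model, seed = seed + 1L)
  list(truth = truth, R = mats$R, baf = mats$baf,
       bin_table = truth$bin_table)
}
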