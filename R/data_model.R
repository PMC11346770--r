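#' @useDynLib scacn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif sd cor lowess kmeans median
#' @importFrom utils head
NULL

#' Construct a genomic bin annotation table
#'
#' Bins are fixed-width genomic windows, the unit of counting and calling.
#' Coordinates are 0-based, half-open. Within a chromosome bins must be
#' sorted, non-overlapping, and equal-width except possibly the last.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer base-pair coordinates (0-based, half-open).
#' @param gc GC fraction per bin, in \[0, 1\].
#' @param mappability mappability fraction per bin, in \[0, 1\].
#' @param masked logical; bins excluded from all downstream computation.
#' @return A `data.frame` of class `bin_table`.
#' @export
bin_table <- function(chrom, start, end, gc, mappability,
                      masked = rep(FALSE, length(chrom))) {
  bt <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), gc = as.numeric(gc),
                   mappability = as.numeric(mappability),
                   masked = as.logical(masked),
                   stringsAsFactors = FALSE)
  validate_bin_table(bt)
  class(bt) <- c("bin_table", "data.frame")
  bt
}

validate_bin_table <- function(bt) {
  stopifnot(all(bt$end > bt$start))
  stopifnot(all(bt$gc >= 0 & bt$gc <= 1), all(bt$mappability >= 0 & bt$mappability <= 1))
  for (ch in unique(bt$chrom)) {
    b <- bt[bt$chrom == ch, ]
    if (nrow(b) > 1) {
      if (is.unsorted(b$start, strictly = TRUE))
        stop("bins on chromosome ", ch, " are not sorted")
      if (any(b$start[-1] < b$end[-nrow(b)]))
        stop("overlapping bins on chromosome ", ch)
    }
  }
  invisible(bt)
}

#' Bin identifiers of the form chrom:start-end
#' @param bt a `bin_table`.
#' @return character vector, one id per bin.
#' @export
bin_ids <- function(bt) sprintf("%s:%d-%d", bt$chrom, bt$start, bt$end)

#' Enumerate the allele-specific copy-number state space
#'
#' All unordered states \{c_minor, c_major\} with total copy number up to
#' `max_total`; the state space searched during calling (often written
#' Omega). The number of states is `sum(floor(T/2) + 1)` for
#' `T = 0..max_total`.
#'
#' @param max_total maximum total copy number (default 10).
#' @return data.frame with columns `c_minor`, `c_major`, `total`.
#' @export
state_space <- function(max_total = 10) {
  stopifnot(max_total >= 0)
  out <- do.call(rbind, lapply(0:max_total, function(tot) {
    cmin <- 0:(tot %/% 2)
    data.frame(c_minor = cmin, c_major = tot - cmin, total = tot)
  }))
  rownames(out) <- NULL
  out
}

#' Expected (RDR, mBAF) location of a copy-number state
#'
#' Bins in state \{c_minor, c_major\} in a cell of ploidy p are expected at
#' RDR = (c_minor + c_major) / p (RDR is normalized to a per-cell mean of 1,
#' so a total equal to the ploidy sits at 1) and mBAF = c_minor / total.
#' The total-0 state has no allelic-imbalance signal and is assigned
#' mBAF 0.5, which keeps nullisomic bins from attracting extreme-mBAF data.
#' Inputs are mirrored internally, so the order of the two alleles is
#' irrelevant.
#'
#' @param c_minor,c_major non-negative integer allele copy numbers
#'   (vectorized; mirrored so order does not matter).
#' @param ploidy positive cell ploidy.
#' @return list with numeric vectors `rdr` and `mbaf`.
#' @export
expected_state_mean <- function(c_minor, c_major, ploidy) {
  stopifnot(ploidy > 0, all(c_minor >= 0), all(c_major >= 0))
  lo <- pmin(c_minor, c_major)
  tot <- c_minor + c_major
  mbaf <- ifelse(tot == 0, 0.5, lo / pmax(tot, 1))
  list(rdr = tot / ploidy, mbaf = mbaf)
}

#' Compute normalized counts, RDR and mBAF feature matrices
#'
#' Applies per-bin normalization factors to the raw counts
#' (`X = R / lambda`), scales each cell by its mean normalized count over
#' unmasked bins to obtain the read-depth ratio (RDR), and mirrors the BAF
#' matrix into mBAF = min(BAF, 1 - BAF). Masked bins are set to `NA` in all
#' derived matrices and excluded from every mean.
#'
#' Zero-count bins inside an otherwise covered cell keep RDR 0, a legitimate
#' homozygous-deletion signal.
#'
#' @param R n x m non-negative integer raw read-count matrix (cells x bins).
#' @param baf n x m B-allele-frequency matrix in \[0, 1\].
#' @param bin_table a `bin_table` with m rows.
#' @param norm_factors per-bin normalization factors lambda (positive over
#'   unmasked bins); default all 1.
#' @return list of class `cellbin_features`: `R`, `X`, `X_bar`, `rdr`,
#'   `baf`, `mbaf`, `bin_table`.
#' @export
compute_features <- function(R, baf, bin_table, norm_factors = NULL) {
  R <- as.matrix(R); baf <- as.matrix(baf)
  m <- nrow(bin_table)
  stopifnot(ncol(R) == m, all(dim(R) == dim(baf)))
  if (any(R < 0, na.rm = TRUE)) stop("negative read counts")
  if (is.null(norm_factors)) norm_factors <- rep(1, m)
  unmasked <- !bin_table$masked
  if (any(norm_factors[unmasked] <= 0, na.rm = TRUE))
    stop("normalization factors must be positive over unmasked bins")

  X <- sweep(R, 2, norm_factors, "/")
  X[, !unmasked] <- NA_real_
  X_bar <- rowMeans(X, na.rm = TRUE)
  zero <- which(!is.finite(X_bar) | X_bar == 0)
  if (length(zero) > 0) {
    stop(errorCondition(
      paste0("cell(s) with zero total count: ", paste(zero, collapse = ", ")),
      class = c("scacn_zero_cell_error", "error"), cells = zero))
  }
  rdr <- X / X_bar
  baf2 <- baf
  baf2[, !unmasked] <- NA_real_
  mbaf <- pmin(baf2, 1 - baf2)

  structure(list(R = R, X = X, X_bar = X_bar, rdr = rdr, baf = baf2,
                 mbaf = mbaf, bin_table = bin_table),
            class = "cellbin_features")
}

#' @export
print.cellbin_features <- function(x, ...) {
  cat(sprintf("cellbin_features: %d cells x %d bins (%d masked)\n",
              nrow(x$R), ncol(x$R), sum(x$bin_table$masked)))
  invisible(x)
}
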