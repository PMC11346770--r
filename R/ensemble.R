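#' Cross-cell frequency of candidate breakpoints
#'
#' Counts, for every genome-wide breakpoint index, the number of cells whose
#' candidate set contains it (exact index matches; the tolerance used in
#' evaluation plays no role in filtering).
#'
#' @param candidates a `breakpoint_sets` (per-cell candidate breakpoints).
#' @return named integer vector: names are breakpoint indices, values are
#'   cell counts.
#' @export
breakpoint_frequency <- function(candidates) {
  all_bps <- unlist(candidates$bps, use.names = FALSE)
  if (length(all_bps) == 0) return(integer(0))
  tab <- table(all_bps)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Ensemble filtering of candidate breakpoints
#'
#' A cell's final breakpoints are the candidate mixture-model breakpoints
#' shared by at least `t` cells, plus (regardless of global frequency) any
#' candidate also found by that cell's local CBS segmentation. The final set
#' is therefore always a subset of the candidates; `t = 1` disables the
#' frequency filter entirely.
#'
#' @param candidates per-cell candidate breakpoints (`breakpoint_sets`).
#' @param cbs per-cell CBS breakpoints (`breakpoint_sets`).
#' @param t minimum number of cells sharing a breakpoint (default 5).
#' @return a `breakpoint_sets` of final per-cell breakpoints.
#' @export
ensemble_breakpoints <- function(candidates, cbs, t = 5) {
  stopifnot(t >= 1, length(candidates$bps) == length(cbs$bps))
  freq <- breakpoint_frequency(candidates)
  final <- mapply(function(cand, loc) {
    keep <- cand[freq[as.character(cand)] >= t]
    sort(unique(c(keep, intersect(cand, loc))))
  }, candidates$bps, cbs$bps, SIMPLIFY = FALSE)
  structure(list(bps = final, n_bins = candidates$n_bins),
            class = "breakpoint_sets")
}

#' Build per-cell segments from final breakpoints
#'
#' Segments tile each chromosome's bins between consecutive breakpoints and
#' chromosome ends; per-segment RDR and mBAF are means over the segment's
#' unmasked bins. Bin indices in the output are 1-based genome-wide column
#' indices (`start_bin`..`end_bin`, inclusive).
#'
#' @param final a `breakpoint_sets` of per-cell final breakpoints.
#' @param features a `cellbin_features`.
#' @return list of class `segment_sets`: one data.frame per cell with
#'   columns chrom, start_bin, end_bin, n_unmasked, rdr_mean, mbaf_mean.
#' @export
build_segments <- function(final, features) {
  bt <- features$bin_table
  n <- nrow(features$rdr)
  chrom_rle <- rle(bt$chrom)
  chrom_start <- cumsum(c(1L, head(chrom_rle$lengths, -1L)))
  chrom_end <- cumsum(chrom_rle$lengths)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    bps <- final$bps[[i]]
    segs <- list()
    for (ch in seq_along(chrom_rle$values)) {
      s <- chrom_start[ch]; e <- chrom_end[ch]
      # breakpoints are 0-based left-bin indices: cut after column b+1
      cuts <- bps[bps >= s - 1L & bps < e - 1L] + 1L
      starts <- c(s, cuts + 1L)
      ends <- c(cuts, e)
      for (z in seq_along(starts)) {
        cols <- starts[z]:ends[z]
        um <- cols[!bt$masked[cols]]
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = chrom_rle$values[ch], start_bin = starts[z],
          end_bin = ends[z], n_unmasked = length(um),
          rdr_mean = if (length(um)) mean(features$rdr[i, um]) else NA_real_,
          mbaf_mean = if (length(um)) mean(features$mbaf[i, um]) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, segs)
  }
  structure(list(segments = out, bin_table = bt), class = "segment_sets")
}
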