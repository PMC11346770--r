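#' Read / write cell-by-bin matrices and bin tables
#'
#' Matrices travel as TSV with the cell identifier in the first column
#' (`cell`) and one column per bin, named `chrom:start-end`. Bin tables are
#' BED-like TSV with a header: chrom, start, end, gc, mappability (and
#' optionally masked). Coordinates are 0-based half-open, as in BED.
#'
#' @param x numeric matrix (cells x bins) with rownames as cell ids.
#' @param bt a `bin_table` describing the columns of `x`.
#' @param path file path.
#' @return `read_cellbin_matrix` returns a numeric matrix with cell ids as
#'   rownames; writers return the path invisibly.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_cellbin_matrix <- function(x, bt, path) {
  stopifnot(ncol(x) == nrow(bt))
  dt <- data.table::data.table(cell = rownames(x) %||% paste0("cell", seq_len(nrow(x))))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::setnames(dt, c("cell", bin_ids(bt)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_cellbin_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  cells <- as.character(dt[[1]])
  x <- as.matrix(dt[, -1, with = FALSE])
  rownames(x) <- cells
  x
}

#' @rdname matrix_io
#' @export
write_bin_table <- function(bt, path) {
  data.table::fwrite(as.data.frame(bt), path, sep = "\t")
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_bin_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  bin_table(dt$chrom, dt$start, dt$end, dt$gc, dt$mappability,
            masked = if ("masked" %in% names(dt)) dt$masked else FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
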