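# Reading and writing expression matrices. Internal orientation is always
# cells-by-genes (N x D); files laid out genes-by-cells are transposed on
# read. Values are log read counts; exact zeros mark candidate dropouts and
# must survive every round trip bit-exactly.

validate_expression <- function(y, strict = TRUE) {
  check_matrix(y)
  if (strict && any(y < 0))
    stop("expression matrix contains negative entries; values must be log read counts >= 0")
  if (nrow(y) < 2) stop("need at least 2 cells")
  if (ncol(y) < 1) stop("need at least 1 gene")
  if (!is.null(rownames(y)) && anyDuplicated(rownames(y)))
    stop("duplicate cell ids")
  if (!is.null(colnames(y)) && anyDuplicated(colnames(y)))
    stop("duplicate gene ids")
  invisible(y)
}

#' Read an expression matrix
#'
#' Reads a labeled CSV/TSV matrix or a MatrixMarket coordinate file (with
#' companion one-column row and column label files) and returns a plain
#' numeric matrix in cells-by-genes orientation. Zeros are preserved
#' exactly; absent entries of a sparse MTX file materialize as 0.
#'
#' @param path file to read. For `format = "mtx"`, labels default to
#'   `<path>.rows` and `<path>.cols` (one label per line).
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param orientation layout of the *source* file: `"cells_by_genes"`
#'   (rows are cells) or `"genes_by_cells"` (rows are genes; transposed on
#'   read).
#' @param transform `"none"` (default: input is already log scale) or
#'   `"log1p"` to apply `log(1 + value)`. Never applied silently.
#' @param row_labels,col_labels label files for MTX input (rows/columns of
#'   the file as stored, before any orientation transpose).
#' @param strict reject negative entries (the log-read-count contract).
#'   Set to `FALSE` for matrices on an unconstrained log scale, e.g.
#'   simulated data or latent coordinates.
#' @return numeric matrix, cells in rows, genes in columns, with dimnames.
#' @export
read_expression <- function(path,
                            format = c("csv", "tsv", "mtx"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            transform = c("none", "log1p"),
                            row_labels = NULL, col_labels = NULL,
                            strict = TRUE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.table(path, sep = sep, header = TRUE, row.names = 1,
                 check.names = FALSE, colClasses = "character"),
      error = function(e) stop(sprintf("failed to parse %s: %s", path,
                                       conditionMessage(e))))
    m <- as.matrix(df)
    suppressWarnings(storage.mode(m) <- "double")
    bad <- which(is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric entry at data line %d of %s", bad[1, 1], path))
  } else {
    if (is.null(row_labels)) row_labels <- paste0(path, ".rows")
    if (is.null(col_labels)) col_labels <- paste0(path, ".cols")
    sm <- Matrix::readMM(path)
    m <- as.matrix(sm)
    rn <- readLines(row_labels)
    cn <- readLines(col_labels)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MTX label files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  }
  if (orientation == "genes_by_cells") m <- t(m)
  if (transform == "log1p") m <- log1p(m)
  validate_expression(m, strict = strict)
  m
}

#' Write an expression matrix
#'
#' Writes a cells-by-genes matrix as labeled CSV/TSV with full double
#' precision, so that `read_expression()` recovers it bit-exactly.
#'
#' @param y cells-by-genes numeric matrix with dimnames.
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @param orientation layout to write (`"genes_by_cells"` transposes).
#' @return `path`, invisibly.
#' @export
write_expression <- function(y, path, format = c("csv", "tsv"),
                             orientation = c("cells_by_genes", "genes_by_cells")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  check_matrix(y)
  if (is.null(rownames(y))) rownames(y) <- paste0("cell", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- paste0("gene", seq_len(ncol(y)))
  m <- if (orientation == "genes_by_cells") t(y) else y
  sep <- if (format == "csv") "," else "\t"
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  lines <- c(paste(c("", colnames(chr)), collapse = sep),
             vapply(seq_len(nrow(chr)),
                    function(i) paste(c(rownames(chr)[i], chr[i, ]), collapse = sep),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Filter genes by zero fraction
#'
#' Drops genes whose fraction of exact-zero entries exceeds
#' `max_zero_fraction` (e.g. 0.95 removes genes that are zero in more than
#' 95% of cells). Order of retained genes is preserved; the removed gene
#' ids are attached as attribute `"removed_genes"`.
#'
#' @param y cells-by-genes matrix.
#' @param max_zero_fraction retain genes with zero fraction `<=` this value;
#'   in `(0, 1]`.
#' @return the filtered matrix, with attribute `"removed_genes"`.
#' @export
filter_genes <- function(y, max_zero_fraction = 0.95) {
  check_matrix(y)
  if (max_zero_fraction <= 0 || max_zero_fraction > 1)
    stop("`max_zero_fraction` must be in (0, 1]")
  zf <- colMeans(y == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep))
    stop("all genes exceed the zero-fraction threshold; relax `max_zero_fraction`")
  removed <- if (is.null(colnames(y))) which(!keep) else colnames(y)[!keep]
  out <- y[, keep, drop = FALSE]
  attr(out, "removed_genes") <- removed
  out
}
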