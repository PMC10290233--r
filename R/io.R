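#' Read a 10x-style Matrix Market count directory
#'
#' Loads a sparse count matrix stored in the 10x Genomics convention: a Matrix
#' Market triplet file (`matrix.mtx`) with companion `features.tsv` (or
#' `genes.tsv`) and `barcodes.tsv` files, any of which may be gzipped. On disk
#' the matrix is genes x cells; it is transposed on load so that cells are
#' rows and genes are columns, the orientation used throughout the package.
#'
#' @param dir_path Directory containing `matrix.mtx[.gz]`,
#'   `features.tsv[.gz]`/`genes.tsv[.gz]` and `barcodes.tsv[.gz]`.
#' @return A sparse `dgCMatrix` of non-negative integer counts, cells x genes,
#'   with cell barcodes as row names and gene symbols as column names.
#' @details The features file may have one column (symbol), two columns
#'   (id, symbol) or three columns (id, symbol, type); the symbol column is
#'   used. Duplicate gene symbols (case-insensitive) are an error: the
#'   correct aggregation is dataset-specific and silently guessing one would
#'   corrupt downstream per-gene thresholding.
#' @seealso [read_counts_csv()], [write_matrix()]
#' @export
read_mtx <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("directory not found: ", dir_path)
  mtx  <- .find_file(dir_path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- .find_file(dir_path, c("features.tsv", "features.tsv.gz",
                                 "genes.tsv", "genes.tsv.gz"))
  bc   <- .find_file(dir_path, c("barcodes.tsv", "barcodes.tsv.gz"))

  m <- .read_mm(mtx)
  features <- .read_tsv_col(feat)
  barcodes <- .read_tsv_col(bc, column = 1L)
  if (nrow(m) != length(features))
    stop("dimension mismatch: matrix has ", nrow(m), " features but ",
         length(features), " feature names")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: matrix has ", ncol(m), " cells but ",
         length(barcodes), " barcodes")

  counts <- Matrix::t(m)          # on-disk genes x cells -> cells x genes
  dimnames(counts) <- list(barcodes, features)
  validate_counts(counts)
}

#' Read a dense CSV count matrix
#'
#' Expects a header row of gene symbols and one row per cell, the first
#' column holding cell barcodes. Gzipped files are read transparently.
#'
#' @param path Path to the CSV file.
#' @return A sparse `dgCMatrix` of counts, cells x genes.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- .read_csv(path)
  if (ncol(dt) < 2L) stop("no gene columns found in ", path)
  barcodes <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cell values in ", path)
  rownames(vals) <- barcodes
  counts <- methods::as(methods::as(Matrix::Matrix(vals, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  validate_counts(counts)
}

#' Write a cells x genes matrix to disk
#'
#' @param x A cells x genes matrix (dense or sparse) with dimnames, or a
#'   fitted [speck] object (its abundance matrix is written).
#' @param path Output path: a directory for `format = "mtx"` (created if
#'   needed; `matrix.mtx`, `features.tsv` and `barcodes.tsv` are written
#'   inside), a file path for `format = "csv"`.
#' @param format `"mtx"` (Matrix Market triplet, genes x cells on disk per
#'   the 10x convention, zeros not materialized) or `"csv"` (dense, header =
#'   gene symbols, first column = barcodes).
#' @return Invisibly, the path written.
#' @export
write_matrix <- function(x, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "speck")) x <- fitted(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry cell barcodes (rownames) and gene symbols (colnames)")
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sp <- methods::as(methods::as(Matrix::Matrix(Matrix::t(x), sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    data.table::fwrite(data.table::data.table(id = colnames(x),
                                              symbol = colnames(x)),
                       file.path(path, "features.tsv"),
                       sep = "\t", col.names = FALSE)
    data.table::fwrite(data.table::data.table(rownames(x)),
                       file.path(path, "barcodes.tsv"),
                       sep = "\t", col.names = FALSE)
  } else {
    dt <- data.table::data.table(barcode = rownames(x))
    dt <- cbind(dt, data.table::as.data.table(as.matrix(x)))
    data.table::fwrite(dt, path)
  }
  invisible(path)
}

#' Read a dense CSV expression/abundance matrix (real-valued)
#'
#' Same layout as [read_counts_csv()] but without the integrality check;
#' used to reload reconstructed or thresholded matrices.
#'
#' @param path Path to the CSV file.
#' @return A dense numeric matrix, cells x genes.
#' @export
read_values_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- .read_csv(path)
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(vals) <- as.character(dt[[1L]])
  vals
}

#' Validate a cells x genes count matrix
#'
#' Checks the invariants every entry point relies on: non-negative integral
#' entries, at least two cells and two genes (the PC standard deviation uses
#' an m - 1 denominator), and gene symbols unique after case folding.
#'
#' @param counts Matrix to validate.
#' @return The validated matrix, invisibly coerced to `dgCMatrix` if sparse
#'   input was given; dense input stays dense.
#' @export
validate_counts <- function(counts) {
  if (nrow(counts) == 0L) stop("no cells")
  if (ncol(counts) == 0L) stop("no genes")
  if (nrow(counts) < 2L) stop("at least 2 cells required, got ", nrow(counts))
  if (ncol(counts) < 2L) stop("at least 2 genes required, got ", ncol(counts))
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(vals < 0)) stop("negative count found; counts must be non-negative")
  if (any(vals != floor(vals))) stop("non-integer count found")
  gs <- colnames(counts)
  if (!is.null(gs)) {
    dup <- duplicated(toupper(gs))
    if (any(dup))
      stop("duplicate gene symbols (case-insensitive): ",
           paste(unique(gs[dup]), collapse = ", "))
  }
  counts
}

.find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing file: none of ", paste(candidates, collapse = ", "),
       " found in ", dir)
}

.read_mm <- function(path) {
  # readMM closes a connection it is handed, so no on.exit here
  m <- if (grepl("\\.gz$", path)) Matrix::readMM(gzfile(path))
       else Matrix::readMM(path)
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}

# fread needs an optional helper package for gz, so gzipped files go
# through a base-R connection instead
.read_csv <- function(path) {
  if (grepl("\\.gz$", path)) {
    utils::read.csv(gzfile(path), header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  } else {
    data.table::fread(path, header = TRUE, data.table = FALSE,
                      check.names = FALSE)
  }
}

# Features TSV: 1 col = symbol, 2-3 cols = (id, symbol[, type]).
.read_tsv_col <- function(path, column = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) == 0L) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (is.null(column)) column <- if (length(parts[[1L]]) >= 2L) 2L else 1L
  vapply(parts, `[[`, character(1), column)
}
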