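#' Read a gene-by-cell expression matrix from disk
#'
#' Two on-disk layouts are supported. `mtx_triplet` is the
#' CellRanger-style layout: a directory (or path to `matrix.mtx`)
#' containing `matrix.mtx`, `features.tsv` and `barcodes.tsv`, with genes
#' in Matrix-Market rows and cells in columns. `dense_delim` is a
#' tab-delimited table with gene rows, a first column of gene ids and a
#' header of cell ids.
#'
#' Orientation is normalised to gene-by-cell. For triplets it is
#' auto-detected from the id-file lengths (a transposed matrix whose
#' dimensions match the swapped id counts is silently transposed);
#' `orientation = "genes_by_cells"` disables the auto-detection.
#'
#' @param path Directory or file path (see Details).
#' @param format `"mtx_triplet"` or `"dense_delim"`.
#' @param layer `"counts"` (validated as non-negative integers) or
#'   `"lognorm"`.
#' @param orientation `"auto"` or `"genes_by_cells"`.
#' @return An [ExpressionMatrix].
#' @export
read_expression <- function(path, format = c("mtx_triplet", "dense_delim"),
                            layer = c("counts", "lognorm"),
                            orientation = c("auto", "genes_by_cells")) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  orientation <- match.arg(orientation)
  if (format == "mtx_triplet") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- file.path(dir, "matrix.mtx")
    feats <- file.path(dir, "features.tsv")
    bars <- file.path(dir, "barcodes.tsv")
    for (f in c(mtx, feats, bars))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    m <- as.matrix(Matrix::readMM(mtx))
    features <- utils::read.delim(feats, header = FALSE,
                                  colClasses = "character")[[1L]]
    barcodes <- utils::read.delim(bars, header = FALSE,
                                  colClasses = "character")[[1L]]
    if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
      # genes x cells, as written
    } else if (orientation == "auto" &&
               nrow(m) == length(barcodes) && ncol(m) == length(features)) {
      m <- t(m)
    } else {
      stop(sprintf(paste0("matrix is %d x %d but there are %d features and ",
                          "%d barcodes"),
                   nrow(m), ncol(m), length(features), length(barcodes)),
           call. = FALSE)
    }
    ExpressionMatrix(m, gene_ids = features, cell_ids = barcodes,
                     layer = layer)
  } else {
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = NA)
    if (ncol(tab) < 2L)
      stop("dense matrix needs a gene-id column and at least one cell",
           call. = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
    ExpressionMatrix(m, gene_ids = genes, cell_ids = colnames(tab)[-1L],
                     layer = layer)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: `mtx_triplet` writes
#' `matrix.mtx`/`features.tsv`/`barcodes.tsv` into a directory,
#' `dense_delim` writes one tab-delimited table.
#'
#' @param x An [ExpressionMatrix].
#' @param path Output directory (`mtx_triplet`) or file (`dense_delim`).
#' @param format Output layout.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             format = c("mtx_triplet", "dense_delim")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(gene_ids(x), file.path(path, "features.tsv"))
    writeLines(cell_ids(x), file.path(path, "barcodes.tsv"))
  } else {
    tab <- cbind(gene_id = gene_ids(x),
                 as.data.frame(apply(x$values, 2L, fmt_num),
                               check.names = FALSE))
    colnames(tab) <- c("gene_id", cell_ids(x))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-cell pseudotime table
#'
#' Expects tab-delimited text with a header and two columns: `cell_id`
#' and `pseudotime`.
#'
#' @param path File path.
#' @return Named numeric vector of pseudotime keyed by cell id.
#' @export
read_pseudotime <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE,
                           colClasses = c("character", "character"))
  if (ncol(tab) != 2L)
    stop("pseudotime table must have exactly two columns", call. = FALSE)
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate cell ids in pseudotime table: ",
         paste(utils::head(tab[[1L]][duplicated(tab[[1L]])], 5),
               collapse = ", "), call. = FALSE)
  t <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(t) || any(!is.finite(t)))
    stop("non-numeric or non-finite pseudotime for cells: ",
         paste(utils::head(tab[[1L]][!is.finite(t) | is.na(t)], 5),
               collapse = ", "), call. = FALSE)
  stats::setNames(t, tab[[1L]])
}

#' @rdname read_pseudotime
#' @param t Named numeric vector of pseudotime.
#' @export
write_pseudotime <- function(t, path) {
  stopifnot(is.numeric(t), !is.null(names(t)))
  utils::write.table(data.frame(cell_id = names(t),
                                pseudotime = fmt_num(t)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a kernel profile as TSV
#'
#' The layout mirrors how the kernel is used: the header row carries the
#' stage-grid pseudotimes (first field `gene_id`), and each subsequent
#' row is one dynamic gene's smoothed expression across the stages.
#'
#' @param path File path.
#' @return A `KernelProfile`.
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  grid <- suppressWarnings(as.numeric(colnames(tab)[-1L]))
  if (anyNA(grid))
    stop("kernel header must contain numeric stage pseudotimes",
         call. = FALSE)
  R <- as.matrix(tab[, -1L, drop = FALSE])
  new_kernel_profile(genes = as.character(tab[[1L]]), stage_grid = grid,
                     R = R)
}

#' @rdname read_kernel
#' @param kernel A `KernelProfile` (see [build_kernel()]).
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "KernelProfile"))
  tab <- cbind(gene_id = kernel$genes,
               as.data.frame(apply(kernel$R, 2L, fmt_num),
                             check.names = FALSE))
  colnames(tab) <- c("gene_id", fmt_num(kernel$stage_grid))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write stage-transfer results as TSV
#'
#' Columns: `cell_id`, `stage_index`, `pseudotime`, `similarity`,
#' `passed_cutoff`.
#'
#' @param path File path.
#' @return A data frame of per-cell transfer results.
#' @export
read_transfer <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE)
  need <- c("cell_id", "stage_index", "pseudotime", "similarity",
            "passed_cutoff")
  if (!all(need %in% colnames(tab)))
    stop("transfer table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tab$cell_id <- as.character(tab$cell_id)
  tab$passed_cutoff <- as.logical(tab$passed_cutoff)
  tab
}

#' @rdname read_transfer
#' @param res Transfer result data frame (see [transfer_labels()]).
#' @export
write_transfer <- function(res, path) {
  out <- res
  out$pseudotime <- fmt_num(out$pseudotime)
  out$similarity <- fmt_num(out$similarity)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
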