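#' Gene-by-cell expression matrix
#'
#' Lightweight container for a dense gene-by-cell expression matrix with
#' validated identifiers. The `layer` records whether the values are raw
#' counts (non-negative integers) or log-normalized expression
#' (non-negative reals, natural log of 1 + counts-per-10k by default).
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param cell_ids Character vector of unique cell identifiers
#'   (default: `colnames(values)`).
#' @param layer Either `"counts"` or `"lognorm"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (matrix with dimnames set), and `layer`.
#' @export
#'
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' ExpressionMatrix(m, layer = "counts")
ExpressionMatrix <- function(values, gene_ids = rownames(values),
                             cell_ids = colnames(values),
                             layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop(sprintf("%d gene ids but %d matrix rows",
                 length(gene_ids), nrow(values)), call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop(sprintf("%d cell ids but %d matrix columns",
                 length(cell_ids), ncol(values)), call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 5), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (layer == "counts") {
    if (any(values < 0))
      stop("counts must be non-negative", call. = FALSE)
    if (any(values != floor(values)))
      stop("counts layer contains non-integer entries", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (layer: %s)\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @rdname ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname ExpressionMatrix
#' @export
cell_ids <- function(x) colnames(x$values)

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or cell identifiers or indices
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,cells Character ids or integer/logical indices; `NULL`
#'   keeps everything.
#' @return An `ExpressionMatrix` restricted (and reordered) accordingly.
#' @export
subset_expression <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    if (is.character(genes)) {
      miss <- setdiff(genes, rownames(v))
      if (length(miss))
        stop("genes not present: ",
             paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    if (is.character(cells)) {
      miss <- setdiff(cells, colnames(v))
      if (length(miss))
        stop("cells not present: ",
             paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    v <- v[, cells, drop = FALSE]
  }
  ExpressionMatrix(v, layer = x$layer)
}

# Align a per-cell vector (possibly named) with the cells of an
# ExpressionMatrix; errors on id mismatch.
align_cells <- function(t, expr, what = "pseudotime") {
  cells <- cell_ids(expr)
  if (!is.null(names(t))) {
    if (!setequal(names(t), cells))
      stop(sprintf("%s cell ids do not match the expression matrix", what),
           call. = FALSE)
    t <- t[cells]
  } else if (length(t) != length(cells)) {
    stop(sprintf("unnamed %s vector must have one value per cell", what),
         call. = FALSE)
  }
  if (anyNA(t) || any(!is.finite(t)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  unname(t)
}
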