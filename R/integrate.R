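#' Assign cells to equal-width pseudotime partitions
#'
#' Partitions are half-open bins of `[0, 1]`:
#' `[(p-1)/P, p/P)` for `p < P` and `[(P-1)/P, 1]` for the last, so
#' `t = 0` maps to partition 1 and `t = 1` to partition `P`.
#'
#' @param pseudotime Numeric vector in `[0, 1]`.
#' @param P Number of partitions (>= 1, default 100).
#' @return Integer partition indices in `[1, P]`.
#' @export
#'
#' @examples
#' assign_partitions(c(0, 0.555, 1), P = 100)
assign_partitions <- function(pseudotime, P = 100L) {
  P <- as.integer(P)
  if (P < 1L) stop("P must be >= 1", call. = FALSE)
  if (anyNA(pseudotime) || any(!is.finite(pseudotime)))
    stop("pseudotime contains non-finite values", call. = FALSE)
  if (any(pseudotime < 0 | pseudotime > 1))
    stop("pseudotime outside [0, 1]", call. = FALSE)
  pmin(P, as.integer(floor(pseudotime * P)) + 1L)
}

#' Integrate batches by time-series partitions
#'
#' Cells from all batches are pooled and binned into `P` equal-width
#' pseudotime partitions; per-gene averages are formed per partition.
#' Two outputs are produced:
#'
#' * `partition_trend` — a gene-by-P matrix of pooled per-partition
#'   means, z-scored gene-wise across the non-empty partitions (empty
#'   partitions are carried as `NA` and excluded from the scaling).
#' * `corrected` — a per-cell matrix where each value is re-centered as
#'   `expression - batch-specific partition mean + pooled partition
#'   mean`, so that within any partition the batch means coincide
#'   exactly; for a single batch this is the identity.
#'
#' Pseudotime itself is never altered, so the cell ordering along the
#' trajectory is preserved; only expression is harmonised.
#'
#' @param datasets List of datasets, each a list with elements `expr`
#'   (an [ExpressionMatrix], `lognorm` layer), `batch` (single label)
#'   and `pseudotime` (per-cell values in `[0, 1]`, named by cell id or
#'   aligned with the matrix columns; the reference uses its own
#'   normalized pseudotime, queries use transferred pseudotime).
#' @param genes Character vector of genes shared by all datasets
#'   (typically the kernel genes).
#' @param P Number of partitions (default 100).
#' @return A list of class `PartitionedDataset`: `cell_ids`, `batch`,
#'   `pseudotime`, `partition_index`, `partition_trend` (gene x P, `NA`
#'   columns for empty partitions), `corrected` (gene x cell),
#'   `empty_partitions` (integer indices).
#' @export
integrate_by_partition <- function(datasets, genes, P = 100L) {
  P <- as.integer(P)
  if (P < 1L) stop("P must be >= 1", call. = FALSE)
  if (!length(datasets)) stop("no datasets supplied", call. = FALSE)
  genes <- as.character(genes)

  mats <- vector("list", length(datasets))
  batch <- character(0)
  pt <- numeric(0)
  cells <- character(0)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    stopifnot(inherits(d$expr, "ExpressionMatrix"))
    if (d$expr$layer != "lognorm")
      stop("integration expects log-normalized expression", call. = FALSE)
    missing <- setdiff(genes, gene_ids(d$expr))
    if (length(missing))
      stop("dataset ", i, " lacks required genes: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    ti <- align_cells(d$pseudotime, d$expr)
    if (any(ti < 0 | ti > 1))
      stop("dataset ", i, " has pseudotime outside [0, 1]", call. = FALSE)
    mats[[i]] <- d$expr$values[genes, , drop = FALSE]
    batch <- c(batch, rep(as.character(d$batch), ncol(mats[[i]])))
    pt <- c(pt, ti)
    cells <- c(cells, cell_ids(d$expr))
  }
  if (anyDuplicated(cells))
    stop("duplicate cell ids across datasets", call. = FALSE)
  X <- do.call(cbind, mats)

  part <- assign_partitions(pt, P)
  occupied <- sort(unique(part))
  empty <- setdiff(seq_len(P), occupied)

  # per-gene means by partition (pooled) and by batch x partition;
  # rowsum() is used for sums and counts alike so group order matches
  group_means <- function(g) {
    s <- rowsum(t(X), g)                       # groups x genes
    cnt <- as.vector(rowsum(rep(1, length(g)), g))
    out <- t(s / cnt)                          # genes x groups
    colnames(out) <- rownames(s)
    out
  }
  pooled <- group_means(as.character(part))
  bp_key <- paste(batch, part, sep = "\r")
  bp <- group_means(bp_key)

  corrected <- X - bp[, bp_key, drop = FALSE] +
    pooled[, as.character(part), drop = FALSE]
  dimnames(corrected) <- list(genes, cells)

  trend <- matrix(NA_real_, nrow = length(genes), ncol = P,
                  dimnames = list(genes, NULL))
  trend[, occupied] <- pooled[, as.character(occupied), drop = FALSE]
  mu <- rowMeans(trend[, occupied, drop = FALSE])
  sdv <- apply(trend[, occupied, drop = FALSE], 1L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1  # flat genes: centred, not scaled
  trend <- (trend - mu) / sdv

  structure(list(cell_ids = cells, batch = batch, pseudotime = pt,
                 partition_index = part, partition_trend = trend,
                 corrected = corrected, empty_partitions = empty),
            class = "PartitionedDataset")
}

#' @export
print.PartitionedDataset <- function(x, ...) {
  cat(sprintf(paste0("PartitionedDataset: %d cells, %d batches, %d ",
                     "partitions (%d empty)\n"),
              length(x$cell_ids), length(unique(x$batch)),
              ncol(x$partition_trend), length(x$empty_partitions)))
  invisible(x)
}
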