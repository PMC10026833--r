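#' Normalize pseudotime to the unit interval
#'
#' Affine rescaling `(t - min(t)) / (max(t) - min(t))`: order-preserving
#' and idempotent. Pseudotime from any trajectory-inference method can be
#' plugged in; only its ordering and relative spacing matter downstream.
#'
#' @param t Numeric pseudotime, optionally named by cell id.
#' @return Rescaled pseudotime with `min = 0`, `max = 1`; names kept.
#' @export
#'
#' @examples
#' normalize_pseudotime(c(2, 4, 6))
normalize_pseudotime <- function(t) {
  if (!is.numeric(t) || length(t) < 2L)
    stop("pseudotime must be numeric with at least 2 values", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t)))
    stop("pseudotime contains non-finite values", call. = FALSE)
  rng <- range(t)
  if (rng[1L] == rng[2L])
    stop("degenerate trajectory: all pseudotime values are identical",
         call. = FALSE)
  (t - rng[1L]) / (rng[2L] - rng[1L])
}

#' Log-normalize a count matrix
#'
#' Per cell: `x <- ln(1 + scale_factor * count / cell_total)`, the
#' standard counts-per-10k log transform. Proportion-based, so doubling
#' all counts of a cell leaves its normalized vector unchanged.
#'
#' @param counts An [ExpressionMatrix] with `layer = "counts"`.
#' @param scale_factor Library-size scale factor (default `1e4`).
#' @return An [ExpressionMatrix] with `layer = "lognorm"`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$layer != "counts")
    stop("log_normalize expects a counts layer", call. = FALSE)
  totals <- colSums(counts$values)
  if (any(totals == 0))
    stop("cells with zero total counts: ",
         paste(utils::head(cell_ids(counts)[totals == 0], 5),
               collapse = ", "), call. = FALSE)
  v <- log1p(sweep(counts$values, 2L, scale_factor / totals, `*`))
  ExpressionMatrix(v, layer = "lognorm")
}

# Shared smoothing engine: cubic B-spline least squares of every column of
# Y (cells x genes) on pseudotime t, F test against the intercept-only
# model, and evaluation of the fitted curves on stage_grid (clamped to the
# observed pseudotime range so the grid never extrapolates).
#
# Returns list(fstat, p_value, grid_matrix [m x genes], df1, df2).
fit_trend_engine <- function(Y, t, stage_grid = NULL, df = 6L) {
  n <- nrow(Y)
  df <- as.integer(df)
  if (df < 3L) stop("spline df must be >= 3", call. = FALSE)
  if (n < df + 2L)
    stop(sprintf("need at least df + 2 = %d cells, got %d", df + 2L, n),
         call. = FALSE)
  B <- splines::bs(t, df = df)
  X <- cbind(1, B)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient spline basis (too few distinct pseudotime values)",
         call. = FALSE)
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  rss <- colSums(res^2)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  df1 <- ncol(X) - 1L
  df2 <- n - ncol(X)
  fstat <- ((tss - rss) / df1) / (rss / df2)
  # constant genes: 0/0 -> define F = 0 (no association)
  fstat[tss <= .Machine$double.eps * n] <- 0
  fstat[fstat < 0] <- 0  # numerical round-off
  p_value <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  grid_matrix <- NULL
  if (!is.null(stage_grid)) {
    g <- pmin(pmax(stage_grid, min(t)), max(t))
    Xg <- cbind(1, stats::predict(B, g))
    grid_matrix <- Xg %*% coef
  }
  list(fstat = unname(fstat), p_value = unname(p_value),
       grid_matrix = grid_matrix, df1 = df1, df2 = df2)
}

#' Fit a smooth expression trend for one gene along pseudotime
#'
#' Least-squares fit of a cubic B-spline basis (`df` basis functions plus
#' an intercept) of expression on pseudotime, with an F test of the
#' spline model against the intercept-only model. The basis contains all
#' polynomials up to degree 3, so noiseless linear or cubic trends are
#' reproduced exactly. The fitted curve is evaluated on `stage_grid`;
#' grid points outside the observed pseudotime range are clamped to the
#' boundary fit.
#'
#' @param expr_g Numeric expression of one gene, one value per cell.
#' @param t Normalized pseudotime, same length/order as `expr_g`.
#' @param stage_grid Increasing grid in `[0, 1]` on which to evaluate the
#'   fitted trend.
#' @param df Spline degrees of freedom (number of basis functions).
#' @param gene_id Optional identifier carried into the result.
#' @return A list of class `GeneTrend`: `gene_id`, `grid_values`
#'   (length `length(stage_grid)`), `fit_statistic`, `p_value`.
#' @export
fit_gene_trend <- function(expr_g, t, stage_grid, df = 6L,
                           gene_id = NA_character_) {
  stopifnot(is.numeric(expr_g), is.numeric(t),
            length(expr_g) == length(t))
  fit <- fit_trend_engine(matrix(expr_g, ncol = 1L), t, stage_grid, df)
  structure(list(gene_id = gene_id,
                 grid_values = as.numeric(fit$grid_matrix),
                 fit_statistic = fit$fstat, p_value = fit$p_value),
            class = "GeneTrend")
}

#' Select trajectory-dynamic genes by spline association testing
#'
#' Every gene is F-tested (spline fit versus a flat profile) along
#' pseudotime; p values are Benjamini-Hochberg adjusted across all tested
#' genes and genes with `q_value < fdr` are returned, ordered by
#' decreasing F statistic.
#'
#' @param expr An [ExpressionMatrix] with `layer = "lognorm"`.
#' @param t Normalized pseudotime, named by cell id or aligned with the
#'   matrix columns.
#' @param fdr False-discovery-rate threshold, strictly in (0, 1).
#' @param df Spline degrees of freedom passed to the smoother.
#' @return List with `genes` (selected ids, F-descending) and `trends`
#'   (data frame: gene_id, fit_statistic, p_value, q_value, selected).
#' @export
select_dynamic_genes <- function(expr, t, fdr = 0.05, df = 6L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$layer != "lognorm")
    stop("dynamic-gene selection expects log-normalized expression",
         call. = FALSE)
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1)
    stop("fdr must lie strictly between 0 and 1", call. = FALSE)
  t <- align_cells(t, expr)
  fit <- fit_trend_engine(t(expr$values), t, stage_grid = NULL, df = df)
  q <- stats::p.adjust(fit$p_value, method = "BH")
  trends <- data.frame(gene_id = gene_ids(expr),
                       fit_statistic = fit$fstat,
                       p_value = fit$p_value,
                       q_value = q,
                       selected = q < fdr,
                       stringsAsFactors = FALSE)
  sel <- trends[trends$selected, , drop = FALSE]
  sel <- sel[order(-sel$fit_statistic), , drop = FALSE]
  list(genes = sel$gene_id, trends = trends)
}

new_kernel_profile <- function(genes, stage_grid, R) {
  genes <- as.character(genes)
  stage_grid <- as.numeric(stage_grid)
  R <- as.matrix(R)
  if (anyDuplicated(genes)) stop("duplicate kernel genes", call. = FALSE)
  if (length(stage_grid) < 2L || any(diff(stage_grid) <= 0))
    stop("stage grid must be strictly increasing with >= 2 stages",
         call. = FALSE)
  if (nrow(R) != length(genes) || ncol(R) != length(stage_grid))
    stop("kernel matrix dimensions do not match genes/stages",
         call. = FALSE)
  if (anyNA(R) || any(!is.finite(R)))
    stop("kernel matrix contains non-finite entries", call. = FALSE)
  dimnames(R) <- list(genes, NULL)
  structure(list(genes = genes, stage_grid = stage_grid, R = R),
            class = "KernelProfile")
}

#' @export
print.KernelProfile <- function(x, ...) {
  cat(sprintf("KernelProfile: %d dynamic genes x %d stages (pseudotime %.3g..%.3g)\n",
              length(x$genes), length(x$stage_grid),
              min(x$stage_grid), max(x$stage_grid)))
  invisible(x)
}

#' Build a kernel gene-expression profile from a reference trajectory
#'
#' The central reference object: an `k x m` matrix of smoothed
#' log-normalized expression for the `k` trajectory-dynamic genes,
#' evaluated at `m` equally spaced pseudotime stages spanning `[0, 1]`.
#' Stage columns act as in-silico anchors for assigning query cells by
#' cosine similarity ([transfer_labels()]).
#'
#' @param expr Reference [ExpressionMatrix] (`lognorm` layer).
#' @param t Normalized pseudotime of the reference cells (named by cell
#'   id or aligned with the matrix columns).
#' @param m Number of stages (>= 2; default 100).
#' @param fdr FDR threshold for dynamic-gene selection.
#' @param df Spline degrees of freedom.
#' @return A `KernelProfile`: `genes`, `stage_grid`, `R` (`k x m`),
#'   plus the full per-gene `trends` table as attribute `"trends"`.
#' @export
build_kernel <- function(expr, t, m = 100L, fdr = 0.05, df = 6L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$layer != "lognorm")
    stop("build_kernel expects log-normalized expression", call. = FALSE)
  m <- as.integer(m)
  if (m < 2L) stop("a kernel needs at least 2 stages", call. = FALSE)
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1)
    stop("fdr must lie strictly between 0 and 1", call. = FALSE)
  t <- align_cells(t, expr)
  stage_grid <- seq(0, 1, length.out = m)
  fit <- fit_trend_engine(t(expr$values), t, stage_grid = stage_grid,
                          df = df)
  q <- stats::p.adjust(fit$p_value, method = "BH")
  trends <- data.frame(gene_id = gene_ids(expr),
                       fit_statistic = fit$fstat,
                       p_value = fit$p_value,
                       q_value = q,
                       selected = q < fdr,
                       stringsAsFactors = FALSE)
  sel <- which(trends$selected)
  if (length(sel) == 0L)
    stop("no dynamic genes pass fdr < ", fdr,
         "; consider a larger fdr threshold", call. = FALSE)
  sel <- sel[order(-trends$fit_statistic[sel])]
  R <- t(fit$grid_matrix[, sel, drop = FALSE])
  kernel <- new_kernel_profile(genes = trends$gene_id[sel],
                               stage_grid = stage_grid, R = R)
  attr(kernel, "trends") <- trends
  kernel
}
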