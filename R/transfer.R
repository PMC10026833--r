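#' Cosine similarity of two vectors
#'
#' `CS(A, B) = sum(A * B) / (||A|| * ||B||)`. Symmetric, bounded in
#' `[-1, 1]`, and invariant to positive rescaling of either argument —
#' the property that makes stage assignment robust to library-size and
#' batch scaling, where Euclidean distance is not.
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return The cosine similarity, a scalar in `[-1, 1]`.
#' @export
#'
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))
cosine_similarity <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for zero-norm vectors",
         call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Align a query expression matrix to the genes of a kernel profile
#'
#' Restricts and reorders the query rows to the kernel's dynamic genes.
#' Kernel genes absent from the query are imputed as zero rows (with a
#' warning); if the overlap fraction falls below `min_overlap` the query
#' is rejected instead.
#'
#' @param query_expr Query [ExpressionMatrix] (`lognorm` layer).
#' @param kernel A `KernelProfile`.
#' @param min_overlap Minimum fraction of kernel genes that must be
#'   present in the query (default 0.8).
#' @return A list of class `QueryProfile`: `genes` (kernel order), `E`
#'   (`k x n` matrix), `cell_ids`, `overlap` (fraction found).
#' @export
align_genes <- function(query_expr, kernel, min_overlap = 0.8) {
  stopifnot(inherits(query_expr, "ExpressionMatrix"),
            inherits(kernel, "KernelProfile"))
  present <- kernel$genes %in% gene_ids(query_expr)
  overlap <- mean(present)
  if (overlap < min_overlap)
    stop(sprintf(paste0("query contains only %.1f%% of the %d kernel ",
                        "genes (minimum %.1f%%)"),
                 100 * overlap, length(kernel$genes), 100 * min_overlap),
         call. = FALSE)
  E <- matrix(0, nrow = length(kernel$genes), ncol = ncol(query_expr$values),
              dimnames = list(kernel$genes, cell_ids(query_expr)))
  E[present, ] <- query_expr$values[kernel$genes[present], , drop = FALSE]
  if (any(!present))
    warning(sprintf("%d kernel gene(s) missing from query, imputed as 0: %s",
                    sum(!present),
                    paste(utils::head(kernel$genes[!present], 5),
                          collapse = ", ")), call. = FALSE)
  structure(list(genes = kernel$genes, E = E,
                 cell_ids = cell_ids(query_expr), overlap = overlap),
            class = "QueryProfile")
}

#' Cosine-similarity matrix between query cells and kernel stages
#'
#' Entry `(j, i)` is the cosine similarity between query cell `j`'s
#' dynamic-gene expression vector and kernel stage `i`'s smoothed
#' profile.
#'
#' @param query A `QueryProfile` (see [align_genes()]).
#' @param kernel The paired `KernelProfile`.
#' @return An `n x m` numeric matrix with entries in `[-1, 1]`, rows
#'   named by cell id.
#' @export
similarity_matrix <- function(query, kernel) {
  stopifnot(inherits(query, "QueryProfile"),
            inherits(kernel, "KernelProfile"))
  if (!identical(query$genes, kernel$genes))
    stop("query gene order does not match the kernel", call. = FALSE)
  qn <- sqrt(colSums(query$E^2))
  if (any(qn == 0))
    stop("query cells with zero-norm expression over kernel genes: ",
         paste(utils::head(query$cell_ids[qn == 0], 5), collapse = ", "),
         call. = FALSE)
  rn <- sqrt(colSums(kernel$R^2))
  if (any(rn == 0))
    stop("kernel stages with zero-norm profile: ",
         paste(utils::head(which(rn == 0), 5), collapse = ", "),
         call. = FALSE)
  S <- crossprod(query$E, kernel$R) / outer(qn, rn)
  rownames(S) <- query$cell_ids
  S
}

#' Transfer stage labels to query cells by maximal cosine similarity
#'
#' Each query cell is assigned the kernel stage with which its
#' dynamic-gene expression has the highest cosine similarity `S(j)`; its
#' transferred pseudotime is that stage's grid value. Ties are broken
#' toward the earliest stage (and reported via a message). An optional
#' cutoff on `S(j)` supports identity calling: cells below the cutoff
#' keep their best stage but are flagged `passed_cutoff = FALSE`.
#'
#' @param query A `QueryProfile` (see [align_genes()]).
#' @param kernel The paired `KernelProfile`.
#' @param cutoff Optional similarity cutoff in `[-1, 1]`; `NULL` (the
#'   default) disables identity calling.
#' @return Data frame with one row per query cell: `cell_id`,
#'   `stage_index` (1-based), `pseudotime`, `similarity`,
#'   `passed_cutoff`.
#' @export
transfer_labels <- function(query, kernel, cutoff = NULL) {
  S <- similarity_matrix(query, kernel)
  idx <- max.col(S, ties.method = "first")
  sim <- S[cbind(seq_len(nrow(S)), idx)]
  n_tied <- sum(rowSums(S == sim) > 1L)
  if (n_tied > 0L)
    message(n_tied, " cell(s) had tied maximal similarity; ",
            "assigned to the earliest stage")
  passed <- if (is.null(cutoff)) rep(TRUE, nrow(S)) else sim >= cutoff
  data.frame(cell_id = query$cell_ids,
             stage_index = idx,
             pseudotime = kernel$stage_grid[idx],
             similarity = sim,
             passed_cutoff = passed,
             stringsAsFactors = FALSE)
}
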