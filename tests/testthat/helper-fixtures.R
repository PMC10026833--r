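# Shared fixtures and independent oracles, built in code.

# small expression matrix with auto ids
make_expr <- function(values, layer = "lognorm") {
  values <- as.matrix(values)
  rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  colnames(values) <- sprintf("c%d", seq_len(ncol(values)))
  ExpressionMatrix(values, layer = layer)
}

# noiseless log-expression dataset: one row per function of pseudotime
make_trend_expr <- function(funs, t) {
  values <- t(vapply(funs, function(f) f(t), numeric(length(t))))
  make_expr(values, layer = "lognorm")
}

# kernel profile built directly from a k x m matrix (bypasses smoothing)
make_kernel <- function(R, stage_grid = seq(0, 1, length.out = ncol(R))) {
  R <- as.matrix(R)
  rownames(R) <- sprintf("g%d", seq_len(nrow(R)))
  new_kernel_profile(genes = rownames(R), stage_grid = stage_grid, R = R)
}

make_query <- function(E, genes = sprintf("g%d", seq_len(nrow(E)))) {
  E <- as.matrix(E)
  dimnames(E) <- list(genes, sprintf("q%d", seq_len(ncol(E))))
  structure(list(genes = genes, E = E, cell_ids = colnames(E), overlap = 1),
            class = "QueryProfile")
}

# independent brute-force stage assigner: double loop over cells and
# stages, scalar cosine, first-stage tie break
brute_force_assign <- function(E, R) {
  n <- ncol(E); m <- ncol(R)
  idx <- integer(n); sim <- numeric(n)
  for (j in seq_len(n)) {
    best_i <- NA_integer_; best_s <- -Inf
    for (i in seq_len(m)) {
      a <- E[, j]; b <- R[, i]
      s <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      if (s > best_s) { best_s <- s; best_i <- i }
    }
    idx[j] <- best_i; sim[j] <- best_s
  }
  list(stage_index = idx, similarity = sim)
}

# textbook coefficient of determination, written via var() so it is not
# a transcription of the package's own formula
r2_oracle <- function(y, p) {
  1 - mean((y - p)^2) / (stats::var(y) * (length(y) - 1) / length(y))
}

# independent Euclidean nearest-stage assigner (comparator in the
# batch-robustness check)
euclidean_assign <- function(E, R) {
  vapply(seq_len(ncol(E)), function(j)
    which.min(colSums((R - E[, j])^2)), integer(1))
}
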