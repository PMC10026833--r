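test_that("partition assignment follows the half-open bin convention", {
  expect_equal(assign_partitions(c(0, 1), P = 100), c(1L, 100L))
  expect_equal(assign_partitions(0.555, P = 100), 56L)
  expect_equal(assign_partitions(c(0, 0.3, 0.99, 1), P = 1), rep(1L, 4))
  # left edges belong to their bin, values just below to the previous one
  P <- 10L
  edges <- (1:9) / 10
  expect_equal(assign_partitions(edges, P), 2:10)
  expect_equal(assign_partitions(edges - 1e-9, P), 1:9)
  expect_error(assign_partitions(c(0.2, 1.2)), "outside")
})

test_that("partition correction equalises batch means exactly", {
  set.seed(13)
  n <- 120
  t <- runif(n)
  base <- rbind(1 + 2 * t, 3 - t, 2 + sin(2 * pi * t))
  shift <- c(0.7, -0.4, 0.2)  # additive-in-log batch effect per gene
  e1 <- make_expr(base + rnorm(3 * n, sd = 0.05))
  e2 <- ExpressionMatrix(
    pmax(base + shift + rnorm(3 * n, sd = 0.05), 0),
    gene_ids = gene_ids(e1),
    cell_ids = sprintf("d%d", seq_len(n)), layer = "lognorm")
  res <- integrate_by_partition(
    list(list(expr = e1, batch = "b1", pseudotime = t),
         list(expr = e2, batch = "b2", pseudotime = t)),
    genes = gene_ids(e1), P = 10)
  for (p in setdiff(seq_len(10), res$empty_partitions)) {
    in_p <- res$partition_index == p
    if (length(unique(res$batch[in_p])) < 2) next
    m1 <- rowMeans(res$corrected[, in_p & res$batch == "b1", drop = FALSE])
    m2 <- rowMeans(res$corrected[, in_p & res$batch == "b2", drop = FALSE])
    expect_lt(max(abs(m1 - m2)), 1e-8)
  }
  # pseudotime is untouched: rank correlation with input is exactly 1
  expect_identical(res$pseudotime, c(t, t))
})

test_that("single-batch integration is the identity", {
  set.seed(19)
  e <- make_expr(matrix(rnorm(5 * 40), nrow = 5))
  t <- runif(40)
  res <- integrate_by_partition(
    list(list(expr = e, batch = "only", pseudotime = t)),
    genes = gene_ids(e), P = 8)
  expect_equal(unname(res$corrected), unname(e$values))
})

test_that("partition trend has P columns with empty partitions flagged as NA", {
  set.seed(37)
  e <- make_expr(matrix(rnorm(4 * 30), nrow = 4))
  t <- runif(30, 0, 0.45)  # upper half of [0,1] empty
  res <- integrate_by_partition(
    list(list(expr = e, batch = "b", pseudotime = t)),
    genes = gene_ids(e), P = 10)
  expect_equal(ncol(res$partition_trend), 10)
  expect_true(all(res$empty_partitions >= 6))
  expect_true(all(is.na(res$partition_trend[, res$empty_partitions])))
  occ <- setdiff(1:10, res$empty_partitions)
  expect_true(all(is.finite(res$partition_trend[, occ])))
  # gene-wise z-scoring across occupied partitions
  expect_equal(unname(rowMeans(res$partition_trend[, occ])), rep(0, 4))
})

test_that("mosaic noiseless trends stay continuous across the window gaps", {
  # two batches covering disjoint pseudotime windows of one smooth path
  t1 <- c(seq(0, 0.2, length.out = 30), seq(0.4, 0.6, length.out = 30),
          seq(0.8, 1, length.out = 30))
  t2 <- c(seq(0.3, 0.35, length.out = 20), seq(0.7, 0.75, length.out = 20))
  # genes whose bumps tile pseudotime evenly, so profile change is
  # uniform along the path and similarity decays with pseudotime distance
  funs <- lapply(seq(0.025, 0.975, length.out = 20), function(ctr) {
    force(ctr)
    function(t) exp(-(t - ctr)^2 / (2 * 0.1^2))
  })
  e1 <- make_trend_expr(funs, t1)
  e2 <- make_trend_expr(funs, t2)
  colnames(e2$values) <- sprintf("d%d", seq_along(t2))
  res <- integrate_by_partition(
    list(list(expr = e1, batch = "b1", pseudotime = t1),
         list(expr = e2, batch = "b2", pseudotime = t2)),
    genes = gene_ids(e1), P = 20)
  occ <- setdiff(seq_len(20), res$empty_partitions)
  trend <- res$partition_trend[, occ, drop = FALSE]
  cs <- function(i, j) cosine_similarity(trend[, i], trend[, j])
  pairs <- t(combn(length(occ), 2))
  sims <- mapply(cs, pairs[, 1], pairs[, 2])
  # adjacency = consecutive occupied partitions; with one-bin gaps these
  # span at most two bins (~0.1 pseudotime), while clearly non-adjacent
  # pairs sit four or more bins (~0.2) apart. Continuity across the
  # batch gaps means every adjacent pair is more alike than any of those.
  bin_gap <- occ[pairs[, 2]] - occ[pairs[, 1]]
  adjacent <- pairs[, 2] - pairs[, 1] == 1
  distant <- bin_gap >= 4
  expect_gte(min(sims[adjacent]), max(sims[distant]))
})
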