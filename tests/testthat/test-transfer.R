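test_that("cosine similarity matches its closed form and invariances", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)))
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 0.974632,
               tolerance = 1e-6)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  set.seed(3)
  a <- rnorm(10)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, 7.3 * a), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("align_genes restores kernel gene order and imputes absences", {
  kernel <- make_kernel(matrix(c(1, 0, 2, 0, 1, 2), nrow = 3))
  q <- make_expr(matrix(runif(12), nrow = 4))
  # query genes shuffled, one extra gene, all kernel genes present
  rownames(q$values) <- c("g3", "g1", "gX", "g2")
  qp <- align_genes(q, kernel)
  expect_identical(qp$genes, kernel$genes)
  expect_equal(qp$E["g1", ], q$values["g1", ])
  expect_equal(qp$E["g3", ], q$values["g3", ])
  expect_equal(qp$overlap, 1)

  # 2/3 overlap below the default 0.8 threshold
  rownames(q$values) <- c("g3", "g1", "gX", "gY")
  expect_error(align_genes(q, kernel), "80")
  # permissive threshold: missing gene imputed as zero, warned
  expect_warning(qp2 <- align_genes(q, kernel, min_overlap = 0.5),
                 "imputed")
  expect_equal(unname(qp2$E["g2", ]), rep(0, 3))
})

test_that("a zero-everywhere kernel gene does not change assignments", {
  set.seed(9)
  R <- rbind(matrix(runif(5 * 8), nrow = 5), 0)
  kernel <- make_kernel(R)
  E <- rbind(matrix(runif(5 * 6), nrow = 5), 0)
  with_gene <- transfer_labels(make_query(E), kernel)
  kernel5 <- make_kernel(R[1:5, ])
  without <- transfer_labels(make_query(E[1:5, ]), kernel5)
  expect_identical(with_gene$stage_index, without$stage_index)
})

test_that("similarity matrix matches scalar cosine and stays in [-1, 1]", {
  kernel <- make_kernel(matrix(c(1, 0, 0, 1), nrow = 2))
  qp <- make_query(matrix(c(1, 1), nrow = 2))
  S <- similarity_matrix(qp, kernel)
  expect_equal(unname(S[1, ]), c(1 / sqrt(2), 1 / sqrt(2)))

  set.seed(17)
  kernel2 <- make_kernel(matrix(rnorm(6 * 9), nrow = 6))
  qp2 <- make_query(matrix(rnorm(6 * 4), nrow = 6))
  S2 <- similarity_matrix(qp2, kernel2)
  expect_true(all(S2 >= -1 - 1e-12 & S2 <= 1 + 1e-12))
  expect_equal(unname(S2[3, 5]),
               cosine_similarity(qp2$E[, 3], kernel2$R[, 5]))
  # a query cell equal to a kernel column attains 1 there
  qp3 <- make_query(kernel2$R[, 3, drop = FALSE])
  expect_equal(unname(similarity_matrix(qp3, kernel2)[1, 3]), 1)
})

test_that("transfer assigns the argmax stage, with scale invariance", {
  set.seed(29)
  kernel <- make_kernel(matrix(runif(8 * 40), nrow = 8))
  # identity: kernel columns transfer to their own stage with S = 1
  self <- transfer_labels(make_query(kernel$R), kernel)
  expect_identical(self$stage_index, seq_len(40))
  expect_equal(self$similarity, rep(1, 40))
  expect_equal(self$pseudotime, kernel$stage_grid)

  # positive per-cell scaling never changes any assignment
  E <- matrix(rexp(8 * 25), nrow = 8)
  base <- transfer_labels(make_query(E), kernel)
  scaled <- transfer_labels(
    make_query(E * rep(runif(25, 0.1, 10), each = 8)), kernel)
  expect_identical(scaled$stage_index, base$stage_index)
  expect_equal(unname(transfer_labels(
    make_query(2.5 * kernel$R[, 5, drop = FALSE]), kernel)$stage_index), 5L)
})

test_that("transfer agrees with the brute-force oracle, ties to earliest stage", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    m <- sample(2:50, 1)
    n <- sample(1:30, 1)
    R <- matrix(sample(1:4, k * m, replace = TRUE), nrow = k)
    if (rep %% 3 == 0 && m >= 2) R[, m] <- R[, 1]  # force exact ties
    E <- matrix(sample(1:4, k * n, replace = TRUE), nrow = k)
    kernel <- make_kernel(R)
    res <- suppressMessages(transfer_labels(make_query(E), kernel))
    oracle <- brute_force_assign(E, R)
    expect_identical(res$stage_index, oracle$stage_index)
    expect_equal(res$similarity, oracle$similarity)
  }
})

test_that("similarity cutoff drives identity calling", {
  kernel <- make_kernel(diag(3) + 0.01)
  qp <- make_query(matrix(c(1, 0, 0, 1, 1, 1), nrow = 3))
  res <- transfer_labels(qp, kernel, cutoff = 0.99)
  expect_true(res$passed_cutoff[1])
  expect_false(res$passed_cutoff[2])
  expect_true(all(transfer_labels(qp, kernel)$passed_cutoff))
})
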