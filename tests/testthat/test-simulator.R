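test_that("stage sampling respects the mosaic batch windows", {
  cfg <- sim_config(n_cells = 3000, seed = 1)
  set.seed(1)
  cells <- sample_stages(cfg)
  b1 <- cells$stage[cells$batch == "batch1"]
  b2 <- cells$stage[cells$batch == "batch2"]
  expect_equal(length(b1), 1500)
  expect_true(all(b1 %in% c(1:20, 40:60, 80:100)))
  expect_true(all(b2 %in% c(30:35, 70:75)))
  # uniformity over the window union within 3 binomial SEs
  pool2 <- c(30:35, 70:75)
  freq <- table(factor(b2, levels = pool2)) / length(b2)
  p <- 1 / length(pool2)
  se <- sqrt(p * (1 - p) / length(b2))
  expect_true(all(abs(freq - p) <= 3 * se))
  # degenerate single window
  cfg1 <- sim_config(batch_windows = list(b = list(c(1L, 1L))),
                     n_cells = 10)
  expect_true(all(sample_stages(cfg1)$stage == 1))
})

test_that("gene trends scale with snr and vanish without signal", {
  cfg0 <- sim_config(n_genes = 200, snr = 0)
  set.seed(2)
  gt0 <- gene_trends(cfg0)
  expect_true(all(gt0$mu == gt0$mu[, 1]))  # constant in stage

  cfg <- sim_config(n_genes = 500, snr = 0.1)
  set.seed(3)
  gt <- gene_trends(cfg)
  expect_equal(sum(gt$gene_meta$is_dynamic), round(0.3 * 500))
  lin <- gt$gene_meta$shape == "linear"
  # linear genes: endpoint difference equals delta exactly
  expect_equal(unname(gt$mu[lin, 100] - gt$mu[lin, 1]),
               gt$gene_meta$delta[lin])
  # mean |delta| scales linearly with snr
  cfg2 <- sim_config(n_genes = 500, snr = 0.2)
  set.seed(3)
  gt2 <- gene_trends(cfg2)
  ratio <- mean(abs(gt2$gene_meta$delta[gt2$gene_meta$is_dynamic])) /
    mean(abs(gt$gene_meta$delta[gt$gene_meta$is_dynamic]))
  expect_equal(ratio, 2, tolerance = 1e-8)
})

test_that("simulated counts are reproducible, integral and library-sized", {
  cfg <- sim_config(n_genes = 300, n_cells = 200, seed = 77)
  d1 <- simulate_counts(cfg)
  d2 <- simulate_counts(cfg)
  expect_identical(d1$counts$values, d2$counts$values)
  expect_identical(d1$true_stage, d2$true_stage)

  v <- d1$counts$values
  expect_true(all(v >= 0 & v == floor(v)))
  expect_true(all(d1$true_stage >= 1 & d1$true_stage <= 100))
  # every cell's stage lies inside its batch's windows
  expect_true(all(d1$true_stage[d1$batch == "batch2"] %in%
                    c(30:35, 70:75)))
  # mean observed total consistent with the library-size model
  mean_total <- mean(colSums(v))
  mu <- exp(cfg$lib_size_logmean + cfg$lib_size_logsd^2 / 2)
  sd_tot <- stats::sd(colSums(v)) / sqrt(ncol(v))
  expect_lt(abs(mean_total - mu), 3 * sd_tot + 0.05 * mu)
})

test_that("simulation datasets round-trip through the on-disk layout", {
  cfg <- sim_config(n_genes = 40, n_cells = 30, seed = 5)
  ds <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  write_simulation(ds, dir)
  back <- read_simulation(dir)
  expect_equal(back$counts$values, ds$counts$values)
  expect_identical(back$true_stage, ds$true_stage)
  expect_true(all(back$batch %in% c("batch1", "batch2")))
  expect_equal(nrow(back$gene_meta), 40)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$subcommand, "simulate")
})

test_that("cosine transfer tolerates batch shifts better than Euclidean", {
  cfg <- sim_config(n_genes = 600, n_cells = 600, snr = 0.25,
                    batch_effect_sd = 0.6, seed = 404)
  ds <- simulate_counts(cfg)
  expr <- log_normalize(ds$counts)
  ref <- names(ds$batch)[ds$batch == "batch1"]
  qry <- names(ds$batch)[ds$batch == "batch2"]
  kernel <- build_kernel(subset_expression(expr, cells = ref),
                         true_pseudotime(ds$true_stage[ref], m = 100),
                         m = 100)
  qp <- align_genes(subset_expression(expr, cells = qry), kernel)
  truth <- true_pseudotime(ds$true_stage[qry], m = 100)
  r2_cos <- r2_score(truth, transfer_labels(qp, kernel)$pseudotime)
  r2_euc <- r2_score(truth,
                     kernel$stage_grid[euclidean_assign(qp$E, kernel$R)])
  expect_gt(r2_cos, r2_euc)
})
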