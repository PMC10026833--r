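#' Configuration for the step-path count simulator
#'
#' Describes a continuous differentiation of `m_stages` discrete stages
#' sampled mosaically by two batches: by default batch1 covers stage
#' windows A (1-20), C (40-60) and E (80-100) while batch2 covers B
#' (30-35) and D (70-75), so the batches share no stages at all — the
#' regime in which anchor-based integration over-corrects.
#'
#' The generative model works on the log scale. Each gene has a baseline
#' `log b_g ~ Normal(baseline_logmean, baseline_logsd^2)`. A fraction
#' `p_dynamic` of genes receive a stage trend of total amplitude
#' `delta_g = snr * effect_scale` log units (random sign); of those, a
#' fraction `nonlinear_prop` follow a nonlinear unit shape (random
#' sigmoid or Gaussian bump) instead of a linear ramp. Per-cell
#' biological noise is `Normal(0, effect_scale^2 * noise_factor / snr)`,
#' so `snr` expresses the stage-effect scale relative to non-stage
#' noise. Batch effects are per-gene log shifts
#' `Normal(0, batch_effect_sd^2)`. Counts are negative binomial with
#' per-cell expected totals drawn log-normally.
#'
#' @param m_stages Number of differentiation stages (default 100).
#' @param n_genes Number of genes (default 2000).
#' @param n_cells Total cells across both batches (default 3000, split
#'   equally; an odd remainder goes to batch1).
#' @param batch_windows Named list: per batch, a list of inclusive stage
#'   intervals `c(lo, hi)`.
#' @param p_dynamic Fraction of genes with a stage trend (default 0.3).
#' @param snr Signal-to-noise ratio, > 0 (default 0.2).
#' @param nonlinear_prop Fraction of dynamic genes with nonlinear trends
#'   (default 0.3).
#' @param batch_effect_sd SD of per-gene log batch shifts (default 0.15).
#' @param nb_dispersion Negative-binomial dispersion (default 0.2; the
#'   NB size parameter is its reciprocal).
#' @param lib_size_logmean,lib_size_logsd Log-normal library-size model
#'   (defaults `log(2e4)` and 0.2).
#' @param baseline_logmean,baseline_logsd Baseline log-expression model
#'   (defaults 0.5 and 1).
#' @param effect_scale Stage-effect scale in log units (default 6).
#' @param noise_factor Scales cell-level noise variance relative to the
#'   squared effect scale (default 5e-4).
#' @param seed Integer seed; the simulation is fully reproducible from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(m_stages = 100L,
                       n_genes = 2000L,
                       n_cells = 3000L,
                       batch_windows = list(
                         batch1 = list(c(1L, 20L), c(40L, 60L), c(80L, 100L)),
                         batch2 = list(c(30L, 35L), c(70L, 75L))),
                       p_dynamic = 0.3,
                       snr = 0.2,
                       nonlinear_prop = 0.3,
                       batch_effect_sd = 0.15,
                       nb_dispersion = 0.2,
                       lib_size_logmean = log(2e4),
                       lib_size_logsd = 0.2,
                       baseline_logmean = 0.5,
                       baseline_logsd = 1,
                       effect_scale = 6,
                       noise_factor = 5e-4,
                       seed = 1L) {
  cfg <- list(m_stages = as.integer(m_stages), n_genes = as.integer(n_genes),
              n_cells = as.integer(n_cells), batch_windows = batch_windows,
              p_dynamic = p_dynamic, snr = snr,
              nonlinear_prop = nonlinear_prop,
              batch_effect_sd = batch_effect_sd,
              nb_dispersion = nb_dispersion,
              lib_size_logmean = lib_size_logmean,
              lib_size_logsd = lib_size_logsd,
              baseline_logmean = baseline_logmean,
              baseline_logsd = baseline_logsd,
              effect_scale = effect_scale, noise_factor = noise_factor,
              seed = as.integer(seed))
  stopifnot(cfg$m_stages >= 2L, cfg$n_genes >= 1L, cfg$n_cells >= 2L,
            cfg$p_dynamic >= 0, cfg$p_dynamic <= 1,
            cfg$nonlinear_prop >= 0, cfg$nonlinear_prop <= 1,
            cfg$snr >= 0, cfg$batch_effect_sd >= 0, cfg$nb_dispersion > 0,
            cfg$effect_scale >= 0, cfg$noise_factor >= 0,
            length(cfg$batch_windows) >= 1L)
  for (b in names(cfg$batch_windows)) {
    for (w in cfg$batch_windows[[b]]) {
      if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 1L ||
          w[2L] > cfg$m_stages)
        stop("invalid stage window in batch ", b, call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

#' Sample ground-truth stages and batch labels
#'
#' Cells are split equally between the batches (odd remainder to the
#' first); within a batch, stages are drawn uniformly over the union of
#' that batch's inclusive stage windows.
#'
#' Uses the current RNG state; [simulate_counts()] seeds it from the
#' config.
#'
#' @param config A [sim_config()].
#' @return Data frame: `cell_id`, `batch`, `stage` (integer in
#'   `[1, m_stages]`).
#' @export
sample_stages <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  batches <- names(config$batch_windows)
  nb <- length(batches)
  base <- config$n_cells %/% nb
  sizes <- rep(base, nb)
  sizes[seq_len(config$n_cells %% nb)] <- base + 1L
  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    pool <- unlist(lapply(config$batch_windows[[i]],
                          function(w) seq.int(w[1L], w[2L])))
    if (!length(pool)) stop("empty window union", call. = FALSE)
    out[[i]] <- data.frame(batch = batches[i],
                           stage = pool[sample.int(length(pool), sizes[i],
                                                   replace = TRUE)],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- cbind(cell_id = sprintf("cell_%05d", seq_len(nrow(res))), res)
  res$cell_id <- as.character(res$cell_id)
  rownames(res) <- NULL
  res
}

# unit-amplitude nonlinear trend shapes on u in [0, 1]
shape_on_grid <- function(kind, u) {
  h <- switch(kind,
              sigmoid = {
                mid <- stats::runif(1L, 0.25, 0.75)
                stats::plogis((u - mid) / 0.1)
              },
              bump = {
                ctr <- stats::runif(1L, 0.2, 0.8)
                wid <- stats::runif(1L, 0.08, 0.2)
                exp(-(u - ctr)^2 / (2 * wid^2))
              })
  rng <- range(h)
  if (rng[2L] > rng[1L]) (h - rng[1L]) / (rng[2L] - rng[1L]) else h * 0
}

#' Per-gene log-mean trends across the stage path
#'
#' Builds the `n_genes x m_stages` matrix of log-scale expected
#' expression `mu_g(s)` plus the per-gene metadata (dynamic/nonlinear
#' flags, trend amplitude `delta`, baseline).
#'
#' Uses the current RNG state; [simulate_counts()] seeds it from the
#' config.
#'
#' @param config A [sim_config()].
#' @return List with `mu` (genes x stages matrix) and `gene_meta` (data
#'   frame: gene_id, baseline, is_dynamic, is_nonlinear, shape, delta).
#' @export
gene_trends <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_genes
  m <- config$m_stages
  u <- (seq_len(m) - 1) / (m - 1)
  log_b <- stats::rnorm(G, config$baseline_logmean, config$baseline_logsd)
  n_dyn <- round(config$p_dynamic * G)
  dyn <- sort(sample.int(G, n_dyn))
  n_nl <- round(config$nonlinear_prop * n_dyn)
  nl <- sort(sample(dyn, n_nl))
  delta <- numeric(G)
  delta[dyn] <- config$snr * config$effect_scale *
    sample(c(-1, 1), n_dyn, replace = TRUE)
  shape <- rep("flat", G)
  shape[dyn] <- "linear"
  shape[nl] <- sample(c("sigmoid", "bump"), n_nl, replace = TRUE)
  H <- matrix(0, nrow = G, ncol = m)
  lin <- setdiff(dyn, nl)
  if (length(lin))
    H[lin, ] <- matrix(u, nrow = length(lin), ncol = m, byrow = TRUE)
  for (g in nl) H[g, ] <- shape_on_grid(shape[g], u)
  mu <- log_b + delta * H
  gene_meta <- data.frame(gene_id = sprintf("gene_%05d", seq_len(G)),
                          baseline = exp(log_b),
                          is_dynamic = seq_len(G) %in% dyn,
                          is_nonlinear = seq_len(G) %in% nl,
                          shape = shape, delta = delta,
                          stringsAsFactors = FALSE)
  rownames(mu) <- gene_meta$gene_id
  list(mu = mu, gene_meta = gene_meta)
}

#' Simulate a two-batch step-path count dataset
#'
#' Draws ground-truth stages ([sample_stages()]) and gene trends
#' ([gene_trends()]), then generates counts: for cell `c` at stage `s`
#' in batch `b`, the expected expression is proportional to
#' `exp(mu_g(s) + beta_gb + eta_gc)` with per-(gene, batch) shift
#' `beta ~ Normal(0, batch_effect_sd^2)` and per-(gene, cell) noise
#' `eta ~ Normal(0, effect_scale^2 * noise_factor / snr)`; per-cell
#' proportions are rescaled so the expected total equals the cell's
#' log-normal library size, and counts are drawn negative-binomially
#' with dispersion `nb_dispersion`. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()] with `snr > 0`.
#' @return A list of class `SimulationDataset`: `counts`
#'   ([ExpressionMatrix], counts layer), `true_stage` (integer per
#'   cell), `batch` (label per cell), `gene_meta`, `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$snr <= 0)
    stop("simulate_counts requires snr > 0", call. = FALSE)
  set.seed(config$seed)
  cells <- sample_stages(config)
  gt <- gene_trends(config)
  G <- config$n_genes
  n <- nrow(cells)
  batches <- names(config$batch_windows)
  beta <- matrix(stats::rnorm(G * length(batches),
                              sd = config$batch_effect_sd),
                 nrow = G)
  eta_sd <- config$effect_scale *
    sqrt(config$noise_factor / config$snr)
  logW <- gt$mu[, cells$stage, drop = FALSE] +
    beta[, match(cells$batch, batches), drop = FALSE] +
    matrix(stats::rnorm(G * n, sd = eta_sd), nrow = G)
  W <- exp(logW)
  lib <- stats::rlnorm(n, config$lib_size_logmean, config$lib_size_logsd)
  lambda <- W * rep(lib / colSums(W), each = G)
  counts <- matrix(stats::rnbinom(G * n, mu = lambda,
                                  size = 1 / config$nb_dispersion),
                   nrow = G,
                   dimnames = list(gt$gene_meta$gene_id, cells$cell_id))
  structure(list(counts = ExpressionMatrix(counts, layer = "counts"),
                 true_stage = stats::setNames(cells$stage, cells$cell_id),
                 batch = stats::setNames(cells$batch, cells$cell_id),
                 gene_meta = gt$gene_meta,
                 config = config),
            class = "SimulationDataset")
}

#' @export
print.SimulationDataset <- function(x, ...) {
  cat(sprintf(paste0("SimulationDataset: %d genes x %d cells, %d stages, ",
                     "batches: %s (snr %.3g, nonlinear %.3g)\n"),
              nrow(x$counts$values), ncol(x$counts$values),
              x$config$m_stages,
              paste(names(x$config$batch_windows), collapse = "/"),
              x$config$snr, x$config$nonlinear_prop))
  invisible(x)
}

#' True normalized pseudotime of simulated cells
#'
#' Maps integer stages `1..m` onto `[0, 1]` via `(s - 1) / (m - 1)`,
#' the scale on which transferred pseudotime is evaluated.
#'
#' @param dataset A `SimulationDataset`, or an integer stage vector if
#'   `m` is given.
#' @param m Number of stages (taken from the dataset config if omitted).
#' @return Numeric pseudotime in `[0, 1]` (named if stages were named).
#' @export
true_pseudotime <- function(dataset, m = NULL) {
  if (inherits(dataset, "SimulationDataset")) {
    s <- dataset$true_stage
    m <- dataset$config$m_stages
  } else {
    s <- dataset
    if (is.null(m)) stop("m is required for a bare stage vector",
                         call. = FALSE)
  }
  (s - 1) / (m - 1)
}

#' Write a simulated dataset to a directory
#'
#' Writes `matrix.mtx` + `features.tsv` + `barcodes.tsv` (counts),
#' `truth.tsv` (cell_id, batch, stage), `gene_meta.tsv` and
#' `manifest.json` (config, seed, package version).
#'
#' @param dataset A `SimulationDataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "SimulationDataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$counts, out_dir, format = "mtx_triplet")
  utils::write.table(data.frame(cell_id = names(dataset$true_stage),
                                batch = unname(dataset$batch),
                                stage = unname(dataset$true_stage)),
                     file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_meta, file.path(out_dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 subcommand = "simulate",
                 config = unclass(dataset$config),
                 seed = dataset$config$seed)
  invisible(out_dir)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list with `counts`, `true_stage`, `batch`, `gene_meta`.
#' @export
read_simulation <- function(dir) {
  counts <- read_expression(dir, format = "mtx_triplet", layer = "counts")
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             colClasses = c("character", "character",
                                            "integer"))
  gene_meta <- utils::read.delim(file.path(dir, "gene_meta.tsv"),
                                 stringsAsFactors = FALSE)
  list(counts = counts,
       true_stage = stats::setNames(truth$stage, truth$cell_id),
       batch = stats::setNames(truth$batch, truth$cell_id),
       gene_meta = gene_meta)
}
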