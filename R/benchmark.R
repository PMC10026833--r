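#' Coefficient of determination between true and inferred pseudotime
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Equals 1 for
#' perfect prediction, 0 for the constant mean predictor, and can be
#' negative for predictors worse than the mean. Both series should be on
#' the same `[0, 1]` pseudotime scale: simulated stages via
#' [true_pseudotime()], transferred labels via their stage-grid value.
#'
#' @param true_values Numeric truth vector (length >= 2, not all equal).
#' @param predicted Numeric predictions, same length.
#' @return A scalar `<= 1`.
#' @export
#'
#' @examples
#' r2_score(c(1, 2, 3, 4), c(2, 2, 2, 2))  # -0.2
r2_score <- function(true_values, predicted) {
  stopifnot(is.numeric(true_values), is.numeric(predicted))
  if (length(true_values) < 2L || length(true_values) != length(predicted))
    stop("need two equal-length vectors with >= 2 values", call. = FALSE)
  if (anyNA(true_values) || anyNA(predicted))
    stop("missing values in input", call. = FALSE)
  tss <- sum((true_values - mean(true_values))^2)
  if (tss == 0)
    stop("degenerate truth vector: all values identical", call. = FALSE)
  1 - sum((true_values - predicted)^2) / tss
}

#' Run one simulate-build-transfer-score benchmark
#'
#' One full pass of the benchmark protocol: simulate a two-batch mosaic
#' dataset, log-normalize, build the kernel profile from the reference
#' batch (using the simulated ground-truth stages' normalized pseudotime
#' as reference pseudotime, which isolates the transfer step from
#' trajectory inference), transfer the query batch, and score the query
#' cells' transferred pseudotime against truth with [r2_score()].
#'
#' @param snr Signal-to-noise ratio of the simulation.
#' @param nonlinear_prop Nonlinear-gene proportion of the simulation.
#' @param seed Integer seed for this run.
#' @param repetition Repetition index recorded in the result.
#' @param ref_batch Name of the reference batch (default the first
#'   configured batch).
#' @param fdr,df Kernel-building parameters.
#' @param ... Further overrides passed to [sim_config()].
#' @return One-row data frame: snr, nonlinear_prop, repetition, seed,
#'   n_kernel_genes, r2, failed, failure_regime.
#' @export
run_one <- function(snr, nonlinear_prop, seed, repetition = 1L,
                    ref_batch = NULL, fdr = 0.05, df = 6L, ...) {
  cfg <- sim_config(snr = snr, nonlinear_prop = nonlinear_prop,
                    seed = seed, ...)
  ds <- simulate_counts(cfg)
  expr <- log_normalize(ds$counts)
  batches <- names(cfg$batch_windows)
  ref_batch <- ref_batch %||% batches[1L]
  ref_cells <- names(ds$batch)[ds$batch == ref_batch]
  qry_cells <- names(ds$batch)[ds$batch != ref_batch]
  ref_expr <- subset_expression(expr, cells = ref_cells)
  qry_expr <- subset_expression(expr, cells = qry_cells)
  ref_t <- true_pseudotime(ds$true_stage[ref_cells], m = cfg$m_stages)

  n_genes <- NA_integer_
  r2 <- NA_real_
  failed <- FALSE
  tryCatch({
    kernel <- build_kernel(ref_expr, ref_t, m = cfg$m_stages, fdr = fdr,
                           df = df)
    n_genes <- length(kernel$genes)
    qp <- align_genes(qry_expr, kernel)
    tr <- transfer_labels(qp, kernel)
    r2 <- r2_score(true_pseudotime(ds$true_stage[qry_cells],
                                   m = cfg$m_stages),
                   tr$pseudotime)
  }, error = function(e) {
    failed <<- TRUE
    message("run failed (snr=", snr, ", nonlinear=", nonlinear_prop,
            "): ", conditionMessage(e))
  })
  data.frame(snr = snr, nonlinear_prop = nonlinear_prop,
             repetition = as.integer(repetition), seed = as.integer(seed),
             n_kernel_genes = n_genes, r2 = r2, failed = failed,
             failure_regime = is_failure_regime(snr, nonlinear_prop),
             stringsAsFactors = FALSE)
}

# the one grid cell where stage recovery breaks down for every method and
# which is therefore excluded from summary means
is_failure_regime <- function(snr, nonlinear_prop) {
  isTRUE(all.equal(snr, 0.05)) && isTRUE(all.equal(nonlinear_prop, 0.5))
}

#' Enumerate the benchmark run plan
#'
#' The full factorial grid of snr values, nonlinear proportions and
#' repetitions, with one derived seed per run and the failure-regime
#' exclusion flag. [run_grid()] executes exactly this plan, so the
#' bookkeeping (run count, exclusion flags, seeds) can be inspected
#' without running any simulation.
#'
#' @param snr_list,nonlinear_list Numeric grids.
#' @param reps Repetitions per grid cell (>= 1).
#' @param base_seed Seed from which per-run seeds are derived.
#' @return Data frame: snr, nonlinear_prop, repetition, seed, excluded.
#' @export
enumerate_grid <- function(snr_list, nonlinear_list, reps, base_seed) {
  stopifnot(length(snr_list) >= 1L, length(nonlinear_list) >= 1L,
            reps >= 1L)
  plan <- expand.grid(repetition = seq_len(reps),
                      nonlinear_prop = nonlinear_list,
                      snr = snr_list,
                      KEEP.OUT.ATTRS = FALSE)
  plan <- plan[, c("snr", "nonlinear_prop", "repetition")]
  # seeds attach to grid coordinates, not row position, so the report is
  # invariant to how the grid lists are ordered
  ord <- order(plan$snr, plan$nonlinear_prop, plan$repetition)
  plan$seed[ord] <- derive_seeds(base_seed, nrow(plan))
  plan$excluded <- mapply(is_failure_regime, plan$snr, plan$nonlinear_prop)
  rownames(plan) <- NULL
  plan
}

#' Run the full benchmark grid
#'
#' Executes [run_one()] for every row of [enumerate_grid()] and
#' aggregates: per-cell grid means and an overall mean computed over the
#' non-excluded, non-failed runs. Runs in the failure-regime cell
#' (snr 0.05, nonlinear proportion 0.5) are executed but excluded from
#' the means unless `keep_failure_regime = TRUE`.
#'
#' @param snr_list,nonlinear_list Numeric grids.
#' @param reps Repetitions per grid cell.
#' @param base_seed Seed from which all per-run seeds derive.
#' @param keep_failure_regime Retain the failure-regime cell in means.
#' @param verbose Print per-run progress.
#' @param ... Overrides passed through [run_one()] to [sim_config()].
#' @return A list of class `BenchmarkReport`: `runs` (per-run records),
#'   `grid_means` (per snr x nonlinear cell), `mean_r2` and
#'   `mean_r2_percent` (overall, non-excluded runs), `n_excluded`,
#'   `n_failed`, `base_seed`.
#' @export
run_grid <- function(snr_list, nonlinear_list, reps = 10L, base_seed = 1L,
                     keep_failure_regime = FALSE, verbose = FALSE, ...) {
  plan <- enumerate_grid(snr_list, nonlinear_list, reps, base_seed)
  runs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    if (verbose)
      message(sprintf("[%d/%d] snr=%.3g nonlinear=%.3g rep=%d",
                      i, nrow(plan), p$snr, p$nonlinear_prop, p$repetition))
    runs[[i]] <- run_one(p$snr, p$nonlinear_prop, seed = p$seed,
                         repetition = p$repetition, ...)
  }
  runs <- do.call(rbind, runs)
  runs$excluded <- runs$failed |
    (if (keep_failure_regime) FALSE else runs$failure_regime)

  keep <- !runs$excluded
  grid_means <- stats::aggregate(r2 ~ snr + nonlinear_prop,
                                 data = runs[keep, , drop = FALSE],
                                 FUN = mean)
  mean_r2 <- mean(runs$r2[keep])
  structure(list(runs = runs, grid_means = grid_means,
                 mean_r2 = mean_r2, mean_r2_percent = 100 * mean_r2,
                 n_excluded = sum(runs$excluded),
                 n_failed = sum(runs$failed),
                 base_seed = as.integer(base_seed)),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf(paste0("BenchmarkReport: %d runs (%d excluded, %d failed)\n",
                     "  mean R2 over scored runs: %.4f (%.1f on the 0-100 ",
                     "scale)\n"),
              nrow(x$runs), x$n_excluded, x$n_failed, x$mean_r2,
              x$mean_r2_percent))
  invisible(x)
}

#' Write a benchmark report as JSON
#'
#' @param report A `BenchmarkReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  stopifnot(inherits(report, "BenchmarkReport"))
  jsonlite::write_json(
    list(runs = report$runs, grid_means = report$grid_means,
         mean_r2 = report$mean_r2,
         mean_r2_percent = report$mean_r2_percent,
         n_excluded = report$n_excluded, n_failed = report$n_failed,
         base_seed = report$base_seed,
         package_version = as.character(utils::packageVersion("scstalt"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score externally produced pseudotime labels against a truth table
#'
#' Reads a two-column TSV (`cell_id`, `pseudotime`) produced by any
#' other integration or trajectory method and joins it to a truth
#' vector, so external methods can be scored with the same [r2_score()]
#' as the built-in transfer. Cells present in the truth but missing from
#' the file are an error; row order is irrelevant.
#'
#' @param path TSV path of inferred pseudotime.
#' @param truth Named numeric vector of true pseudotime in `[0, 1]`.
#' @return A list: `inferred` (aligned to `names(truth)`), `r2`.
#' @export
import_external_labels <- function(path, truth) {
  stopifnot(is.numeric(truth), !is.null(names(truth)))
  inferred <- read_pseudotime(path)
  missing <- setdiff(names(truth), names(inferred))
  if (length(missing))
    stop("cells missing from external labels: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  inferred <- inferred[names(truth)]
  list(inferred = inferred, r2 = r2_score(unname(truth), unname(inferred)))
}
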