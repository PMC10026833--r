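# scstalt

Stage label transfer and mosaic integration for single-cell RNA-seq
trajectories.

## The problem

Two single-cell datasets can sample the *same* continuous
differentiation process while sharing *no* cell populations at all —
one lab captures the early and late segments, another the intermediate
windows. Anchor-based integration (mutual nearest neighbours,
shared-population anchors) over-corrects in this mosaic regime: with no
genuinely shared cells, anchors form between distinct stages and
collapse them. `scstalt` is for researchers who need to place query
cells onto a reference differentiation trajectory — and to integrate
mosaic batches — without assuming any population overlap.

## The method

1. **Kernel profile.** Given a reference expression matrix and a
   pseudotime `t` normalized to [0, 1], fit each gene's log-normalized
   expression on a cubic B-spline basis in `t`, keep the genes whose
   spline fit beats a flat profile (F test, Benjamini–Hochberg,
   `q < 0.05`), and evaluate the `k` fitted trends at `m` equally spaced
   stages. This yields the kernel matrix

   `R[k, m] = (g_i^j)`, one column per stage — a set of in-silico
   anchors summarising the whole trajectory.

2. **Transfer.** A query cell with dynamic-gene expression `E[j]` is
   assigned the stage maximising cosine similarity

   `CS(A, B) = (A · B) / (||A|| ||B||)`,
   `S(j) = max_i CS(E[j], R[i])`,

   and inherits that stage's pseudotime. Cosine similarity is invariant
   to positive per-cell scaling, which makes the assignment robust to
   library-size and multiplicative batch effects; an optional cutoff on
   `S(j)` supports identity calling.

3. **Integration.** All cells (reference + transferred query) are binned
   into `P = 100` equal-width pseudotime partitions; partition-wise
   batch centering equalises batch means exactly within each partition,
   and a gene-wise z-scored partition trend matrix summarises the joint
   trajectory.

4. **Benchmark.** A negative-binomial step-path simulator generates
   two-batch mosaic datasets (stages 1–100; batch 1 covers windows
   1–20, 40–60, 80–100; batch 2 covers 30–35, 70–75) with tunable
   signal-to-noise ratio and nonlinear-trend proportion, and the
   harness scores stage recovery with
   `R^2 = 1 − Σ(y − ŷ)² / Σ(y − ȳ)²`.

## Worked example

Simulate a mosaic two-batch dataset, build the kernel from batch 1,
transfer batch 2, and score the recovery:

```r
library(scstalt)

cfg <- sim_config(snr = 0.2, nonlinear_prop = 0.3, seed = 42)
sim <- simulate_counts(cfg)
sim
#> SimulationDataset: 2000 genes x 3000 cells, 100 stages, batches: batch1/batch2 (snr 0.2, nonlinear 0.3)

expr <- log_normalize(sim$counts)
ref  <- names(sim$batch)[sim$batch == "batch1"]
qry  <- names(sim$batch)[sim$batch == "batch2"]

kernel <- build_kernel(subset_expression(expr, cells = ref),
                       true_pseudotime(sim$true_stage[ref], m = 100),
                       m = 100)
kernel
#> KernelProfile: 1436 dynamic genes x 100 stages (pseudotime 0..1)

qp  <- align_genes(subset_expression(expr, cells = qry), kernel)
res <- transfer_labels(qp, kernel)
head(res, 3)
#>      cell_id stage_index pseudotime similarity passed_cutoff
#> 1 cell_01501          72  0.7171717  0.9503730          TRUE
#> 2 cell_01502          74  0.7373737  0.9522142          TRUE
#> 3 cell_01503          36  0.3535354  0.9499828          TRUE

r2_score(true_pseudotime(sim$true_stage[qry], m = 100), res$pseudotime)
#> [1] 0.9824051
```

Batch 2 was simulated only in stage windows 30–35 and 70–75 — stages the
kernel never saw a query-batch cell for — yet its cells land in the
right windows (`cell_01503` at stage 36, the others in the low 70s) with
an overall R² of 0.98 against the simulated truth.

The same pipeline is available from the shell via the thin CLI
(`exec/stalt` in the installed package):

```sh
stalt simulate  --seed 1 --out sim/
stalt kernel    --counts sim/ --pseudotime ref_pt.tsv --stages 100 --out kernel.tsv
stalt transfer  --kernel kernel.tsv --query query/ --out transfer.tsv
stalt integrate --kernel kernel.tsv --ref sim/ --ref-pseudotime ref_pt.tsv --query query/ --out integrated/
stalt benchmark --snr 0.05,0.1,0.15,0.2,0.25 --nonlinear 0.1,0.2,0.3,0.4,0.5 --reps 10 --seed 1 --out report.json
```

Every subcommand writes a `manifest.json` recording its options, seed
and package version.

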