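# burstfeedback

Genome-wide inference of transcriptional burst kinetics and
auto-regulatory feedback from static single-cell RNA-seq UMI snapshots.

Most genes are transcribed in bursts: short bouts of mRNA production
(whose rate of occurrence is the **burst frequency** `a` and whose mean
yield is the **burst size** `b`) separated by silent intervals.  When the
gene product regulates its own promoter, the steady-state mRNA copy-number
distribution is reshaped: **negative feedback** compresses the upper tail,
**positive feedback** pushes mass toward a low-expression state plus a
high-expression state.  `burstfeedback` fits a mechanistic steady-state
model to per-gene UMI counts and decides, gene by gene, between no
feedback, negative feedback and positive feedback.

## Model

The latent copy number follows the stationary density

```
f(x) ∝ x^(a(1+ε)−1) · e^(−x/b) · (1 + (x/k)^h)^(−a/h)
```

where `ε` is the promoter leakiness (fixed at 0.05), `k` the binding
constant of the feedback loop and `h` the Hill coefficient (`h > 0`
negative feedback, `h < 0` positive feedback, `h = 0` none).  Counts are
observed through Binomial thinning with capture probability `λ` (default
0.5).  The observed-count pmf is evaluated by generalized Gauss–Laguerre
quadrature (closed negative-binomial form when `h = 0`), maximized by
multi-restart bounded L-BFGS-B per feedback form, and the form is chosen
by AICc (2 free parameters for `h = 0`, 4 otherwise).  A Monte-Carlo
chi-square test checks goodness of fit.

## Worked example

Simulate three genes with known kinetics, fit all three feedback forms,
and test goodness of fit:

```r
library(burstfeedback)

truth <- list(
  gene_none = KineticParams(5, 3),                  # no feedback
  gene_neg  = KineticParams(4, 10, k = 8, h = 4),   # negative feedback
  gene_pos  = KineticParams(4, 8,  k = 5, h = -4))  # positive feedback
se  <- simulateExperiment(truth, nCells = 1000, seed = 1)
res <- fitBurstKinetics(se, restarts = 10, gof = TRUE, gofReps = 300,
                        seed = 2)
res[, c("gene", "form", "a", "b", "k", "h", "gof_p", "gof_pass")]
#>        gene     form    a    b    k     h  gof_p gof_pass
#> 1 gene_none     none 5.63 2.68   NA  0.00 0.6146     TRUE
#> 2  gene_neg negative 4.68 9.23 7.55  4.36 0.8073     TRUE
#> 3  gene_pos positive 3.96 8.00 4.85 -5.57 0.0565     TRUE
```

All three genes recover their generating form and parameters.  Per-gene
objects carry the full selection detail:

```r
y   <- counts(sampleDataset(truth$gene_pos, nCells = 1000, seed = 3))
inf <- selectModel(fitGene(y, restarts = 10, seed = 4), gene = "gene_pos")
inf
#> GeneInference for gene_pos
#>   selected form: positive
#>   AICc: none=7400.49, negative=7404.51, positive=7219.02
#> KineticParams (positive feedback)
#>   burst frequency a = 3.677, burst size b = 8.804
#>   leakiness epsilon = 0.05, binding constant k = 4.49, Hill h = -5.456
```

Downstream statistics (model-based CV², residual CV², promoter-motif
regressions) live in `cv2AndRcv2()`, `burstStatsTable()` and
`regressionTvalues()`.  Real data enter through `loadUmiCsv()` and
`qcPipeline()`, which assembles two allelic UMI matrices into one
inference-ready `SummarizedExperiment`.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "burst-pipeline.R", package = "burstfeedback"))')" \
  fit --counts-file counts.csv --out results/ --seed 1
```

Commands: `qc`, `simulate`, `fit`, `gof`, `stats`, `robustness`.  Exit
codes: 0 success, 2 missing input, 3 invalid configuration.  Each run
writes a JSON manifest; identical configurations produce byte-identical
outputs.

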