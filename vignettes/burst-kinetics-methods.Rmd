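---
title: "Methods: burst kinetics and auto-regulatory feedback from UMI snapshots"
author: "burstfeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst kinetics and auto-regulatory feedback from UMI snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstfeedback)
```

## The model

Transcription proceeds in bursts arriving at frequency $a$ with
geometric-mean size $b$.  When the gene product feeds back on its own
promoter through a Hill-type interaction with binding constant $k$ and
coefficient $h$, the stationary density of the latent product abundance
$x$ is

$$
f(x) \;=\; N \, x^{a(1+\epsilon)-1} e^{-x/b}
  \left(1 + (x/k)^h\right)^{-a/h},
$$

with leakiness $\epsilon$ (fixed at $0.05$ throughout) and normalizer
$N$.  The three feedback forms are $h > 0$ (negative feedback,
suppressing abundance above $k$), $h < 0$ (positive feedback) and the
$h = 0$ limit (no feedback), where $f$ reduces to a Gamma density with
shape $a$ and scale $b$.  Molecule counts are Poisson given $x$, and
sequencing observes each molecule independently with capture probability
$\lambda$ (default $0.5$), which composes to Poisson with rate
$\lambda x$.  The observed-count pmf is therefore

$$
P(y) \;=\; \frac{\int_0^\infty \mathrm{Pois}(y \mid \lambda x) f(x)\,dx}
                {\int_0^\infty f(x)\,dx}.
$$

For $h = 0$ this integral is the negative binomial
$P(y) = \binom{y+a-1}{y} \left(\tfrac{b\lambda}{1+b\lambda}\right)^y
 \left(\tfrac{1}{1+b\lambda}\right)^{a}$, implemented in closed form
(`observedPmfNonfeedback()`); `modelMoments()` gives
$E[Y] = \lambda a b$ and $\mathrm{Var}[Y] = \lambda ab + \lambda^2 ab^2$.

## Numerical evaluation

Feedback forms are integrated with a generalized Gauss–Laguerre rule
(`gaussLaguerreRule()`), computed by the Golub–Welsch method with a
first-component-only implicit-shift QL iteration in C++ and cached per
$(\text{order}, \alpha)$.  After the change of variable
$t = x(\lambda + 1/b)$, one node set serves every count value $y$ and all
contributions are accumulated in log space.

The split between the quadrature weight $t^\alpha e^{-t}$ and the smooth
remainder depends on the sign of $h$:

* $h = 0$: $\alpha = a - 1$ (the Gamma kernel itself);
* $h > 0$: $\alpha = a(1+\epsilon) - 1$, smooth part
  $H(x) = (1 + (x/k)^h)^{-a/h}$;
* $h < 0$: the Hill factor diverges like $(x/k)^{-a}$ at the origin, so
  the kernel behaves as $x^{a\epsilon-1}$ there.  We therefore use
  $\alpha = a\epsilon - 1$ and fold the bounded remainder
  $G(x) = x^{a} H(x)$ into the smooth part.  Without this split the
  quadrature misses the near-origin singularity entirely (errors of
  order $10^{-1}$); with it, agreement with adaptive numerical
  integration is at the $10^{-9}$ level.

Positive feedback requires $\epsilon > 0$ for integrability, enforced by
the `KineticParams` validity check.

```{r pmf}
th <- KineticParams(4, 8, k = 5, h = -4)   # positive feedback
p <- observedPmf(th, lambda = 0.5)
head(round(p, 4), 10)
sum(p)
```

The default order is 200, chosen so that the pmf matches adaptive
integration to better than $10^{-7}$ across Hill coefficients
$|h| \le 5$; `observedPmf(..., check = TRUE)` re-evaluates at doubled
order and warns if any entry drifts.  **Known limit:** for very sharp
negative feedback ($h \gtrsim 6$) combined with wide kernels (large $b$,
small $k$), the Hill transition narrows to width $k/h$ and the fixed-order
rule loses accuracy; raise `order` in that regime.

## Inference

`fitGene()` maximizes the tabulated-count likelihood per feedback form
with bounded L-BFGS-B: $a \in (0.1, 30)$, $b \in (1, 20)$,
$k \in (1, 1000)$ (optimized on the $\log_{10}$ scale),
$h \in (1, 10)$ or $(-10, -1)$.  The first restart starts from the
method-of-moments inversion $a_0 = m^2/(v - m)$,
$b_0 = (v/m - 1)/\lambda$; later restarts (default 30) jitter $a_0, b_0$
by $\times U(0.8, 1.2)$ and redraw $h_0$ and $k_0$.  Fits ending within
$10^{-3}$ of a bound (normalized coordinates) are flagged and excluded
from selection, as are optimizer failures.

`selectModel()` compares the per-form minima by
$AICc = -2\log L + 2p + 2p(p+1)/(n-p-1)$ with $p = 2$ free parameters for
the non-feedback model and $p = 4$ otherwise; exact ties break toward the
simpler form.  `gofTest()` checks the selected fit with a Monte-Carlo
chi-square test: per-count categories with the sparse upper tail pooled
(model mass below $10^{-6}$ per count), null distribution simulated from
the fitted model, add-one-smoothed empirical p-value, pass at
$p \ge 0.05$.

```{r fit}
y <- counts(sampleDataset(th, nCells = 1000, seed = 3))
inf <- selectModel(fitGene(y, restarts = 10, seed = 4), gene = "demo")
inf
```

## Synthetic data and validation

`sampleDataset()` draws cells directly from the truncated observed-count
pmf (tail mass $10^{-8}$), so generator and likelihood agree by
construction; `applyDropout()` composes an extra per-molecule Binomial
loss, equivalent to lowering $\lambda$.  Recovery is scored by the
squared log-scale error
$(\log_{10} a_t - \log_{10} \hat a)^2 +
 (\log_{10} b_t - \log_{10} \hat b)^2$ (`recoveryError()`; base 10).

`robustnessSuite()` runs the full simulate–fit–select loop over a
parameter grid, cell numbers and dropout levels.  The packaged validation
uses a six-point grid — two non-feedback parameter sets, two negative
((4, 10, k = 8, h = 4), (6, 6, k = 10, h = 3)) and two positive
((4, 8, k = 5, h = −4), (3, 6, k = 4, h = −3)) — at 200, 500 and 2000
cells.  These problem sizes are the package's own choice: median recovery
error is well below 0.5 at 2000 cells and decreases with cell number.

**Identifiability note.**  Feedback is only detectable when the Hill
factor visibly reshapes the pmf, which requires $|h| \ge 2$ *and* a
binding constant below the expression scale $ab$.  With $k \approx ab$
the feedback pmf is within a few $10^{-3}$ pointwise of a negative
binomial, and no selector can distinguish the forms from snapshot data
— AICc then correctly prefers the 2-parameter model.  The generator is
deliberately minimal: no amplification noise, batch effects or
cell-cycle structure.

## Quality control and downstream statistics

`qcPipeline()` assembles two allelic UMI matrices: per allele it drops
genes expressed in fewer than `minCells` cells, cells expressing fewer
than `minGenes` genes, and genes with mean count below `minMean` (one
pass, in that order); genes surviving both alleles are kept and the
alleles' cells concatenated.  Per gene, counts strictly above the
empirical $1 - q$ quantile are masked via a logical `"keep"` assay so
they are excluded from that gene's fit only.

`cv2AndRcv2()` computes model-based $CV^2 = \mathrm{Var}/E^2$ and the
expression-level-corrected residual $rCV^2 = CV^2 - 1/\log_2 \mu$
(undefined at $\mu \le 1$).  `regressionTvalues()` fits
`response ~ (TATA * Inr + CCAAT * GC) * feedback` by OLS and reports
coefficient t-values, flagging rank-deficient terms instead of dropping
them silently.

## Reproducibility

Every stochastic function accepts a seed and restores the caller's RNG
state; per-task seeds derive deterministically from a master seed, so
`runBurstPipeline()` runs are byte-identical given the same
configuration.  The package-wide defaults ($\lambda = 0.5$,
$\epsilon = 0.05$, 30 restarts, 1000 goodness-of-fit replicates) are the
full-fidelity protocol; `defaultConfig()` uses lighter settings (10
restarts, 200 replicates) for routine runs.
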