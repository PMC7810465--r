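---
title: "Methods: cross-species staging of bulk transcriptomes on an endotoxemia timeline"
author: "sepstager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species staging on an endotoxemia timeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepstager)
```

## The model

`sepstager` implements a reference-based staging procedure. A murine
endotoxemia (LPS) single-cell time course — kidneys sampled at 0, 1, 4, 16,
27, 36 and 48 hr — serves as a molecular clock. For each time point $t$ a
*signature* is derived: the genes differentially expressed in $t$'s cells
versus all other cells (one-vs-rest), together with their log2 fold
changes. A bulk query sample (e.g. a human sepsis-AKI biopsy) is summarized
as a gene-wise log2 fold-change vector against the mean of reference
(unaffected) samples, and the sample is assigned the time point whose
signature fold changes it tracks best, measured by Spearman's $\rho$ over
the signature genes. The key assumptions are:

* counts are adequately described by a negative-binomial (gamma-Poisson)
  model, $\mathrm{Var}(y) = \mu + \phi\mu^2$;
* between-library composition differences are removable by trimmed-mean
  (TMM) normalization;
* the rank pattern of a time point's signature fold changes is conserved
  across species and platform once genes are translated to one-to-one
  orthologues — the magnitudes need not transfer, which is why a rank
  correlation is the staging statistic;
* reference samples are exchangeable with the baseline (time-0) state of
  the model organ.

## The differential-expression engine

The engine is intentionally transparent: every step is a closed-form
computation validated against independent brute-force oracles in the test
suite, rather than a wrapper around an external tool.

**TMM factors.** For column $k$ against a reference column $r$ (the column
whose upper-quartile expression is closest to the mean upper quartile),
gene-wise $M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$ values are doubly
trimmed — 30% from each tail of $M$ and 5% from each tail of the average
abundance — and combined by a precision-weighted mean, with inverse
delta-method variances as weights. Factors are rescaled to geometric mean
1 (enforced to 1e-9 in tests). If trimming removes every gene the function
stops and suggests smaller trims.

**Dispersion.** Counts are rescaled to a common effective library size;
within each group with $\ge 2$ replicates the method-of-moments estimate
$\hat\phi_g = (v_g - \bar{c}\,m_g)/m_g^2$ is formed (the $\bar{c}\,m_g$
term is the depth-corrected Poisson expectation), pooled across groups by
residual degrees of freedom. The *common* dispersion is a 10% trimmed mean
of the raw estimates, floored at zero only after averaging: flooring each
gene first would turn symmetric estimation noise into a positive bias and
an inflated common value under Poisson-like data. Tagwise values are then
floored and shrunk, $\phi_g = (1-w)\max(\hat\phi_g,0) + w\,\phi_{\rm
common}$ with $w = 0.3$ by default — enough pooling to stabilize
gene-level Wald variances without masking genuine heterogeneity. Without
replicates anywhere the engine falls back to a fixed dispersion (default
0.1, configurable) with a warning.

**Wald test.** Group rates are estimated as $\hat{r} = \sum y / \sum L$
(effective library sizes as offsets) and the statistic is
$z = (\log\hat{r}_1 - \log\hat{r}_0)\big/\sqrt{1/Y_1 + \phi S_1/L_1^2 +
1/Y_0 + \phi S_0/L_0^2}$ with $S = \sum L_i^2$. The statistic uses the
*unshrunk* rates: a prior enters it only when a group total is zero (where
the raw log-rate is undefined). Testing shrunk rates against unshrunk
variances attenuates $z$ and makes the test conservative; keeping them
separate holds the empirical type-I error at the nominal level (0.05
within [0.03, 0.07] across null simulations). Genes with zero counts
everywhere are excluded and reported with $p = 1$, $\log_2\mathrm{FC} =
0$.

**Fold changes and the prior.** Reported fold changes are
$\log_2\frac{\mathrm{CPM}_1 + 0.5}{\mathrm{CPM}_0 + 0.5}$: the prior count
of 0.5 lives on the depth-normalized (per-million) scale, i.e. 0.5 per
library-size-scaled column. Placing it on the raw-count scale would
aggregate to hundreds of pseudo-counts across a 300-cell group and shrink
true effects of weakly expressed genes by several tenths of a log2 unit;
on the CPM scale it only guards against zeros. Significance uses the
Benjamini–Hochberg step-up with a *strict* threshold (FDR < 0.05; a gene at
exactly 0.05 is excluded).

## Staging choices

* **Cells as replicates.** Time-point signatures are computed treating the
  2000 subsampled cells per time point as replicates in the one-vs-rest
  contrast. A single-pseudobulk-per-condition alternative exists in the
  concordance branch (with the fixed fallback dispersion, since one column
  per condition has no replicates); cells-as-replicates is the default for
  staging because it retains within-time-point variance information.
* **Per-time-point gene sets.** Each correlation $\rho(s, t)$ uses only
  time point $t$'s signature genes (intersected with the query universe),
  not the union across time points: the signature is the unit of meaning,
  and unions let large signatures dominate small ones.
* **Orthologue collisions.** Only one-to-one mouse-human pairs are kept;
  one-to-many and many-to-one pairs are dropped (and counted). Keeping an
  arbitrary member would inject duplicated fold-change values with no
  principled ordering.
* **Tie-breaks and degenerate cells.** The argmax over time points breaks
  ties toward the earliest hour (deterministic, and the clinically
  conservative call). Correlations over fewer than `min_genes = 10`
  overlapping genes, or against a constant vector, are NaN with a warning
  and excluded from the argmax; Spearman on a handful of pairs is too
  unstable to rank stages.
* **Coarse labels.** early = {0, 1, 4}, mid = {16}, late = {27, 36, 48} hr.
  The 16-hr point sits at the transition between the injury and recovery
  phases of the endotoxemia trajectory, so it forms the "mid" class by
  itself. This mapping is a declared convention of the package and is
  configurable (`stage_map`).
* **Severity test.** Stage-severity association uses Spearman's $\rho$
  with a seeded permutation $p$-value (default 10,000 permutations, +1
  correction, two-sided) rather than the large-sample approximation:
  biopsy cohorts can be as small as ~20 samples, and assigned stage ranks
  are heavily tied.

## The concordance branch

Pairwise one-vs-one NB tests between condition columns feed FDR-sorted
gene lists, split by fold-change sign and truncated to the top
`k = 500`. FDR ties are broken by $|\log_2\mathrm{FC}|$ descending, then
gene id — "sorted by FDR" alone is not a total order, and determinism
requires one. The Jaccard matrix over these lists is ordered by
complete-linkage clustering implemented directly (naive $O(n^3)$ over at
most a few dozen comparisons; transparency over speed), with equidistant
merges resolved lexicographically by comparison id. The Jaccard index of
two empty lists is defined as 1 with a warning: the comparison is vacuous,
not discordant. Probe-to-gene harmonization keeps, per gene name, the
probe with the highest total counts, a stated convention where only
"discard non-matches" is canonical.

## What the generator emulates — and what it does not

`simulate_timecourse()` draws gamma-Poisson counts with log-normal gene
baselines, log-normal library sizes (sdlog 0.3, enough depth variation to
exercise normalization), per-cell mitochondrial fractions carried by
`mt-`-prefixed genes so QC covariates agree with the matrix, and disjoint
planted signature programs (default 40 genes per time point at log2 fold
change 3, dispersion 0.1). Signature mass is renormalized per cell, so the
planted programs induce the mild compositional shift TMM must absorb.
Defaults (2000 genes, 300 cells per time point) are the desk-scale study
used throughout the tests; the real tissue sizes (5,165–11,809 cells per
time point, 63,287 in total; `recovered_cell_counts()`) are an order of
magnitude larger.

`simulate_query_bulk()` draws bulk queries *directly* from a chosen time
point's expected expression program on the orthologue-mapped gene universe
(multiplicative log-normal noise, then Poisson counting noise) — queries
are independent bulk libraries, not sums of cells, mirroring how biopsy
libraries are generated. References are drawn from the baseline (time-0)
program. Query stages default to the six post-baseline time points: a
baseline query is, by construction, distributionally identical to the
references, its fold-change vector is pure noise around zero, and no
rank-correlation method can stage it — it is an unidentifiable case, not a
hard one. `simulate_severity()` plants
$\mathrm{SOFA} = \mathrm{clamp}(\mathrm{round}(20 - 2\,\mathrm{rank} +
\varepsilon), 0, 24)$ by default, the "later stage, lower severity"
pattern.

The generator does **not** emulate: cell-type structure beyond a nominal
label (no differential composition over time), batch or platform effects
between species, ambient RNA or doublets, gene-gene correlation, or
zero-inflation beyond what the NB produces. Passing tests therefore show
that the pipeline recovers planted structure under its own model
assumptions at realistic noise levels — not that it is robust to every
artefact of real cross-species data.

## Determinism and numerics

Every randomized operation routes through a helper that fixes the RNG
family (Mersenne-Twister, "Rejection" sampling) and restores the caller's
RNG state, so results are bit-reproducible from `(inputs, seed)` and
functions never perturb the session RNG. Pipeline artifacts round floats
to 6 decimals in TSVs and the JSON report carries no timestamps, making
two runs with the same config byte-identical. Oracle agreement is enforced
in tests to 1e-9 (Spearman, BH, Jaccard, cophenetic heights) and 1e-6
(TMM, against both a direct-summation oracle and `edgeR::calcNormFactors`).

Problem sizes in the test suite were chosen as the smallest at which the
statistical properties under test are comfortably away from their
thresholds: the standard 2000 × 2100 study for acceptance-level checks,
600-gene / 80-cell bundles for pipeline mechanics, and 10 null replicates
for calibration.

## Known limitations

* Stage assignment is a hard argmax; samples between two adjacent
  biological states receive a single label (with the tie going early) and
  no mixture weight.
* The Wald test relies on large aggregate counts per group; with very few
  cells and very low expression its normal approximation weakens, which is
  why all-zero and near-zero genes are handled separately.
* One-to-one orthologue filtering discards genuinely informative
  one-to-many families (e.g. duplicated immune genes).
* The severity permutation test conditions on the assigned stages; it does
  not propagate staging uncertainty.
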