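---
title: "Methods: network guilt-by-association and the MIAS immunoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network guilt-by-association and the MIAS immunoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmias)
```

## The problem

Only a minority of patients respond to anti-PD-1 checkpoint blockade, and
response depends on tumor cells presenting antigen through the MHC class I
pathway to infiltrating T cells. `netmias` asks, for every gene in a large
protein interaction network, "how functionally close is this gene to the
MHC class I antigen-presentation machinery?", and then converts that
network evidence, together with tumor expression data, into a per-sample
immunoscore (the MIAS) that predicts response.

## Association scores by random walk with restart

Given an undirected gene network with column-normalized adjacency
(transition) matrix $W$ and a seed set of MHC class I pathway genes, the
walk iterates

$$p_{t+1} = (1-\gamma)\, W p_t + \gamma\, p_0,$$

where $p_0$ places equal mass on each seed and $\gamma$ is the restart
probability. The stationary vector is the per-gene association score.
Numerical choices:

* **Restart probability** $\gamma$: default 0.5, a mandatory, recorded
  parameter. Propagation results are rank-stable over a broad range of
  $\gamma$; 0.5 balances local and global network structure.
* **Convergence**: the iteration stops when the $L_1$ change between
  successive vectors falls below `tol` ($10^{-10}$ by default, well inside
  double precision; at most 10,000 iterations, then an error reporting the
  last residual). The fixed point equals the direct linear solve
  $\gamma (I - (1-\gamma) W)^{-1} p_0$, which the test suite verifies to
  $10^{-8}$ on random graphs.
* **Degree-0 nodes** keep an all-zero transition column: they receive only
  restart-injected mass when seeded (stationary score $\gamma$) and 0
  otherwise, and they are listed in a warning. Total mass is conserved
  exactly when no such sinks exist.
* **Seed set**: the default `default_mhc_seeds()` is
  HLA-A/HLA-B/HLA-C plus PDCD1 and CD274. Genes that the method is
  expected to *discover* (TAP1, B2M, ...) are deliberately not seeds.
  The seed set is fully configurable and recorded in every manifest.

Centrality baselines (degree, betweenness, eigenvector) are provided for
comparison; betweenness sums each unordered pair once (a global constant
relative to the ordered-pair convention, leaving all rankings unchanged),
and eigenvector centrality is computed on the largest connected component
with a deterministic dense solve below 500 nodes and all-ones-started
power iteration above.

## Pathway evidence: GSEA and the truncated product

Two lines of pathway evidence are combined. The *association* analysis
runs preranked GSEA on the association-ranked gene list; the
*deregulation* analysis ranks genes by the signal-to-noise ratio between
responders and non-responders (each group SD floored at $0.2\,|\mu|$) and
applies the same running-sum statistic. The enrichment score is the
classic weighted Kolmogorov–Smirnov extremum (hit weight
$|s|^{\alpha}$ with $\alpha = 1$ by default; $\alpha = 0$ gives the
rank-only statistic, invariant under monotone score transforms).

Because the association input is a single ranking, phenotype permutation
is impossible; both analyses therefore use gene-label permutation, flagged
in the output metadata. Each gene set draws its permutations from its own
seeded substream so that p-values are independent across sets; the nominal
p-value is the same-sign tail fraction with add-one smoothing, and NES
divides the observed ES by the mean |ES| of same-sign permutations.
Sets with ranked-universe overlap outside [5, 2000] are skipped with a
message.

The two p-values are combined with the two-test truncated product: the
statistic is $w = \prod_i p_i^{I(p_i \le \tau)}$ (default $\tau = 0.01$),
whose null tail probability is evaluated analytically by conditioning on
how many p-values fall below $\tau$. At $\tau = 1$ this reduces to
Fisher's two-test closed form $w(1 - \ln w)$. The combined p-value has an
atom at 1 of null mass $(1-\tau)^2$ — it is exactly uniform only below
$1-(1-\tau)^2$ and conservative above, which is the intended behavior of
a truncation test. The uniformity check in the test suite therefore uses
$\tau = 0.25$, where the 5% level lies inside the uniform range; the
default $\tau = 0.01$ is kept for analysis, where only very small
combined p-values are of interest.

## From association to the MIAS signature

For each cancer type, per-gene immune correlation is computed against an
externally supplied immune-infiltration score (e.g. ESTIMATE; this package
never computes it). Spearman correlation is the default — it is robust to
expression skew and consistent with the rank statistics used elsewhere in
the pipeline — with Pearson available by flag; counts/TPM input is
quantile-normalized across samples first (skipped for pre-normalized
input), and the path taken is recorded.

Immune-positive and immune-negative gene sets are the top 10% of the
association ranking filtered at $|\rho| \ge 0.2$. The response signature
merges the association rank $r1_g$ and the immune-correlation rank
$r2_g$ by the rank product

$$MR_g = \sqrt{r1_g \times r2_g},$$

keeping the 100 smallest $MR_g$ (boundary ties broken lexicographically
for determinism). The MIAS of a sample is the ssGSEA normalized
enrichment score of the signature in that sample's expression profile:
genes are ranked within the sample, the weighted ECDF difference is summed
over all list positions (weight $\mathrm{rank}^{0.25}$, the cited ssGSEA
convention), and raw scores are normalized across the scored cohort by
their range. Raw scores depend only on within-sample ranks, so any
monotone per-sample transform (including TPM vs log-TPM) leaves them
unchanged. Cross-platform comparisons should restrict the universe to the
genes shared by all platforms (`universe` argument of `mias_score()`);
the universe used is written to the run manifest.

Copy-number states use the printed strict thresholds (log2 ratio > 0.5
gain, < −0.5 loss, boundaries neutral); "recurrently altered" defaults to
3 or more altered samples per alteration type (no published threshold
exists, so the value is configurable and recorded). Drug–target tables
are joined against the immune-negative set only: genes whose high
expression tracks low infiltration are the candidate targets for
combination therapy.

## What the synthetic generators emulate

The generators replace the external network and cohort data with planted
ground truth:

* `simulate_network()` — a preferential-attachment backbone (1000 genes,
  3 edges per node by default) plus a planted 50-gene module with
  within-module edge probability 0.6 containing the 5 seed genes. This
  emulates the community structure that guilt-by-association exploits.
* `simulate_expression_cohort()` — a latent per-sample immune axis
  $z \sim N(0,1)$; immune-positive genes get log-expression
  $a z + \varepsilon$ with $a$ set so the population correlation is
  `rho_target` (default 0.5, a typical magnitude for strongly
  immune-tracking genes); negative genes use $-a$; everything else is
  independent log-normal noise (downstream steps are rank-based and real
  pipelines quantile-normalize, so the marginal shape is inert).
* `simulate_response_cohort()` — signature genes shifted by `effect_sd`
  (default 1.5) SD in responders, 30/30 samples by default.
* `simulate_study()` — the composition used for end-to-end validation:
  1500 genes, a 250-gene module, 250 immune-positive genes, and a
  100-gene intersection (excluding seeds) that is the true signature.
  The deliberate partial overlap means neither network proximity nor
  immune correlation alone identifies the signature — the situation the
  rank product is designed for. Under these conditions the rank product
  recovers about two thirds of the planted signature, and ablating either
  evidence channel (shuffling correlations, or shuffling association
  scores) measurably degrades the response AUC. The ablation comparison
  uses a 0.75 SD planted effect so that scores are off the AUC ceiling
  and differences between scenarios are visible.

What the generators do **not** model: dropout and batch structure,
correlated co-expression modules beyond the single immune axis, realistic
mutational processes, or copy-number segmentation. Passing tests
demonstrate the algorithms are implemented correctly and recover planted
structure under fair noise — not that the biological signal in any real
cohort is of comparable strength.

## Problem sizes and determinism

All simulation-based checks run at desk scale: networks of 1000–1500
nodes, cohorts of 60–200 samples, 200 random gene sets at 1000
permutations, $10^5$ Monte Carlo pairs for the truncated product. Every
stochastic step takes an explicit integer seed, generators are pure
functions of their parameters and seed, and permutation p-values are
bit-for-bit reproducible; pipeline runs write a JSON manifest (parameters,
input checksums, package version) sufficient to reproduce the run.

## Known limitations

* Unweighted, undirected networks only; identifier harmonization across
  resources is the caller's responsibility (identifiers are opaque,
  case-sensitive strings).
* Nominal GSEA p-values only — no FDR across gene sets, matching the way
  the combined pathway evidence is meant to be screened, not inferred on.
* The deregulation analysis uses gene-label permutation; with very small
  cohorts a phenotype permutation would be preferable but is typically
  infeasible at the cohort sizes this method targets.
* ssGSEA range normalization makes the NES cohort-relative: MIAS values
  are comparable within a scored cohort, not across cohorts scored
  separately.
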