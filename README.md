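# netmias

Network guilt-by-association prediction of genes, pathways and a
per-sample immunoscore (MIAS) for anti-PD-1 immunotherapy response.

## What it does, and for whom

Tumors evade T-cell killing by degrading MHC class I antigen
presentation, and genes functionally coupled to that pathway shape
response to PD-1/PD-L1 checkpoint blockade. `netmias` is for
computational biologists who have a gene interaction network, tumor
expression cohorts and immune-infiltration scores, and want to:

1. score every gene's association with the MHC class I pathway by
   **random walk with restart** from a seed set
   (HLA-A/-B/-C, PDCD1, CD274 by default),

   p<sub>t+1</sub> = (1 − γ) W p<sub>t</sub> + γ p<sub>0</sub>,

   with W the column-normalized adjacency matrix and γ the restart
   probability (default 0.5);
2. find response-associated **pathways** by combining preranked GSEA on
   the association ranking with two-group GSEA deregulation evidence via
   the truncated product method, w = ∏ p<sub>i</sub><sup>I(p<sub>i</sub> ≤ τ)</sup>,
   with an analytic null tail;
3. select **immune-positive / immune-negative** associated genes (top
   decile of the ranking, |ρ| ≥ 0.2 against an immune-infiltration
   score) and flag recurrently altered or druggable ones;
4. build the 100-gene **MIAS signature** by rank product,
   MR<sub>g</sub> = √(r1<sub>g</sub> · r2<sub>g</sub>), of association
   rank and immune-correlation rank, and score each sample's **MIAS**
   as the ssGSEA normalized enrichment score of that signature — higher
   MIAS predicts response;
5. evaluate predictions with ROC/AUC, one-sided Wilcoxon–Mann–Whitney,
   hypergeometric overlap and Spearman agreement.

Centrality baselines (degree, betweenness, eigenvector), TPM conversion,
rank-product integration of multiple predictors, and synthetic-data
generators with planted ground truth are included. Immune-infiltration
scores (e.g. ESTIMATE) are consumed as input, never computed.

## Worked example

A fully synthetic study with planted truth: a 1500-gene scale-free
network with a 250-gene module around the seeds, an expression cohort
with a latent immune axis, and a 100-gene true signature at the
module × immune-positive intersection.

```r
library(netmias)

st  <- simulate_study(rng_seed = 1)
rwr <- random_walk_with_restart(column_normalize(st$network), st$seeds)
rwr
#> association_scores: 1500 genes, gamma = 0.5, converged in 24 iterations (L1 residual 6.35e-11)

ranked <- rank_and_percentile(rwr)
head(ranked, 3)
#>     gene     score rank percentile
#> 1 g00131 0.1028277    1 0.06666667
#> 2 g01349 0.1022635    2 0.13333333
#> 3 g00272 0.1021473    3 0.20000000

corr <- immune_correlation(st$expr, st$immune)   # Spearman by default
sig  <- select_mias_signature(ranked, corr, n_signature = 100)
head(sig, 3)
#>     gene  r1 r2       mr
#> 1 g00792  25  6 12.24745
#> 2 g00199 160  2 17.88854
#> 3 g01019  23 16 19.18333
sum(sig$gene %in% st$truth$signature_genes)
#> [1] 61
```

The top association scores (~0.10) are the stationary probabilities of
the restart walk: module genes soak up most of the non-restart mass.
Each signature row shows the two merged ranks — g00792 is 25th by
network association and 6th by immune correlation, giving the best rank
product — and 61 of the 100 selected genes are truly planted.

Scoring a treated cohort in which the true signature is up-shifted by
1.5 SD in responders:

```r
rc <- simulate_response_cohort(st$truth$signature_genes,
                               effect_sd = 1.5, rng_seed = 2)
m    <- mias_score(rc$expr, sig)
resp <- rc$labels$response[match(m$sample, rc$labels$sample)] == "response"
roc_auc(m$mias, resp)
#> roc_result: AUC = 1.0000 (61 points)
mw <- mann_whitney_one_sided(m$mias[resp], m$mias[!resp])
sprintf("U = %.0f, one-sided p = %.3g", mw$u, mw$p)
#> [1] "U = 900, one-sided p = 1.51e-11"
```

A command-line wrapper over the same functions is installed at
`inst/cli/netmias.R` (`associate`, `centrality`, `gsea`, `combine-p`,
`ssgsea`, `select`, `mias`, `evaluate`, `overlap`, `simulate`, `run`);
`run_pipeline()` executes the whole chain from a YAML config and writes
per-stage TSVs plus a JSON run manifest.

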