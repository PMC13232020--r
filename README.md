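# TcellTrails

Reconstruction and statistical validation of putative **T cell migration
trails** on 10x Visium / Visium HD spatial transcriptomics slides.

Tumor-infiltrating T cells become progressively exhausted as they advance
through the tumor microenvironment. On a spatial slide this leaves a
signature: chains of adjacent T-cell-containing spots whose exhaustion
state increases along the chain. TcellTrails finds those chains and tests
whether they behave like genuine migration routes, for anyone analyzing
tumor spatial transcriptomics with an interest in immune-cell trafficking.

## The method in brief

For T-cell-infiltrated spots (raw detection of CD8A/CD8B/CD4/CD3D/CD3E/CD3G),
the **exhaustion score** of spot *i* is the shifted residual of

&nbsp;&nbsp;&nbsp;&nbsp;`Σ exhaustion-marker expression_i  =  α + β · Σ T-marker expression_i + ε_i`

(markers PDCD1, LAG3, HAVCR2, TIGIT, CTLA4, ENTPD1, TOX), i.e. exhaustion
controlled for T-cell content, with min z = 0. A **directed graph** connects
spots closer than 130 µm from lower to higher z with weight `z_v − z_u`.
Candidate trails between low-z starts and high-z ends (33% quantiles) come
from (1) Dijkstra's minimum-weight spanning path and (2) nodes close to a
straight line in (x, y, z) after rescaling xy onto the z range, ordered by
projection. Trails need ≥ 6 nodes and ≥ 500 µm span. A trail is **final**
when the mean pairwise correlation of its spots' T-stage-gene expression
beats all of its own 5–15 sampled alternative routes and the 85th percentile
of all alternatives pooled. Validation compares trails against **matched
control sets** (same length, same expression cluster, same adjacency/span
constraints; 5,000 sets by default): mixed-effects chemokine gradients along
the trail index, empirical differential expression with BH-FDR, shared
TCR/BCR variable genes between consecutive spots, Fisher enrichment, and
phenotype ranking against single-cell cluster means.

A seeded synthetic-slide generator with planted ground-truth trails
(`simulateDataset`) makes the whole pipeline testable offline.

## Worked example

```r
library(TcellTrails)

sim <- simulateDataset(synthConfig(seed = 5))   # 30x30 hex slide, 5 planted trails
res <- runPipeline(sim$dataset,
                   trailsConfig(nControlSets = 100, nVariableGenes = 100,
                                seed = 5),
                   outDir = "run1", verbose = FALSE)

length(res$trails)
#> [1] 29
res$trails[[1]]
#> Trail [dijkstra]: 8 nodes, span 770 um, z 0 -> 228000
head(res$trend, 4)
#>      gene_set   beta    se          p n_obs n_trails sd_trail sd_resid method
#> 1 cxcl9_10_11 186.11 15.03  3.165e-35   196       29   250.36    419.1 lmm_ml
#> 2      ccl4_5 148.94 12.18  2.139e-34   196       29    90.18    342.9 lmm_ml
#> 3      cxcl16  70.26 10.49  2.136e-11   196       29    71.53    295.7 lmm_ml
#> 4  macrophage 297.80 13.65 1.525e-105   196       29   256.14    380.2 lmm_ml
```

The printed trail is an ordered chain of 8 adjacent spots whose exhaustion
score rises from 0 to 228,000 (TPM-scale residual units). The 29 final
trails are overlapping variants tracing the 5 planted corridors. The trend
table says CXCL9/10/11 expression climbs by ~186 TPM per index step along
the trails (mixed-model Wald p ≈ 3e-35) — the planted chemokine gradient
is detected, as are the CCL4/5, CXCL16 and macrophage-marker gradients.
`run1/` receives the trail tables, DE table, trend tests and a JSON
manifest; a rerun with the same config and seed is byte-identical.

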