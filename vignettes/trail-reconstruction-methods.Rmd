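---
title: "Reconstructing T cell migration trails on spatial transcriptomics slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing T cell migration trails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TcellTrails)
```

## The problem and the model

Tumor-infiltrating T cells do not appear in the tumor bed at random: they
enter through vessels, move along remodeled collagen tracks, and become
progressively exhausted as they advance through the tumor
microenvironment. A spatial transcriptomics slide captures a snapshot of
this process. TcellTrails reconstructs *putative migration trails* — ordered
chains of adjacent T-cell-containing capture spots along which the
exhaustion state of the T cells increases — and then asks, statistically,
whether those chains behave like genuine migration routes.

The core quantities are:

* **T spots.** A spot is T-cell infiltrated when it has at least one raw
  transcript (configurable threshold) summed over the surface markers CD8A,
  CD8B, CD4, CD3D, CD3E, CD3G.

* **Exhaustion score `z`.** Across T spots, the sum of exhaustion-marker
  expression (PDCD1, LAG3, HAVCR2, TIGIT, CTLA4, ENTPD1, TOX) is regressed
  by ordinary least squares on the sum of T-marker expression; the score is
  the residual, shifted so that its minimum is 0. The regression controls
  for the *number* of T cells in a spot, so `z` reflects their exhaustion
  *state*. We compute both sums on TPM-normalized expression by default so
  that sequencing depth is controlled as well; raw-count sums are available
  (`use = "counts"`). This was left open in the original description of the
  method; normalized sums make scores comparable across spots of very
  different depth, which matters on sparse slides.

* **The ascent graph.** Nodes are T spots (or, on Visium HD, groups of
  adjacent pixels with similar scores; see below). Edges connect nodes
  closer than 130 µm in 2D — on the standard hexagonal 110 µm lattice this
  is exactly the 6 neighbors — oriented from lower to higher `z`, with
  weight `z_v − z_u`. Score ties are oriented from the smaller to the
  larger node id; this keeps the graph acyclic and the search
  deterministic.

* **Trails.** Between candidate endpoints (the lowest-scoring 33% of nodes
  as starts, the highest 33% as ends), trails are found two ways:
  1. *Minimum-weight spanning path*: Dijkstra's algorithm over the edge
     weights, preferring routes whose exhaustion increases gradually.
     Because the weights are score differences, every admissible route
     between the same endpoints telescopes to the same total weight
     `z_end − z_start`; the deterministic tie-break (fewer nodes, then
     smaller node ids) therefore selects the most direct of the tied
     routes. This is a property of the weight definition itself and is
     verified against exhaustive path enumeration in the tests.
  2. *Line in 3D space*: after rescaling x and y affinely onto the range of
     `z`, nodes within a small perpendicular distance of the 3D segment
     joining a start and an end are collected and ordered by their scalar
     projection, starting from the low-score end. This relaxes strict
     monotonicity: small score fluctuations are tolerated, large
     "drawbacks" between consecutive nodes are not.

  Trails shorter than 6 nodes or spanning less than 500 µm start-to-end
  are discarded; start/end pairs closer than 500 µm are pruned before the
  search, which changes nothing and saves most of the work.

* **Trail selection.** For each candidate trail, 5–15 *alternative routes*
  between the same endpoints are sampled by self-avoiding random walks on
  the undirected T-node graph (no requirement on the score direction; all
  other trail constraints apply). A candidate is kept only if the mean
  pairwise Pearson correlation of its nodes' stage-gene expression exceeds
  (a) that of every one of its own alternatives and (b) the 85th percentile
  of all alternatives pooled. Stage genes are the candidate T-state markers
  significantly positively correlated with T-marker load in the data at
  hand. The intuition: a stream of cells moving down one physical corridor
  is phenotypically more coherent than an arbitrary same-endpoint path.

* **Matched controls.** Spots are clustered on 3,000 variable genes (PCA +
  k-means, 6 clusters by default), and for each final trail one control
  trail of the same length is sampled inside the trail's majority cluster,
  subject to the same adjacency / T-spot / ≥ 0.5 mm-span constraints. One
  control per trail forms a control set; 5,000 sets form the permutation
  null for every downstream statistic (empirical two-sided p-values on the
  plain-proportion convention, so p = 0 is attainable; the
  `(count+1)/(n+1)` variant is available).

## Downstream statistics

* **Gradient trend tests** (`trendTest`): summed normalized expression of a
  chemokine panel (CXCL9/10/11; CCL4/5; CXCL16; macrophage markers CD68,
  CD163, CD80, CD14) is modeled against the 1-based spot index along each
  trail with a random intercept per trail, fitted by maximum likelihood
  (lme4) with a two-sided Wald test on the slope. Singular fits fall back
  to per-trail OLS slopes with a one-sample t-test, and the output records
  which path was taken.

* **Empirical differential expression** (`deTest`): per gene, mean
  normalized expression over on-trail spots versus the distribution of the
  same statistic over control sets; BH adjustment across genes; a gene is
  called up at FDR < 0.05 and fold change > 1.2, where the fold-change
  denominator is the mean of the per-set null means.

* **Shared TCR/BCR variable genes** (`sharedVgeneTest`): a variable gene
  (TRAV/TRAJ/TRBV patterns for TCR; IGHV/IGKV/IGLV for BCR) is *shared* by
  a consecutive spot pair when it is detected (raw count > 0) in both.
  Detection rather than magnitude makes the statistic robust to depth. Per
  trail the consecutive-pair counts are averaged; the median across trails
  is compared with the control-set null.

* **Over-representation** (`oraFisher`): one-sided Fisher exact enrichment
  of the upregulated genes in GMT gene sets over the variable-gene
  universe, computed as the hypergeometric upper tail, BH-adjusted.

* **Phenotype ranking** (`phenotypeRank`): given a cluster-by-gene table of
  mean expression from an annotated single-cell reference, each
  upregulated gene's cluster means are ranked ascending (ties share the
  average rank); clusters are summarized and ordered by their median rank,
  the top cluster being the best guess for the migrating phenotype. The
  package consumes any such table; re-clustering a single-cell atlas is
  out of scope.

## Visium HD

HD pixels are far smaller and sparser than standard spots. After per-pixel
scoring, `hdAggregate` grows nodes greedily: an unassigned seed pixel
absorbs the unassigned pixels within 5× the pixel pitch whose scores are
within a small tolerance (default 5% of the score range — the tolerance is
deliberately tied to the data scale), until all pixels are assigned. Seeds
are visited in descending T-marker load with id tie-breaks, so the
partition is deterministic. Node score is the member mean and node
coordinates the member centroid; the adjacency threshold for the graph
should then be set relative to the node sizes.

## The synthetic-data generator

`simulateDataset` emulates the structure the method assumes, with known
ground truth, so every stage is testable without external downloads:

* a 30 × 30 hexagonal lattice at 110 µm pitch (interior spots have exactly
  6 neighbors at the pitch);
* 5 planted straight trails of 8 adjacent spots; straight geometry is the
  regime in which the 3D-line method is meaningful, and a length-8 trail
  spans 770 µm, comfortably above the 500 µm filter;
* T-cell infiltration in 40% of off-trail spots — a moderately-to-densely
  infiltrated section; this also keeps the off-trail T-node graph
  connected enough for alternative-route sampling to be exercised (site
  percolation on the triangular lattice sits at 0.5);
* exhaustion markers rising log-linearly along trails (0.6 per step) with
  off-trail T spots at the mid-trail level, so trail starts rank low and
  trail ends high among all nodes;
* chemokine and macrophage markers rising at log(1.3) per step, matching
  what the mixed-model trend test estimates;
* stage genes with lognormal per-(trail, gene) factors (sd 0.8) shared
  along each trail — the coherence signal the selection stage tests —
  against per-spot factors elsewhere;
* per-trail "clones" of TCR variable genes detected along the trail;
* negative-binomial counts (size 6) over 200 background genes at mean 60
  (≈ 12,000 UMIs per spot, a realistic Visium depth), thinned by 5%
  dropout; a per-T-spot lognormal density factor (sd 0.1) scales the
  immune compartment jointly.

The count depth and noise settings matter: the exhaustion score inherits
noise both from the marker sums and from the regression itself (the fitted
slope multiplies T-marker noise into the residual), and the per-step
gradient must clear that noise for planted trails to remain monotone. The
defaults above put the per-step rise several-fold above the per-node score
noise — the strong-gradient regime in which recovery is expected — and
keep marker counts a small fraction of the library, avoiding the
compositional squeeze that would otherwise flatten late trail steps in
TPM units. With gradients set to 0 and stage coherence disabled the
generator produces matched *null slides* used to measure false trails.

What the generator does **not** emulate: tissue-domain structure (tumor /
stroma / immune regions and their spatially autocorrelated expression),
histology, segment-level clonality, or platform artifacts beyond uniform
dropout. Two consequences are worth knowing. First, passing recovery tests
here shows the machinery is correct under its own assumptions, not that
trails on a real slide are migration routes. Second, expression clusters
computed on domain-free synthetic slides are not spatially contiguous, so
on a 900-spot slide a 6-cluster matching can leave a trail's cluster too
fragmented for any adjacent same-cluster control walk to exist — the
control generator then raises its diagnostic error honestly. The packaged
validation experiments therefore cluster synthetic slides at k = 3 while
the pipeline default for real data stays k = 6.

## Numerical and design choices

* **Normalization**: per-spot TPM-like scaling (counts / UMI × 1e6) feeds
  every downstream step unless an operation states raw counts (T-spot
  detection and V-gene sharing are detection-based on raw counts).
* **Variable genes**: variance of log1p(TPM), top n, seed-free and
  deterministic with ties broken by gene order.
* **3D-line cutoff**: default 5% of the score range; the original method
  leaves it to the user with the advice to keep it small. The drawback
  tolerance defaults to 10% of each trail's own score span.
* **Tie-breaking**: everywhere deterministic (node ids), so a fixed seed
  makes whole runs byte-identical; the run manifest (config + seeds)
  suffices to reproduce a run.
* **Alternative-route sampling**: self-avoiding random walks with restart
  on dead ends, walk length capped at 4× the trail length, at most 300
  attempts per candidate. Candidates with fewer than 5 alternatives are
  excluded from selection and reported (criterion (a) is undefined on an
  empty comparison set); keeping them subject only to the pooled
  percentile is available via `insufficientPolicy = "keep"`.
* **Empirical p**: plain proportion by default because a statistic outside
  the whole null should report p = 0 in this framework.
* **Zero-variance stage vectors** (all-dropout spots) contribute 0 to the
  mean pairwise correlation instead of propagating NaN.
* **k-means over graph clustering** for control matching: deterministic
  given a seed and dependency-free; any labeling can be supplied.
* **Degenerate trend fits**: identical per-trail slopes (noise-free input)
  report p = 0 for a nonzero slope rather than failing the t-test.

## Problem sizes in the packaged experiments

The validation suite and `scripts/acceptance.R` run entirely on synthetic
slides: 30 × 30 grids (900 spots, ~250 genes), 20 recovery replicates and
8 null slides in the tests (6 and 4 in the script), 500/100 trend-test
calibration/power replicates in the tests (200/60 in the script), 150–200
control sets for the empirical-DE checks, and 50 sets for control
validation. These sizes give stable estimates for every property while
keeping a full run in the minutes range; all seeds derive from a single
master seed.

## Known limitations

* Trails are snapshots: increasing exhaustion along a chain of spots is
  consistent with migration but cannot prove directed movement.
* The exhaustion score is a linear-residual summary; strongly nonlinear
  marker–load relationships would leak into `z`.
* The Dijkstra route among tied-weight routes is decided by the
  deterministic tie-break, not by biology; the 3D-line method assumes
  near-linear score growth along near-straight paths, and planted
  log-linear gradients are recovered mainly by the graph method.
* Control generation requires each trail's expression cluster to contain
  enough adjacent T spots; very fine clusterings on small or fragmented
  slides fail loudly rather than silently relaxing the matching.
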