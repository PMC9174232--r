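---
title: "Methods: co-expression modules, cell-cell communication, trajectories and biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, cell-cell communication, trajectories and biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclrcomm)
```

# Scope and philosophy

`sclrcomm` implements the analytical chain that links single-cell
expression matrices to cell–cell communication maps and biomarker
rankings: QC filtering, signed weighted co-expression networks with
module eigengenes, ligand–receptor (LR) interaction networks between
cell-type-annotated modules, pseudotime trajectories with module
dynamics, random-forest feature importance, cross-species module
overlap, and paired ROC/AUC comparison. Every stage is a plain function
with an explicit contract, and the package ships a synthetic-data
generator that plants each kind of structure the chain is meant to find.
The design priority throughout is *determinism*: given a seed, every
stage — including the embedding and the clustering — returns the same
answer, so recovery claims can be tested instead of narrated.

# Quality control and differential expression

Cells are kept when they detect **strictly more than** `min_genes` genes
(a value > 0 counts as detected). The strict inequality is deliberate:
"more than 300 expressed genes" reads as `> 300`, and the boundary cell
at exactly 300 is dropped. Typical cutoffs are 300 for droplet data, 500
for public human datasets and 2000 for deep full-length protocols. Genes
enter the network when they reach `min_value` (inclusive; FPKM-scale
default 10) in at least `min_cells` cells (default 1).

Expression is log-transformed as `log2(x + 1)` before any
correlation-based step. Whether the original analyses correlated raw or
logged FPKM is not knowable from the outside; the log is the
variance-stabilising default here and can be skipped via
`log_values = FALSE` in the pipeline configuration.

Differential expression uses the two-sided Wilcoxon rank-sum test with
BH adjustment and fold change `log2((mean_A + eps)/(mean_B + eps))`,
`eps = 1e-9` (the pseudocount only guards division by zero; it is far
below any realistic expression value). Significance requires
`adjusted_p < 0.05` **and** `|log2FC| > 0.25`, the marker-detection
convention. The exact rank-sum null is enumerated when both groups have
at most 10 cells and no ties occur; otherwise the normal approximation
with tie and continuity correction is used. The crossover at 10 keeps
the test exact at the scale where exactness matters and fast everywhere
else.

# The signed network and module detection

Adjacency is `((1 + cor)/2)^beta`. The *signed* form matters for module
interpretation: anti-correlated genes (e.g. a quiescence program versus
an activation program) must not end up in one module, which unsigned
`|cor|^beta` would allow. `beta` is selected by `pick_soft_threshold()`:
for each candidate power the connectivity distribution is binned
(10 equal-width bins on k, empty bins dropped, at least two required)
and `log10 p(k)` is regressed on `log10 k`; the signed fit index is
`R^2 x sign(-slope)` so that only *decreasing* degree distributions can
qualify as scale-free. The smallest power reaching 0.85 wins; if none
does, the best power is returned with a warning — pure-noise data, which
has no scale-free structure at any power, always takes this branch.

Module detection clusters `1 - TOM` with average linkage. Three
decisions here were genuinely open:

* **Cut height.** The dendrogram is cut at the midpoint of the largest
  gap in the sorted merge heights. On module-structured data the merge
  heights are bimodal — within-module merges sit low, background
  agglomeration sits near 1 — and the largest gap separates the two
  regimes; a fixed quantile cut does not, because the top of the tree is
  always background. A fixed `cut_height` can be supplied to override
  the gap rule.
* **Stability.** A branch only becomes a module if its mean
  within-branch TOM exceeds twice its mean TOM to non-members. Pure
  noise fails this ratio (within ≈ between), which is what sends > 90%
  of independent genes to "unassigned" instead of into one giant
  spurious module.
* **Merging.** Modules smaller than `min_size` (default 30 genes) are
  merged into the larger module whose representative profile (eigengene
  when expression is available, TOM centroid otherwise) correlates most;
  an undersized module with no larger neighbour is dissolved to
  unassigned rather than violating the size floor. Module pairs whose
  representatives correlate above `merge_cor = 0.75` are merged — the
  mirror image of the common merge height 0.25 on the eigengene
  dissimilarity scale.

Leftover genes join their best module only when their mean TOM to it
beats the 95th percentile of their TOM to all genes; otherwise they stay
unassigned. Modules are named M1, M2, … by decreasing size, which makes
partitions comparable across runs up to this relabelling.

Eigengenes are first principal components of per-gene standardised
module expression, scaled to unit variance and oriented so the mean
correlation with member genes is nonnegative (exact ties orient the
first member gene positive). A module containing a constant gene is a
hard error naming the module — silent NaN propagation is worse than a
loud stop. In `module_membership()`, by contrast, a constant *query*
gene is not an error: its correlation is recorded as 0 and flagged,
because membership tables are screened in bulk.

# Communication

Gene-to-cell-type attribution goes through modules: a module is
annotated with the cell type whose marker set it overlaps most (ties and
zero overlap give "unannotated"; marker sets must be disjoint), and an
LR pair contributes a directed source→target edge only when both genes
sit in annotated modules. This is the module route to communication
networks — attribution by co-expression context, not by per-cell
expression thresholds — and it makes decoy pairs among unassigned genes
exactly inert. Interaction counts are directed; autocrine pairs land on
the diagonal. Ranking cell types by in+out degree identifies the
communication hub (in heart tissue, the fibroblast).

The LR map embeds LR genes by classical metric MDS on `1 - cor`.
Deterministic geometry was preferred over a stochastic neighbour
embedding because the map's downstream use here is quantitative
(within/between-group distances), not aesthetic.

Enrichment uses the one-sided hypergeometric upper tail (equivalently a
one-sided Fisher's exact test), BH-adjusted across sets; annotation sets
are intersected with the universe first. The same machinery drives
cross-species module overlap after ortholog mapping, where the
best-match rule (minimal adjusted p, ties by larger overlap, then name)
requires `adjusted_p < 0.05` to declare correspondence at all.

# Trajectories

`embed_cells()` offers MDS (default) and PCA backends; both are
deterministic. Display uses 2 dimensions, but lineage geometry is
computed in 5 (`n_dim = 5`) in the package's own workflows: with only 2
MDS dimensions, branch tips of a Y-shaped trajectory are occasionally
compressed toward each other and the centroid spanning tree can link
tip to tip. Five dimensions keep the branch angle open at negligible
cost.

`cluster_snn()` builds the k-nearest-neighbour graph (Euclidean),
weights each neighbouring pair by `shared / (2k - shared)` shared
neighbours, drops zero-weight pairs and maximises modularity by
deterministic greedy agglomeration (igraph's fast-greedy). Two
properties deserve honesty. First, modularity maximisation on an SNN
graph *subdivides* large diffuse clusters when k is small relative to
cluster size: on two 60-cell Gaussian blobs with k = 10 the subdivided
partition has strictly higher modularity than the 2-blob partition
(≈ 0.69 vs ≈ 0.50), so exact blob recovery requires k commensurate with
cluster size (k ≈ 25 for 60-cell blobs); what holds at any k is that
clusters never mix well-separated blobs. Second, greedy modularity has
no resolution knob — granularity is controlled through k — so the
clustering interface deliberately exposes `k` and `seed` only.
Over-clustering is harmless downstream: lineages are paths over cluster
centroids, and extra clusters along a branch just add path vertices.

Lineages are root-to-leaf paths of the Euclidean minimum spanning tree
over cluster centroids — a deterministic simplification of simultaneous
principal curves that preserves what module-dynamics conclusions need:
branch structure and cell ordering. The root must be chosen; by default
`select_root_cluster()` picks the cluster with the highest fraction of
"control" cells, mirroring the usual choice of the control-dominated
cluster as the trajectory origin. Pseudotime is arc length along the
piecewise-linear centroid path after orthogonal projection, scaled to
[0, 1]; cells beyond the ends clamp to 0/1.

Module dynamics smooth an eigengene against pseudotime with a sliding
local mean: each of 100 grid points averages the `span x n` cells
nearest in pseudotime (`span = 0.3` default — wide enough to be stable
at a few hundred cells, narrow enough to show a branch-specific rise).
The direction call ("increasing" / "decreasing" / "non-monotone")
compares the smoothed endpoint difference with a permutation null
(default 1000 shuffles, two-sided 5%). The reported `trend` standardises
the endpoint difference by the curve's range, so a perfectly monotone
curve scores exactly 1. Mutual exclusivity of two modules — the
signature of alternative cell programs — is flagged when their
eigengenes correlate at or below −0.3; the threshold is configurable and
deliberately lenient, since eigengene correlations are attenuated by
within-module noise.

# Classification and biomarkers

Feature importance is random-forest mean decrease in accuracy — raw,
unscaled permutation importance (500 trees by default, `mtry` at the
package default of √p) — so a constant feature scores exactly 0 and the
ranking is invariant to affine rescaling of any feature.
"Significantly involved in classification" is operationalised in
`importance_significance()` as importance above the 97.5th percentile of
a label-permutation null of the *maximum* feature importance (default
100 permutations), which controls the family-wise error across features.

AUC is the Mann–Whitney estimator with half credit for ties, computed by
midranks; `roc_curve()` thresholds at each unique score descending, and
its trapezoidal area equals the rank estimator to numerical precision
(asserted at 1e-12 in the tests). The paired comparison of two markers
on the same samples is the DeLong test: the variance of the AUC
difference is estimated from the empirical covariance of per-sample
placement values, and the standardised difference is referred to a
normal. A stratified bootstrap (2000 resamples, positives and negatives
resampled separately, normal reference on delta/sd) is available as the
secondary method; the two agree on reject/accept in the package's
validation simulations. Degenerate inputs are pinned down: identical
score vectors give delta 0 and p 1; zero estimated variance with nonzero
delta gives p 0. The diagnosis-versus-severity screen computes, per
protein, one AUC for control-vs-disease and one for
non-advanced-vs-advanced disease, exposing the dissociation between
markers that diagnose and markers that grade severity.

# The synthetic-data generator

`generate_expression()` draws from a log-normal latent-factor model:

    expr = max(exp(baseline + Σ_m loading_gm · activity_mc + noise) − 1, 0)

followed by independent Bernoulli dropout. The model is continuous (like
FPKM/RPKM data), and a shared latent activity with positive loadings
makes each module an approximate rank-1 correlation block — exactly
rank-1 as noise → 0 — which is the property every downstream stage
consumes. Cell types raise the mean activity of their modules by
`activity_shift` (default 2 log-units); marker genes are the leading
genes of a type's first active module, or dedicated boosted background
genes for types without modules. Planted LR pairs draw their ligand from
a module active in the source type and their receptor from a module
active in the target type; decoys are sampled among unassigned genes, so
a correct pipeline reproduces the planted interaction-count matrix
exactly on noiseless data.

Trajectory configurations replace the random activity of designated
modules with deterministic functions of a uniform pseudotime: rising
modules ramp linearly, falling modules mirror them, and in two-branch
configurations each rising module is tied to one lineage — shared ramp
before the branch point (0.5 by default), and on the opposite branch the
program is suppressed back toward baseline after it. The suppression
makes branch programs mutually exclusive, the behaviour reported for
module pairs in diseased-heart trajectories, and gives the two branches
a wide geometric angle. Condition metadata labels cells with pseudotime
below 0.25 as "control", which is what the default root selection keys
on.

What the generator does **not** emulate: count noise (no negative
binomial), batch effects, doublets, ambient contamination, or
library-size variation. Passing recovery tests therefore demonstrates
that the chain's logic is correct and its estimators consistent under
the stated model — not that any particular biological dataset will
yield clean modules. The QC functions are exercised by the generator's
dropout; they are not a substitute for dataset-specific QC.

# Problem sizes and numerical conventions

The validation suite runs, per replicate: module recovery at 500 genes ×
200 cells with five planted 40-gene modules at noise SD 0.3; the
communication chain at 260 genes × 240 cells, four cell types, twelve
planted LR pairs and five decoys at noise 0; trajectories at 150 genes ×
250 cells with 20 replicate seeds; the biomarker screen at
60/25/15-sample groups with unit noise. These sizes were chosen as the
smallest at which each recovery statistic is stable across seeds, and
they keep the whole validation run in tens of seconds.

Numerical conventions collected in one place: correlations of constant
vectors are 0 with a flag (never NaN) everywhere except inside
`module_eigengenes()`, where a constant member gene is an error; TOM and
adjacency are validated against symmetry and range on entry; oracle
equalities (TOM triple-sum, AUC pair counting, trapezoid-vs-rank) are
asserted at 1e-12; hypergeometric p-values are exact via `phyper`; BH
adjustment is `p.adjust`; all tie-breaks (module naming, top-gene
ranking, cell-type ranking, best-match selection, MST paths) resolve
lexicographically so that equal inputs give equal outputs.

# Known limitations

* The tree cut is a deterministic simplification of dynamic tree cut; on
  data with strongly nested module structure (modules inside modules) a
  single gap-based cut height can merge levels that an adaptive cut
  would separate.
* Centroid-path pseudotime is piecewise linear; strongly curved
  trajectories with few clusters acquire arc-length distortion that
  simultaneous principal curves would iron out.
* The SNN/modularity clustering subdivides diffuse clusters at small k,
  as discussed above; choose k near the expected cluster size when exact
  cluster recovery matters.
* The LR stage needs externally supplied marker sets and an LR pair
  table; the package plants and recovers them synthetically but curates
  neither.
* `run_pipeline()` orchestrates the simulated end-to-end workflow; for
  real data the individual functions are the intended interface, with
  file readers (`read_expression`, `read_lr_database`) provided for TSV
  and matrix-market inputs.
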