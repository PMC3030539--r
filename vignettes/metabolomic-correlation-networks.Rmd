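---
title: "Metabolomic correlation networks: models, parameters and design choices"
author: "metcornet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic correlation networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `metcornet`, the
parameters that matter, the numerical and design choices that were
genuinely open, and what the package's tests do and do not establish.

## The analysis problem

Metabolite profiling experiments yield a metabolites × samples matrix of
relative abundances over groups of biological replicates (genotypes,
tissues). Beyond mean-level changes, the *correlation structure* between
metabolites across replicates reflects shared regulation: metabolites in
the same pathway, or under the same regulatory control, co-vary. The
pipeline turns that idea into a reproducible procedure: test mean changes,
build a correlation network per condition, extract densely connected
clusters, and ask whether the clusters line up with known pathway
annotations better than chance.

## Differential abundance: the rank product

After log2 transformation, group A is compared to group B by the rank
product. For each of the $K = n_A n_B$ cross-group sample pairs the
per-metabolite log-ratios are ranked (rank 1 = most up-regulated for the
"up" analysis, most down-regulated for "down"; ties receive average
ranks), and

$$RP_g = \Big(\prod_{k=1}^{K} \mathrm{rank}_{g,k}\Big)^{1/K}.$$

**Null distribution.** The false discovery proportion
$pfp(g) = E[\#\{\text{null } RP \le RP_g\}]/\mathrm{rank}(RP_g)$ is
estimated from `nPerm` (default 1000) random permutations of each
metabolite's values across the tested samples, with the full ratio/rank
recomputation per permutation. The construction matters: the $K$ cross
pairs reuse the same $n_A + n_B$ samples and are strongly dependent, so a
null that draws $K$ *independent* rank permutations is far too narrow and
calls a large fraction of null metabolites significant. Permuting the data
preserves the dependence and restores calibration (the suite verifies a
null call rate well below 0.05). `pfp` is reported uncapped, with a capped
convenience column; calls use `pfp < 0.05`.

**Missing values.** Rank product requires complete rows and errors
otherwise; Spearman correlation (below) instead uses pairwise-complete
observations with the per-pair $n$ recorded. These are documented choices;
standard practice differs between the two statistics.

## Correlations and edge significance

Spearman's $r$ is the Pearson correlation of within-pair ranks (average
ranks on ties) over pairwise-complete samples. It is preferred over
Pearson here because relative peak areas carry occasional heavy-tailed
outliers, to which rank correlation is robust — the synthetic generator
plants exactly this contamination so the property is testable. The
no-correlation test uses $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of
freedom; $|r| = 1$ yields $p = 0$ by convention. Pairs with fewer than 4
complete observations or zero rank variance are excluded with a warning.

**Local fdr.** Edge calls use the local false discovery rate from the
two-component mixture $f(p) = \eta_0 \cdot 1 + (1 - \eta_0)h(p)$:
$\eta_0 = \min(1, \frac{\#\{p > 0.5\}}{0.5\,m})$ (Storey's estimator at
$\lambda = 0.5$), $\hat f$ is the Grenander nonincreasing density — the
slope of the least concave majorant of the empirical CDF anchored at
$(0,0)$ and $(1,1)$, computed by a monotone-chain upper hull — and
$fdr(p) = \min(1, \eta_0/\hat f(p))$. Significance is `fdr < 0.05`. The
algorithm is pinned to this construction; numeric agreement with other
local-fdr implementations is not promised, only the calibration
properties that the test suite checks (pure-null call rate near zero,
high precision under a 20% signal mixture). Below ~50 p-values the
estimate is unreliable and the function warns.

**Differential correlation.** Two conditions are compared per pair via
Fisher's variance-stabilizing transform $z = \operatorname{atanh}(r)$ and
$Z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ with a two-sided normal
p-value, using each condition's per-pair $n$; local fdr is then applied
across all tested pairs of the analysis set (per analysis set, not jointly
across sets — a documented choice). Pairs with $|r| = 1$ cannot be
transformed and are flagged.

## Networks, the threshold sweep and threshold selection

An edge joins two metabolites when $r \ge$ threshold. Negative
correlations are excluded from networks by default — they are rare in
metabolomic data — though tables retain them and a flag enables
$|r|$-thresholding. Networks are swept over thresholds 0 to 1 by 0.01,
computing six measures: density $2E/(N(N-1))$, global transitivity
(3 × triangles / connected triples; the average-local variant is available
via `igraph` directly), average degree $2E/N$, average path length over
connected ordered pairs only (the networks are disconnected at high
thresholds), component count and edge count. The null band comes from 100
randomized datasets in which every metabolite's values are permuted
independently across samples — marginals preserved, all inter-metabolite
dependence destroyed. (Degree-preserving edge rewiring is a different null
and is out of scope; value permutation is the pinned interpretation of
"randomized data".)

**Threshold selection.** On correlated data the component curve has a
characteristic shape: near-1 component at low thresholds, a first rise
where noise-level correlations drop out, a plateau where correlated
modules persist as intact blocks, and a second rise where the modules
themselves dissolve into isolated nodes. The selector returns the
threshold at the start of the *longest plateau strictly between the
curve's starting and maximum values*. A naive arg-max of the one-step
forward difference is used as a fallback when no plateau of at least 3
grid steps exists, but as a primary rule it is unreliable: on synthetic
modular data the module-dissolution rise is often steeper per step than
the noise-separation rise, and the arg-max then lands *above* the
within-module correlation range, fragmenting every module before
clustering. The plateau rule keeps the selection between the two
transitions (empirically within ±0.1 of the value separating within- from
between-module correlation quantiles at loading/noise = 2). A flat curve
falls back to 0.5 with a warning, and an explicit override always wins —
the canonical choice for real data of this kind is $r \ge 0.5$.

## DPClus clustering

The clustering stage extracts densely connected node sets by tracking two
quantities: the cluster density $d_k = 2|E_k|/(|N_k|(|N_k|-1))$ and, for a
candidate node $n$ outside cluster $k$, the cluster property
$cp_{nk} = E_{nk}/(d_k\,|N_k|)$, where $E_{nk}$ counts edges from $n$ into
the cluster. Parameters `cpIn` and `dIn` both default to 0.5; overlapping
mode is on by default; `minClusterSize` defaults to 2.

The published description of the algorithm leaves internals open, so this
implementation pins them explicitly (the contract is the invariant suite,
not bit-compatibility with the original program):

* **Weights.** Edge weight = number of common neighbors of its endpoints;
  node weight = sum of incident edge weights.
* **Seeding.** The node with maximal weight; ties broken by higher degree,
  then lexicographic id — a total order, so results are fully
  deterministic and independent of input node order.
* **Growth.** Candidates (neighbors of the cluster in the working graph)
  are ordered by (edges into cluster desc, node weight desc, id asc); the
  *first* candidate whose addition keeps density ≥ `dIn` and whose
  cp ≥ `cpIn` is added, and the scan repeats. A singleton cluster's
  density is defined as 1 so growth can start (the formula is 0/0 there).
* **Emission and removal.** A grown cluster is emitted if it has at least
  `minClusterSize` nodes; its grown members are removed from the working
  graph either way, and the loop continues until the working graph is
  edgeless. Nodes in no emitted cluster are reported as unclustered.
* **Overlapping extension.** Each emitted cluster is extended in the
  *original* graph by previously removed nodes that still meet the cp and
  density conditions (same candidate ordering, recomputed per step). The
  extension never alters the working graph, so downstream extraction is
  unaffected; extended members are recorded separately.

Cluster-level structure is summarized by `clusterAdjacency`: clusters are
connected when they share a member or an original edge runs between them.

## Enrichment and the S-value

Per cluster and pathway, the one-sided over-representation p-value is the
upper hypergeometric tail $P(X \ge a)$ of the 2×2 table over the
annotation universe. Two choices change every p-value and are therefore
explicit: the universe is the *analyzed* metabolites present in the
annotation (not all annotation members), and no multiple-testing
correction is applied across pathways within a cluster — raw per-cluster
best p-values ($p_{\min}$) feed the set-level control instead. Overlapping
cluster members count fully in each cluster they belong to.

The set-level statistic is the S-value, $S = \frac{1}{n}\sum_i p_{\min,i}$
over clusters with a defined $p_{\min}$ (clusters with no annotated member
are excluded with a warning). Its null distribution comes from randomized
cluster sets that preserve every cluster's size, drawing members uniformly
without replacement within a cluster and independently across clusters
(default 100 sets); `globalPermutation = TRUE` instead applies one
universe-wide relabeling per set, preserving overlap structure — the
stricter reading of "permutation of the metabolite names". The empirical
p-value $(1 + \#\{S_{null} \le S\})/(n_{random} + 1)$ is never exactly
zero.

## The synthetic-data generator

`syntheticConfig()` defines the simulated study; `generateProfiles()`
emits a log2-scale matrix where metabolite $i$ in module $m$ has

$$x_{is} = \mu_i + \text{shift}(g_s, i) + \lambda f_{m,s} +
\varepsilon_{is},$$

with $f_{m,s}$ standard normal per sample, $\mu_i \sim U(8, 12)$ (typical
log2 relative peak areas), $\varepsilon_{is} \sim N(0, \sigma)$, and, with
probability `outlierFraction`, $\varepsilon$ inflated by `outlierScale` —
a multiplicative contamination of the residual, not the mean, so rank
correlation's robustness is testable against Pearson. Loadings are all
positive (metabolomic correlations are predominantly positive), a single
latent factor per module being the simplest mechanism that produces the
modular topology the pipeline analyzes. Mean shifts are additive on the
log2 scale, matching the transform stage.

Defaults emulate a three-genotype root profiling design: 59 metabolites
over 53 samples (WT 17, mto1 16, tt4 20), four modules of sizes
12/10/8/6, a +2 log2 shift on three module-1 metabolites in mto1 (a
methionine-like over-accumulation), `factorLoading = 1`,
`noiseSd = 0.5`, `outlierFraction = 0.02`, `outlierScale = 5`. Real
studies of this kind do not report within-group variances or correlation
strengths, so loading/noise = 2 is a calibration choice, not an estimate:
it yields within-module Spearman $r \approx 0.75$–0.85 against a
between-module null spread of roughly ±0.3 at these sample sizes —
separable but not trivial. All randomness flows through R's
Mersenne-Twister with inversion normals under a required seed; identical
config + seed gives identical output on any platform.

`generatePathwayAnnotation()` labels each planted module as one pathway
and adds decoy pathways of comparable size drawn at random (metabolites
may carry several labels, as in real pathway databases).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: instrument-level effects (peak detection,
retention-time drift, deconvolution artifacts), metabolite identification
ambiguity, non-Gaussian biological variation beyond the outlier model,
correlation structure more intricate than single-factor blocks (nested or
overlapping modules, negative regulation), and missing values that are
not missing at random. Conclusions about calibration and recovery
transfer to real data only insofar as these simplifications are benign.

## Pipeline orchestration and reproducibility

`runPipeline()` executes transform → rank product + PCA → per-group
correlations with fdr edge calls → sweep + threshold → network → DPClus →
enrichment + S assessment → all-pairs differential correlations, and
optionally writes every artifact (TSV tables, GraphML and edge-list
networks, cluster and assessment JSON, the resolved configuration with
seed and versions) to an output directory with stable ordering — repeated
runs with the same inputs are byte-identical. A single master seed fans
out to per-stage child seeds through a fixed integer derivation, so each
stage is independently reproducible. `compareConditions()` intersects two
bundles' metabolite sets exactly by id (identifier reconciliation across
platforms is out of scope) and runs the differential-correlation test per
shared group.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic data
at the study scale the defaults define: oracle equivalence on 100 random
instances each (Spearman vs rank-then-Pearson, graph metrics vs all-pairs
BFS, hypergeometric tail vs full enumeration, all to 1e-12); Fisher-Z
type-I error over 10,000 null pairs at $n_1 = n_2 = 17$; null edge-call
rates over 200 module-free datasets; rank-product null rates over 50;
planted-module recovery, pathway hits and S-value significance over 20
replicate 59 × 53 datasets with 100 randomized cluster sets each. These
sizes make the checks statistically meaningful while keeping a full run in
minutes.

## Known limitations

* The DPClus reconstruction is pinned but not guaranteed to match the
  original program's output on shared inputs; divergences on real data
  should be attributed here first.
* The local fdr estimator is coarse below ~50 tests and is applied per
  analysis set; joint modeling across sets is not attempted.
* Average path length over connected pairs only makes disconnected and
  connected graphs comparable but mixes scales when components are many.
* No partial-correlation or mutual-information similarity measures; no
  degree-preserving rewiring nulls; no GSEA-style enrichment; no raw
  chromatography processing or metabolite identification.
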