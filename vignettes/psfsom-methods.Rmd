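---
title: "Pathway signal flow portraits: models, parameters and design choices"
author: "psfsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway signal flow portraits: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psfsom)
```

# Scope

`psfsom` computes pathway signal flow (PSF) activities at the sink nodes of
signed pathway topologies from gene-expression fold changes, arranges the
sink profiles on a self-organizing map (SOM), and mines the resulting
landscape: deregulation spots, differential sink activity against a control
class, and communities of sample classes that share pathway deregulation.
This vignette is the package's account of the underlying models, the
parameters that matter, and the choices made where the design was genuinely
open.

# The PSF propagation model

A pathway is a directed graph whose nodes carry gene sets and whose edges
carry a sign: +1 for activating interactions, −1 for inhibiting ones
(KGML relation subtypes containing "inhibition" or "repression"; everything
else, including "indirect effect" and unannotated subtypes, conservatively
defaults to +1). Sources are nodes of in-degree zero, sinks of out-degree
zero; sinks are read as the pathway's functional outputs.

Propagation is multiplicative. With linear fold changes FC mapped to nodes
(arithmetic mean over a node's measured genes, neutral 1.0 where nothing is
measured, compounds always 1.0):

* `signal(source) = input_signal × FC(source)` with `input_signal = 1` by
  default — a deregulated receptor changes its own output;
* an activating edge u→v contributes `signal(u)`, an inhibiting edge
  contributes `1/signal(u)`;
* `signal(v) = FC(v) ×` the **arithmetic mean** of the parent contributions.

The mean (rather than the sum) over parents is what makes the calibration
contract hold for any in-degree: if every FC equals 1 then every signal is
exactly 1, so PSF = 1 means "no deregulation" on every topology. The mean is
our fixed choice for combining multiple parents; a sum would inflate signal
with in-degree, a product would conflate convergent evidence with chain
length. On an activation-only chain the model reduces to the closed form
`PSF = input × Π FC(node)`, and on a path with k inhibiting edges the sink
responds monotonically to the source FC — increasing for even k, decreasing
for odd k. Both properties are asserted in the test suite against
independent oracles (direct products; sorted evaluation points).

**Cycles.** KEGG maps contain feedback loops but the propagation needs a
topological order. `break_cycles()` removes back edges found by a depth-first
search from the source nodes, visiting nodes in lexicographic id order so
the removal set is deterministic; components unreachable from any source are
searched the same way afterwards. A graph in which every node lies on a
cycle has no defensible entry point and is rejected. This is artifact
plumbing, not biology: which feedback edge is cut is a modeling convention,
and the log records every removal.

**Missing expression** keeps the topology intact (FC = 1 pass-through)
instead of deleting nodes; deleting them would silently change path lengths
and therefore PSF magnitudes.

# Preprocessing

Heterogeneous expression matrices are brought to a common representation in
three steps: probe rows are averaged per gene (probes without a mapping are
discarded), the transformation type is auto-detected and undone, and values
are divided by the mean of the in-dataset control samples. The log-scale
autocheck is a quantile heuristic: with quantiles q at probabilities
(0, 0.25, 0.5, 0.75, 0.99, 1), the matrix is declared linear when
q(0.99) > 100, or when the full range exceeds 50 with a positive first
quartile; otherwise it is treated as log2 (log10 only when configured
explicitly). The constants are fixed here so the decision is reproducible;
the decision is logged, and an `assume` argument overrides it. Fold-change
normalization against in-dataset controls is the only cross-dataset
integration step — no batch correction — so every downstream value is
interpretable as "relative to this dataset's healthy state". By
construction the mean FC of a dataset's controls is exactly 1 per gene,
which the tests assert to 1e-9.

Note that testing many classes against one shared control group correlates
their fold changes: a control mean that is low by chance inflates FC in
*every* class. This matters for the disease graph (below).

# SOM portraying

Sink profiles are first centralized: log2(PSF) minus the sink-wise mean over
all samples, so the map organizes *changes* of flow rather than absolute
levels. Training is classic online Kohonen learning with the portraying
configuration: 50 × 50 grid (tests and desk-scale runs use 10 × 10),
Euclidean best-matching unit, learning rate `0.02 / (1 + 0.01 t)` with t the
presentation counter, Gaussian neighborhood of radius 3 grid units, 12
epochs, seeded shuffled presentation order. Determinism is part of the
contract: identical seed and data give bit-identical weights and
assignments.

**Initialization.** Unit weights start as bilinear blends of four observed
profiles — those with extreme combined scores on the first two principal
components anchor the grid corners. Every prototype is therefore a convex
combination of real data and is topologically pre-ordered. We deliberately
avoid random initialization over the data range: with a *fixed* radius-3
neighborhood, units far from every best-matching unit are corrected only
weakly during training, and off-manifold random prototypes survive as
spurious extremes in class portraits, corrupting threshold-based spot
detection. (Trainers that shrink the neighborhood from map-covering radii
do not have this problem; this trainer keeps the radius fixed by design, so
the initialization has to stay on the manifold.)

**Portraits and spots.** A class portrait is the per-unit mean of the weight
entries over the class's samples. Over-expression spots are 4-connected
components (rectangular grid, non-toroidal borders) of units at or above
90 % of the portrait maximum, taken only when the maximum is positive;
under-expression spots mirror this at the minimum. We read "90 percent of
the extremes" as a fraction of the signed extreme value, not as a quantile —
the alternative reading would always flag 10 % of the map, even for flat
portraits. A `spot_method = "kmeans"` variant (3-group k-means on unit
values) is available for landscapes without a single dominant peak. The
summary map unions class over-spots and letters the merged components by
descending peak. Spots list the sinks assigned to their units; sinks whose
planted effect is much weaker than the class's strongest response sit below
the 90 % contour by construction, which is why the spot-recovery tests use
uniformly deregulated cascades while the differential-recovery tests use
graded branch effects.

# Differential sink activity

Per sink, the effect is the difference of mean log2 PSF between a disease
class and the control class — a log fold difference. The statistic is a
pooled two-sample t whose per-sink variance `v_k` is shrunk toward the
median pooled variance across sinks:

    v*_k = λ v_med + (1 − λ) v_k,
    λ = min(1, Σ var-hat(v_k) / Σ (v_k − v_med)²)

with `var-hat(v_k) = 2 v_k² / df` the normal-theory variance of a pooled
variance estimate on `df = n_a + n_b − 2` degrees of freedom. This is the
Opgen-Rhein/Strimmer-style intensity with the median as target; the
normal-theory var-hat is our fixed choice of estimator. When all empirical
variances coincide the statistic reduces exactly to the ordinary pooled t
(asserted against `t.test(var.equal = TRUE)`), and on null simulations the
empirical type-I error at p < 0.05 stays within [0.03, 0.07]. Degrees of
freedom are `n_a + n_b − 2` without a Welch correction — the standard
companion of a pooled, shrunken variance, and a documented approximation.
Multiple testing uses Benjamini–Hochberg q-values; a sink is significant iff
p < 0.05 **and** q < 0.2. BH was chosen because "FDR estimation" without
further qualification is read as the step-up procedure; empirical-null
methods are out of scope.

# Class similarity and the disease graph

Class profiles (portrait vectors, or mean PSF profiles) feed three
complementary views: average-linkage hierarchical clustering under
`1 − Pearson r` or Euclidean distance (average linkage keeps heights
ultrametric and is robust to outlier classes; constant profiles are rejected
under Pearson, where the correlation is undefined), a second-level SOM on a
small grid, and FastICA (symmetric decorrelation, logcosh contrast, PCA
whitening, seeded orthonormal start). ICA components are sign-fixed by
making each component's largest-magnitude loading positive, so seeded runs
are exactly reproducible. The FastICA routine is implemented in-package.

The disease graph connects two classes when at least one pathway has a sink
significant in both with the same sign of the log fold difference; the edge
weight counts such pathways. A `level = "sink"` switch counts shared sinks
instead. Communities come from igraph's Pons–Latapy walktrap with walk
length 4 (igraph's conventional default); isolated classes form singleton
communities rather than being dropped, since an outlier class is a finding,
not an error.

# The synthetic benchmark

The generator emulates the structure the method is designed for: layered
branched DAGs (each internal node has at least one parent and one child, so
sources are exactly the first layer and sinks the last), about seven sinks
per pathway, inhibitory edges drawn with probability 0.15, two genes per
node, serialized as KGML so the real parser is exercised. Expression is
log-normal baseline (meanlog 7, sdlog 1) times per-sample log-normal noise
(`noise_sd` on the log2 scale, default 0.3) times the planted effect.
Deregulation is planted on *gene expression*, upstream of everything, so
fold-change computation and propagation are genuinely exercised rather than
asserted on pre-cooked PSF values.

Two planting modes exist per class. `"path"` (default) multiplies the genes
on one source-to-sink path — excluding the terminal sink — by the effect
size, producing graded downstream responses; `"pathway"` plants every gene
of the target pathway, deregulating all its sinks uniformly. Ground truth is
derived by noiseless propagation of the planted fold changes; a sink counts
as truly deregulated when its expected |log2 PSF| is at least
`truth_min_log2` (default 0.25). The floor reflects detectability under the
design's own conditions: at 20 samples per class and noise 0.3 the standard
error of a log2 fold difference is about 0.1, putting 80 % power near 0.27 —
sinks diluted below that by multi-parent averaging carry less signal than
noise and are not meaningful recovery targets.

What the generator does **not** emulate: platform-specific probe effects,
batch structure, correlated gene-gene noise, overlapping pathway membership
of genes, or realistic KEGG motif statistics. Passing the synthetic suites
therefore shows that the pipeline recovers what its model class can express,
not that any particular biological claim holds on real cohorts.

**Benchmark designs and problem sizes.** The end-to-end recovery suite uses
a 4-block design (12 disease classes in blocks of three sharing a planted
branch, alternating direction, 10 pathways, effect 2, noise 0.3, 20 samples
per class, 20 seeds): differential recovery is scored against the
ground-truth sink sets, false positives against sinks with no planted effect
at all. The disease graph for this benchmark is built with sink-level
counting: with single-target classes, pathway-level weights are 1 within and
between blocks alike (shared-control correlation creates the spurious
cross-block edges), so only the sink-level weights carry the block contrast.
The two-super-group design (up-regulated versus down-regulated whole-pathway
planting, three classes each) feeds the hierarchical first-split check on
10 × 10 portraits. Calibration is asserted over 1,000 freshly generated
topologies. These sizes are the package's chosen desk-scale study
conditions; all suites run in well under a minute each on one CPU.

# Interfaces

Every stage is an exported function; `run_pipeline()` chains them from a
config list or JSON file, writes every intermediate artifact under a run
directory and records seed, parameters and MD5 checksums in a manifest, so
reruns are byte-verifiable. A thin command-line wrapper
(`inst/cli/psfsom.R`) exposes `simulate` and `run` subcommands; the
remaining stage-wise entry points of the design are the exported functions
themselves, which is the natural R idiom. Models and graphs are saved in
text formats only (TSV, JSON, GraphML, Newick, KGML).

# Known limitations

* The propagation rule fixes one of several defensible conventions
  (mean parent combination, reciprocal inhibition, sources multiplying the
  input); alternative combination rules (max/min) are out of scope.
* Cycle breaking is a deterministic convention, not an inference about which
  feedback edge is biologically dispensable.
* The shrinkage-t degrees of freedom ignore the estimation of the shrinkage
  intensity; with very few sinks the test is only approximately calibrated.
* Fold-change normalization against a shared control group correlates
  classes; disease-graph edge weights should be read with that in mind.
* The SOM is non-toroidal and trained with a fixed neighborhood radius;
  portraits are comparable across classes of one run but not across runs
  with different seeds or grids.
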