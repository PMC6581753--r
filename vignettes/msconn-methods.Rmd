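---
title: "Methods: connectome classification and nodal statistics in msconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome classification and nodal statistics in msconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msconn)
```

# Overview

`msconn` analyses structural brain connectomes: square symmetric matrices of
tractography fiber counts between q = 84 parcellated gray-matter regions.
It targets longitudinal clinical cohorts — the motivating application is
multiple sclerosis (MS), whose clinical courses (CIS, RR, SP, PP, plus
healthy controls) differ in how inflammation and neurodegeneration degrade
white-matter connectivity. The package provides two complementary analyses:

1. **Classification**: a single-layer graph convolutional network (GCN)
   trained to predict the clinical course from a subject's thresholded
   connectivity graph, with or without local graph metrics as node features.
2. **Nodal statistics**: per-node, per-metric linear mixed-effects models
   comparing clinical groups longitudinally, with post-hoc pairwise
   contrasts.

Because clinical connectome datasets of this kind are generally not publicly
distributable, the package includes a first-class synthetic cohort generator
whose data model matches what both analyses assume, so the entire pipeline
is testable end to end.

# Graph construction

A connectivity matrix A (non-negative, symmetric, zero diagonal) is
sparsified by proportional thresholding: with q nodes there are
(q² − q)/2 node pairs and the threshold operator keeps exactly

T = floor((q² − q) · τ / 2)

edges of **largest** weight, zeroing the rest. At the default τ = 0.35 and
q = 84 this keeps T = 1220 edges. Only pairs with positive fiber count are
eligible, so graphs rawer-sparser than τ are left intact. Numerical
conventions, fixed for determinism:

* T is rounded down (floor).
* Ties at the cutoff weight are broken by lexicographic node-pair order;
  as a consequence the kept edge set is monotone in τ.
* The binary variant of a graph replaces every kept weight by 1; support is
  preserved exactly.

# Local graph metrics

Four local metrics are computed per node, each in a binary and a weighted
variant, following the conventions of the Brain Connectivity Toolbox
literature. For weighted variants, weights are first rescaled by the
largest weight of the thresholded graph, w̃ = w / max(w), and weighted
shortest paths measure edge length as 1/w̃ (fiber counts are affinities:
stronger connections are "shorter"). The four metrics:

* **Degree / strength**: D_i = Σ_j a_ij (binary) or Σ_j w_ij (weighted;
  raw weights, keeping fiber-count units).
* **Clustering coefficient**: CC_i = 2 t_i / (k_i (k_i − 1)), where t_i
  counts triangles around i; the weighted variant replaces triangle counts
  by triangle intensities (w̃_ij w̃_jh w̃_hi)^(1/3).
* **Local efficiency**: the global efficiency of the subgraph induced by
  i's neighbors: E_i = Σ_{j≠h ∈ N_i} [d_jh(N_i)]⁻¹ / (k_i (k_i − 1)), with
  paths restricted to run inside the neighborhood and unreachable pairs
  contributing zero. The weighted variant multiplies each term by
  (w̃_ij w̃_ih)^(1/3) and uses weighted restricted path lengths.
* **Betweenness centrality**: BC_i = 1/((n−1)(n−2)) Σ ρ_hj(i)/ρ_hj over
  ordered pairs h ≠ j, both ≠ i, where ρ counts shortest paths; pairs with
  no connecting path contribute zero.

Two convention choices deserve explicit mention because the literature
prints several variants:

* The weighted clustering coefficient keeps the same ½ pair-counting factor
  as the binary triangle count (equivalently: the ordered-pair intensity sum
  with the 2/(k(k−1)) normalizer).
* The weighted local efficiency applies the cube root to the incident
  weight product only, not to the inverse path length.

Both choices are the unique ones under which every weighted metric reduces
*exactly* to its binary counterpart when all weights are equal — an
invariant the test suite enforces on random graphs, alongside agreement
with brute-force enumeration oracles on all graphs up to 8 nodes and
permutation equivariance. Nodes with fewer than two neighbors get CC = E =
0 by definition (a division-by-zero guard).

Shortest-path machinery is delegated to `igraph`; the package's own test
oracles enumerate simple paths exhaustively and independently.

# Node features

Six feature conditions define the classifier input X (q × d):

* `identity` — the q × q identity matrix ("featureless": the model can
  only exploit graph structure); exempt from normalization.
* `D`, `BC`, `CC`, `E` — one metric as a single column (d = 1).
* `all-graphs` — all four metrics as columns in the fixed order
  [D, BC, CC, E] (d = 4).

Metric columns are min-max normalized to [0, 1] **per graph and per
column**. Normalizing per graph keeps every sample self-contained — no
statistics flow from training to test graphs — at the cost of discarding
between-graph scale differences in a metric (those are still visible to
the classifier through the adjacency). A constant column maps to zeros.
`normalize = FALSE` exposes raw columns for users who prefer a
cohort-level scheme.

# The classifier

The graph-convolution layer is H(X, A) = ReLU(Â X W) with the renormalized
adjacency Â = D̃^(−1/2)(A + I)D̃^(−1/2), D̃_ii = Σ_j (A + I)_ij. The full
architecture is:

GC layer (k = 100 channels, no bias — the layer formula has none) →
ReLU → dropout (α = 0.3, training only) → flatten (column-major) → dense
layer with bias → softmax over C classes.

The parameter count is d·k + q·k·C + C; for the reference configuration
(q = 84, identity features d = 84, k = 100, C = 4) that is
8400 + 33600 + 4 = 42,004 trainable weights — including the dense bias,
which we keep because a linear output layer without an intercept would
force all class scores through the origin.

For weighted runs, Â is computed from the weighted adjacency after
rescaling weights to [0, 1] by the graph maximum; without this, raw fiber
counts in the hundreds would swamp the unit self-loop that lets a node
retain its own features. With all-equal weights the weighted and binary
pipelines coincide (tested).

Training minimizes categorical cross-entropy with full-batch Adam
(learning rate 0.001, β₁ = 0.9, β₂ = 0.999), inverted dropout, and early
stopping: 10% of the training samples (stratified) are held out, and
training stops when that validation loss has not improved for 20 epochs
(500 epochs maximum by default), restoring the best-validation weights.
Initialization is seeded uniform Glorot. Backpropagation is implemented
analytically in vectorized R; a finite-difference check in the test suite
confirms the gradients to 1e−5 relative error. Everything is deterministic
given the seeds.

# Evaluation design

`cross_validate()` runs stratified 3-fold cross-validation. The fold unit
is the **subject** by default: all sessions of a subject share a fold, so
longitudinal correlation cannot leak across the train/test boundary
(`by_subject = FALSE` mimics scan-level splitting). Scores are macro
precision, recall and F-measure — per-class scores averaged with equal
class weight, 0 substituted for undefined ratios — reported per fold with
across-fold mean and standard deviation. Macro (not micro) averaging is
used because the clinical classes are imbalanced and each course matters
equally.

`wilcoxon_compare()` implements the two-sided Wilcoxon–Mann–Whitney test
for comparing score samples (e.g. weighted vs unweighted F-measures) or
metric distributions between groups: complete enumeration of all
assignments for combined n ≤ 20 (exact even under ties), tie-corrected
normal approximation with continuity correction beyond.

# Per-node mixed-effects comparison

For each (node, metric, variant) slice of the long metric table, the
longitudinal group comparison fits

value_ij = β₀ + β₁(clinical phenotype_i) + β₂(scan session_ij) + b_0i + ε_ij

with a random intercept b_0i per subject, via `lme4`/`lmerTest`. Phenotype
is a treatment-coded factor with a configurable reference level. The
omnibus phenotype test uses the Satterthwaite denominator-degrees-of-freedom
approximation by default, with an asymptotic Wald alternative
(`ddf = "wald"`); Satterthwaite was chosen over Kenward–Roger because its
behavior is stable across mixed-model solvers while remaining close to KR
at these sample sizes. When the omnibus test is significant at α = 0.05,
all pairwise contrasts of estimated marginal group means are extracted with
Tukey adjustment (`emmeans`); there is no across-node correction by default
— detections are reported per node at nominal level, and users can apply
`p.adjust` across nodes if desired. Slices where the mixed model is
degenerate (e.g. zero residual variance in noiseless data) fall back to a
fixed-effects-only fit and are flagged as not converged; their estimates
remain valid.

The test suite verifies calibration by simulation: the type-I error of the
phenotype test stays within [0.03, 0.08] at α = 0.05 over 500 null
replicates, and a planted group effect of 2 at 40 subjects is recovered
within 10%.

# The synthetic cohort generator

The generator emulates the statistical structure the two analyses assume,
not the imaging pipeline that produces real connectomes. Its data model:

* **Topology**: edges are Bernoulli per node pair on a modular template —
  six bilateral "lobar" modules of 14 regions each (packaged as
  `inst/extdata/modular_template_84.csv`), with within-module pairs 3×
  more probable than between-module pairs (probability multipliers scaled
  to mean 1). Brain graphs are modular, not Erdős–Rényi; this makes
  clustering, local efficiency and thresholding behave realistically.
* **Weights**: present edges carry 1 + negative-binomial counts
  (dispersion `nb_size = 5`) — fiber counts are overdispersed relative to
  Poisson — with mean `base_weight_scale` (default 25) modulated by
  subject, session and severity.
* **Disease severity** (per group, in [0, 1]) attenuates both edge
  probability (factor 1 − c_d·severity, c_d = 0.3) and edge weight
  (factor 1 − c_w·severity, c_w = 0.5). Severity acts 1.6× harder on
  within-module pairs than on between-module pairs (exposures scaled so
  the edge-averaged attenuation equals the stated factors): progressive
  disease thus erodes clustering and local efficiency as well as raw
  density and strength, which matches the nodal alterations reported for
  progressive MS and — importantly — leaves a group signal that survives
  the degree normalization of the GCN and proportional thresholding.
* **Longitudinal structure**: each subject draws one random intercept on
  log-weights (sd `subject_sd` = 0.2) reused across sessions, and a
  per-session multiplicative drift (default −1% per session) models slow
  decline. This is exactly the random-intercept-plus-session data model
  the mixed-effects analysis fits, so generator effects are recoverable by
  `fit_node_lmm()`.
* **Default design**: 24 HC / 12 CIS / 30 RR / 28 SP / 20 PP subjects with
  1/5/6/7/6 sessions (580 scans), severity 0 / 0.1 / 0.45 / 1.0 / 0.7. The
  severity grading is ordered by typical disease burden with the
  secondary-progressive course most affected, and spaced widely enough
  that the four patient courses are well-separated at the connectome
  level — learnable but not trivially so. Severity, the attenuation
  constants and all scales are config fields, so harder or easier cohorts
  are one argument away.

Reproducibility: one master seed; each subject owns a deterministic
substream derived from (seed, subject index), so single subjects can be
regenerated independently and cohorts are bitwise reproducible.

What the generator does **not** emulate: MRI acquisition, tractography
biases, lesion anatomy, demographic covariates (age, sex, disability
scores), hemispheric asymmetries, and distance-dependent connection
probabilities. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's statistics and learning machinery behave as designed
under a matched data model — not that any particular accuracy level will
be attained on real clinical data.

# Problem sizes used by the test and acceptance runs

All checks run on synthetic data generated at call time:

* Metric oracle equivalence: 200 random graphs of 4–8 nodes (exhaustive
  path enumeration oracles).
* Classification recovery: a 4-course cohort of 30 subjects × 3 sessions
  per group (360 scans, 84 nodes), identity features, weighted graphs,
  τ = 0.35, 3 folds — macro F ≥ 0.9 expected, and weighted ≥ unweighted.
  The permutation null (10 label shuffles) runs on 8 subjects × 2 sessions
  per group and must give chance-level F.
* Mixed-model calibration: 500 null replicates of 20 subjects × 3
  sessions; effect recovery at 40 subjects × 3 sessions, 200 replicates.
* Rank-sum exactness: complete-enumeration comparison for all n = m ≤ 4.

These sizes are the package's choices for routine verification; the same
functions scale to the full default cohort.

# Known limitations

* One GC layer only; no multi-layer stacks, pooling or recurrent
  extensions for exploiting the longitudinal sequence jointly.
* Full-batch training in R: fine for hundreds of 84-node graphs, not
  intended for thousands of large graphs.
* The weighted-efficiency and weighted-clustering conventions are one
  defensible reading of a literature that prints several variants; both
  are documented above and pinned by tests.
* Per-graph feature normalization discards between-graph metric scale;
  the adjacency still carries it in weighted runs.
* Whether weighted experiments should feed weighted Â or weighted features
  over a binary Â is ambiguous in parts of the literature; this package
  feeds weighted Â (and weighted metric features when requested).
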