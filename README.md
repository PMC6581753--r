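# msconn

Graph convolutional classification and nodal statistics for structural
brain connectomes.

## The problem

Structural connectomes represent a brain as a weighted graph: nodes are
q = 84 parcellated gray-matter regions, edge weights are tractography
fiber counts. In multiple sclerosis (MS), inflammation and
neurodegeneration progressively erode this network, and the clinical
courses of the disease — clinically isolated syndrome (CIS),
relapsing-remitting (RR), secondary-progressive (SP) and
primary-progressive (PP) — degrade it to different degrees. Two questions
follow for anyone holding a longitudinal connectome cohort:

1. Can a subject's clinical course be predicted from their connectivity
   graph alone — and do local graph metrics help, or is the raw structure
   itself the signal?
2. Which regions' local network properties differ between clinical
   groups, accounting for repeated scans of the same subject?

`msconn` implements both analyses, plus a synthetic cohort generator that
emulates the assumed data model, so the whole pipeline runs and is tested
without access to clinical data (which is typically not distributable).

## The methods in brief

* **Thresholding**: proportional sparsification Υ keeps the
  T = floor((q² − q)·τ/2) strongest edges; τ = 0.35 keeps 1220 of the
  3486 possible edges at q = 84.
* **Local metrics**: degree/strength, clustering coefficient, local
  efficiency and betweenness centrality, each in binary and weighted
  variants (weights rescaled by the network maximum, path lengths 1/w̃),
  validated against exhaustive enumeration oracles.
* **Classifier**: a graph convolutional network
  H(X, A) = ReLU(Â X W), Â = D̃^(−1/2)(A + I)D̃^(−1/2), with k = 100
  channels, dropout 0.3, and a dense softmax head — 42,004 trainable
  weights in the reference 4-class identity-feature configuration —
  trained with Adam (lr 0.001) and early stopping, evaluated by
  subject-stratified 3-fold cross-validation with macro
  precision/recall/F-measure, and compared across conditions with an
  exact Wilcoxon–Mann–Whitney test.
* **Nodal statistics**: per node and metric, the linear mixed model
  `value ~ group + session + (1 | subject)` with Satterthwaite tests and
  Tukey-adjusted pairwise contrasts gated on the omnibus phenotype test.

See `vignettes/msconn-methods.Rmd` for the full model description and all
numerical conventions.

## Worked example

```r
library(msconn)

# small illustrative cohort: 3 groups, 6 subjects each, 2 sessions
cfg <- cohort_config(
  groups = data.frame(group = c("HC", "RR", "SP"),
                      n_subjects = 6L, n_sessions = 2L,
                      severity = c(0, 0.45, 1)),
  seed = 42)
cohort <- generate_cohort(cfg)
cohort[[1]]$matrix
#> <connectivity_matrix: 84 nodes, 1404 positive edges, total fiber count 24002>

g <- threshold_graph(cohort[[1]]$matrix, tau = 0.35)
g
#> <brain_graph: 84 nodes, 1220 edges, weighted, tau = 0.35>

strength <- node_degree(g, weighted = TRUE)
head(sort(strength, decreasing = TRUE), 3)
#>   lh.frontal.01 lh.cingulate.04   rh.frontal.07
#>             772             749             715

tbl <- build_metric_table(cohort, tau = 0.35)
slice <- subset(tbl, node == "lh.frontal.01" & metric == "degree" & weighted)
fit <- fit_node_lmm(slice, reference = "HC")
fit
#> <lmm_fit: 3 groups, phenotype p = 4.734e-05, session p = 0.6082, converged>
posthoc_contrasts(fit)
#>   contrast estimate       se   p_adjusted
#> 1  HC - RR 145.5833 74.23432 1.562863e-01
#> 2  HC - SP 467.7500 74.23432 4.000315e-05
#> 3  RR - SP 322.1667 74.23432 1.589303e-03
```

The thresholded healthy-control graph keeps exactly the 1220 strongest
connections. The mixed model on this region's weighted degree (strength)
finds a clear phenotype effect: strength drops by ~468 fibers from HC to
the severe SP group and by ~322 from RR to SP (Tukey-adjusted p < 0.002),
while HC vs the milder RR group is not significant at these sample sizes —
the graded degradation the generator plants and the nodal analysis is
designed to detect.

Classification on a larger synthetic cohort (30 subjects × 3 sessions per
patient course) with `cross_validate(cohort, ms_tasks()$four_class,
condition = "identity", weighted = TRUE)` reaches a mean macro F-measure
around 0.9, and weighted graphs outperform their binarized counterparts —
the qualitative pattern expected when edge weights carry group
information.

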