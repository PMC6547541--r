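---
title: "Inferring single-cell regulatory networks in Z-score space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring single-cell regulatory networks in Z-score space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scregnet)
```

## The problem

Drop-out events — expressed transcripts recorded as zeros for technical
reasons — are the dominant artifact of single-cell RNA-seq. Two genes that
are genuinely co-expressed in the same cell type frequently suffer mutually
exclusive drop-outs, so Pearson, Spearman or Cosine coefficients computed on
(normalized) counts find almost nothing at realistic sparsity levels.
`scregnet` sidesteps the problem with a change of variable: each gene is
represented not by its expression vector over cells but by its vector of
signed differential-expression Z-scores over all pairs of cell clusters.
Correlated genes follow similar patterns of differential expression between
cell sub-types, and those patterns survive dropout because each Z-score
aggregates evidence over whole clusters.

## The pipeline

1. **Normalization.** Every cell is scaled to the mean library size. Genes
   detected in fewer than `min_cells` cells (default 5) are masked out of
   DE and correlation; the container retains them for bookkeeping. The
   threshold is a package choice — common practice puts it between 3 and 10
   detecting cells — and is exposed as a parameter.
2. **Recursive clustering.** Cells are split by Ward (`ward.D2`)
   hierarchical clustering; each resulting cluster is re-clustered with its
   own freshly selected highly variable genes until no meaningful
   separation remains. The per-branch HVG re-selection is the point:
   a single global HVG set describes only the major cell types, and
   sub-types are invisible in it.
3. **Noise model + pairwise DE.** For every pair of leaf clusters, every
   cell of one cluster is compared against every cell of the other; a
   numerical noise model converts each fold-change into a p-value, and the
   signed `-log10` p-values are summed into a per-gene raw score, which is
   standardized against a reshuffled-label null into `Z_num`. An
   independent tie- and continuity-corrected Wilcoxon rank-sum Z is merged
   in quadrature: `|Z_final| = sqrt(Z_num^2 + Z_wilcoxon^2)`, rewarding
   genes that both tests agree on. The sign is taken from `Z_num`, falling
   back to the Wilcoxon sign when `Z_num` is zero.
4. **Correlation + thresholds.** Pearson, Spearman and Cosine coefficients
   are computed between gene Z-profiles; the combined coefficient is the
   worse (smaller-magnitude) of Pearson and Cosine when they agree in sign
   and zero otherwise. The top 0.1% of pairs by absolute combined
   coefficient become candidate edges; the magnitude of the last admitted
   pair is the adaptive threshold `rho_thresh`, and kept pairs with
   `|rho_s| < |rho_thresh - 0.15|` are vetoed by the Spearman control.
5. **Network.** Edges where neither endpoint is an annotated regulator of
   gene expression are discarded (GO sub-setting); isolated nodes and
   components below 1% of the current node count are pruned to a fixpoint.
   Summary statistics mirror the usual per-network report: density
   (edges/nodes), component count, average shortest path on the largest
   component, fast-greedy modularity, and a bootstrap Kolmogorov–Smirnov
   p-value for a discrete power-law fit to the degree sequence.
6. **Analytics.** Five node centralities (degree, normalized betweenness,
   per-component normalized closeness, PageRank at damping 0.85,
   eigenvector on the largest component), absolute centrality deltas
   between two conditions (top 1000 by |delta|), strict consensus shifts
   across all five metrics, and correlation-inversion detection
   (sign flips; "strong" when `rho_a - rho_b` exceeds 1 in magnitude).

## Design choices in the open spots

**Noise model internals.** Pseudo-replicate groups are formed greedily from
the most mutually similar cells (Spearman correlation over the 200 most
expressed genes, threshold at the 90th percentile of the similarity
distribution, group size 5, at most 20 groups). All within-group cell pairs
contribute log2 fold-changes, binned into 15 expression-level bins by the
pair's log2 mean; a fold-change's p-value is its add-one-smoothed two-sided
empirical tail within its bin, so `p = 1` at zero change and the floor is
`1/(N_bin + 1)`. Datasets too small or heterogeneous for grouping can use a
Poisson null (`noise_model_poisson()`), which emulates pure counting noise.

**Raw-score standardization.** The null is estimated from 3 random
within-pool label permutations. The per-gene null mean is the mean of the
permuted scores. The per-gene null standard deviation is pooled across
genes as `c * m_g` — linear in the gene's effective number of comparisons
`m_g` (cell pairs in which the gene is detected at least once) — because a
per-gene estimate from 3 draws would be hopelessly noisy; `c` carries a
`sqrt(1 + 1/R)` inflation because the null mean is itself estimated from
`R` draws. Counting detection in at least one (rather than both) cells of
a pair is a choice; both variants are defensible and the one-sided variant
is exposed through the code.

**Calibration.** On homogeneous data split at random, `Z_num` and
`Z_wilcoxon` are individually close to unit normal. The merged score's
null variance is then forced to `E[Z_num^2] + E[Z_wilcoxon^2] ≈ 2` by the
quadrature formula itself — the merged sd concentrates near `sqrt(2)`,
which is what the calibration tests check.

**Tree cutting.** Cut heights are evenly spaced fractions of the tree
height (level k cuts at `(1 - k/10)` of the maximum merge height), ordered
root-to-leaves so cluster counts never decrease with the level index.
Spacing the levels on the height axis rather than on the merge-height
multiset matters: almost all merges sit near the leaves, so multiset
deciles would always land deep in the tree and the shallow, major-cluster
cuts would be unreachable. At the first pair of consecutive increases in
the count sequence the tree is cut just before the first of the two; if
the pattern never occurs we cut at the median level. "Two increases in a
row" is read as two *consecutive* increases. Heterogeneity of a small branch is proxied by its chosen cut
level: level 6 of 9 or deeper counts as heterogeneous and licenses
re-clustering below `2 * min_size` cells. `min_size` defaults to 50 below
5000 cells and `n/100` above, scaling the documented example. Children
smaller than `min_size` merge into the sibling with the nearest centroid.
If the root split comes back with a single cluster, the root tree is cut
into two instead: the Z-score stage is undefined with fewer than two
clusters, and a forced binary split at the root is the least-surprising
fallback.

**Distances.** Cell-cell distance is 1 − Pearson over the branch's HVG
log2 expression. Correlation distance is scale-robust and standard for
expression data; Euclidean distance on raw counts would be dominated by
the few most abundant genes.

**Combination rules.** A sign conflict between Pearson and Cosine yields a
combined coefficient of 0: "the worst of the two" has no natural value
across signs, and zero is conservative. Boundary ties at the adaptive
threshold are all kept, making the kept set deterministic across
platforms. The Spearman bound uses `|rho_thresh - 0.15|` exactly as
written.

**Power-law goodness of fit.** Discrete maximum-likelihood fit with
KS-minimizing `xmin` (igraph's plfit), p-value from 200 semi-parametric
bootstrap replicates in the Clauset style: data below `xmin` resampled
empirically, tail drawn from the fitted law, refit, and the p-value is the
fraction of replicates whose KS statistic reaches the observed one.

## The synthetic generator

`simulate_counts()` draws a Splat-style hierarchy: gamma baseline gene
means (shape 2, scale 12), per-cluster DE factors (each cluster moves a
random 30% of genes 4-fold up or down), log-normal library factors
(sd 0.25), and negative-binomial counts at dispersion 0.3 over 2000 genes,
1000 cells and 5 equal clusters. Ten planted modules of ten genes share a
single cluster profile each, making their reference correlations true
positives by construction. The truth set is every gene pair with
`|Pearson| > 0.8` on `log2(count + 1)` of the pre-dropout reference.

Dropout is Bernoulli thinning whose keep-probability is logistic in the
*entry-level* underlying log mean (with unit slope this is the
Michaelis–Menten detection curve `mu / (mu + M)`): lowly expressed
transcripts drop out more, and a gene's detection rate tracks its true
expression in each cell, which is how empirical dropout behaves. The
intercept is calibrated by bisection so the realized zero fraction lands
within one percentage point of the target. A uniform mode exists for
ablation. When degrading an existing matrix (`add_dropout()`), the
observed count stands in for the unknown underlying mean.

The generator emulates clustered NB counts with planted co-regulation and
tunable sparsity. It does not emulate batch effects, doublets, cell-cycle
structure, continuous differentiation trajectories, or realistic
library-size distributions of specific platforms — so passing benchmarks
here show robustness to dropout and cluster granularity, not to every
artifact of real data.

## Problem sizes and numerical notes

The dropout-recovery benchmark runs 10 simulation repetitions of
2000 genes × 1000 cells at two degradation levels (88% and 97% zeros),
the scale at which the recovery behavior stabilizes while remaining
desk-computable. Unit and property tests run on matrices of a few hundred
genes and cells. The pairwise DE kernel enumerates only non-zero value
pairs (zero-zero pairs score 0 and zero-nonzero pairs are weighted by the
opposite group's zero count), so its cost scales with the squared non-zero
density rather than `n1 * n2`; a brute-force reference implementation is
kept for equivalence tests at 1e-9. Null standard deviations are floored
at 1e-8; empirical p-values are add-one smoothed everywhere (permutation p
cannot be 0); clusters with fewer than two cells are merged into the
nearest cluster by centroid correlation before DE. The correlation stage
needs at least three cluster-pair comparisons; if a heavily degraded
matrix clusters into fewer than three leaves, the pipeline retries the
clustering once at half the partition size before raising an error.

## Known limitations

- The adaptive threshold assumes the candidate-pair pool is large; with
  very few genes the top-0.1% rule keeps almost nothing.
- Closeness centrality is normalized within components and is therefore
  incomparable across very differently fragmented networks.
- Modularity values depend on the community algorithm (fast-greedy here)
  and should be compared only within one convention.
- The ES statistic is infinite when a hub set contains no essential or no
  non-essential genes; the Haldane-corrected companion value is reported
  alongside.
- Centrality deltas carry no significance measure; they are ranked
  magnitudes by design.
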