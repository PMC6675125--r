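---
title: "Methods: tree-ensemble scoring of miRNA-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-ensemble scoring of miRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdforest)
```

## The prediction problem

Curated databases record a few thousand experimentally supported
miRNA-disease associations -- a binary matrix $Y \in \{0,1\}^{nm \times nd}$
in which only a few percent of entries are 1 and the 0 entries are
*unlabeled*, not negative. The task is to rank the unlabeled pairs so that
true-but-unrecorded associations surface at the top. The working premise is
guilt by association: functionally similar miRNAs tend to be involved in
phenotypically similar diseases.

`mdforest` scores every candidate pair with an ensemble of CART regression
trees. Each base learner sees all known positives, its own uniformly drawn
balanced negative sample, a random subset of the feature catalog, and a
per-side principal-component projection; the pair score is the average of
the tree outputs, hence always in $[0,1]$.

## Similarity models

**Disease semantic similarity.** Each disease maps to a term in an ontology
DAG; its DAG is the ancestor closure $T(D)$. Model 1 assigns the disease's
own term contribution 1 and each ancestor $\Delta$ times the best
contribution among its children inside the DAG
($\Delta = 0.5$ by default, so a direct parent contributes 0.5, a
grandparent 0.25). The semantic value $DV1(D)$ is the sum over $T(D)$, and

$$SS1(i,j) = \frac{\sum_{t \in T(i) \cap T(j)} \left(D1_i(t) + D1_j(t)\right)}
                 {DV1(i) + DV1(j)}.$$

Model 2 replaces the position-based contribution with information content,
$D2(t) = -\log\!\big(\#\text{DAGs containing } t \,/\, \#\text{diseases}\big)$
(natural log; the base cancels between numerator and denominator of the
similarity, so it only affects the stored contribution maps). A term found
in every DAG is uninformative and contributes 0. When two distinct diseases
both have semantic value 0 -- every shared term in every DAG -- the ratio is
0/0; we define the off-diagonal similarity as 0 and the diagonal as 1.

**Interaction-profile kernels.** For entities without ontology or
functional-similarity coverage, similarity falls back to a Gaussian kernel
on association profiles,
$GM(i,j) = \exp(-\gamma_m \lVert Y(i,\cdot) - Y(j,\cdot)\rVert^2)$ with
$\gamma_m = \gamma' / \tfrac1{nm}\sum_i \lVert Y(i,\cdot)\rVert^2$, and the
column analogue for diseases. $\gamma' = 1$ by default (the customary
choice of the kernel's source literature); both bandwidths are computed
independently from their own side of $Y$. An all-zero $Y$ leaves the
bandwidth undefined and is an error.

**Integration.** $SD$ is the mean of the two semantic models where both
diseases have DAGs and $GD$ elsewhere; $SM$ is functional similarity where
both miRNAs have it and $GM$ elsewhere. A DAG-bearing pair whose ancestor
sets are disjoint keeps its semantic value of 0 rather than falling back to
the kernel: 0 is a legitimate similarity, and switching branches on the
*value* rather than on data availability would make the integration rule
discontinuous in the inputs.

## Feature catalog

The source method delegates its feature list to an unpublished catalog, so
the concrete catalog here is this package's own documented instantiation,
32 features per side in fixed order:

* **statistical (13)** -- off-diagonal similarity-row sum and mean, a
  10-bin equal-width histogram of the row over $[0,1]$ normalized to
  proportions, and the association degree;
* **graph-theoretic (6)** -- on the weighted similarity graph (self-loops
  removed, path distance $1 - s$): count of neighbors above the mean
  off-diagonal similarity, mean similarity of the 5 nearest neighbors,
  weighted betweenness, harmonic closeness (the harmonic form handles
  disconnected graphs without special-casing), leading-eigenvector
  centrality, and PageRank. The eigenvector is computed with a dense
  symmetric eigendecomposition rather than ARPACK because ARPACK's random
  start breaks bit-level reproducibility;
* **factorization (13)** -- truncated SVD of $Y$ at rank 11, each entity's
  singular vector scaled by the singular values (zero-padded when $Y$ has
  lower rank), plus its degree and normalized degree.

The graph block runs on the *weighted* similarity graph rather than a
thresholded binary one; a threshold would be an arbitrary extra parameter,
and the neighbor-count feature already supplies a thresholded view. The
factorization block is per-entity (degrees and latent factors) because the
feature matrices are per-entity by construction; pair-level interaction
information reaches the trees through the spliced latent factors.

Every feature matrix carries a fingerprint of the exact $Y$ it was computed
from, and both training and scoring refuse mismatched fingerprints. This
guards the easiest mistake in cross-validation of this method: forgetting
that *all three* feature blocks (directly, or through the kernels inside
$SM$/$SD$) depend on $Y$ and must be recomputed after every fold mask.

## Base learner and ensemble

With $P$ the positive pairs and $U$ the unlabeled ones, each of the $M$
(default 50) base learners:

1. draws $N \subset U$, $|N| = |P|$, uniformly without replacement
   (a per-disease variant used by the negative-sampling comparison draws
   each disease's negatives to match its positive count);
2. samples $d_1 = \lfloor r \cdot d \rfloor$ feature indices (default
   $r = 0.8$, $d_1 = 25$), the same index set for both sides;
3. fits a centering-only PCA per side on the subset columns over *all*
   entities of that side (labels are not used, so there is no leakage) and
   keeps $\min(10, d_1)$ components, giving a spliced pair representation
   of $d_2 = 20$ dimensions at the defaults;
4. grows a CART regression tree on the $d_2$-dimensional pair vectors with
   0/1 targets: exact squared-error-minimizing splits, candidate thresholds
   at midpoints between consecutive distinct feature values, ties broken to
   the smallest feature index then smallest threshold, `x <= s` routed
   left, grown until nodes are pure or unsplittable (no depth cap by
   default; `min_samples_split`, `min_impurity_decrease` and `max_depth`
   are exposed). Leaves predict their training-target mean.

Per-learner randomness comes from streams seeded `seed + k`, so enlarging
$M$ never reshuffles earlier learners and every run is reproducible from
one master seed. Setting `use_pca = FALSE` reproduces the
dimensionality-reduction ablation (the subset features are spliced
directly), and `mode = "rf"` reproduces the bagging baseline: one fixed
negative set, bootstrap resampling of the training pairs per tree, all
features, no PCA.

The split search is implemented twice: a C++ scan used in production and a
pure-R scan retained as an independent second route; tests check both
against brute-force enumeration. When two splits attain *exactly* the same
loss (e.g. two features that isolate the same point set) the tie is
mathematically degenerate and the implementations may differ in which
equally optimal split they return; the tests therefore pin the optimal
loss always and the split itself only when it is unique.

## Evaluation protocols

All protocols mask positives in $Y$, recompute kernels, integrated
similarities and features from the masked matrix, retrain the ensemble,
and rank held-out positives among candidates. AUC uses the Mann-Whitney
estimator (ties count one half), which the tests verify equals the
trapezoidal area under an explicitly threshold-swept ROC curve.

* **Global LOOCV** removes one positive at a time and ranks it against all
  unlabeled pairs. Because candidate pools are identical across held-out
  samples, the AUC is the mean per-sample normalized rank, and the
  reported ROC sweeps normalized-rank thresholds.
* **Local LOOCV** ranks the held-out pair only among its own disease's
  unlabeled pairs; candidate counts differ per disease, so the per-sample
  normalized-rank form is the natural pooling rule (the source experiment
  plots a single curve without stating one). Local AUC below global is an
  empirical observation, not an asserted invariant.
* **k-fold CV** (default $k = 5$, 10 repeats at desk scale, 100 in the
  source experiment) partitions positives into folds differing by at most
  one in size; the reported spread is the population standard deviation
  over repeats.
* **Label randomization** permutes all entries of $Y$ (preserving counts)
  and re-runs a protocol; scores should collapse to chance.

Full LOOCV retrains one ensemble per held-out positive, which is faithful
but quadratic in $|P|$; a `fast` mode trains once on the unmasked data and
only masks the candidate pool. It is an optimistic approximation (the
held-out pair is in its own training set) and is labeled as such.

## The synthetic world

The generator produces the three inputs with the statistical structure the
method assumes, so the whole pipeline is testable offline:

* $Y$: miRNAs and diseases split into `n_blocks` (default 3) groups; each
  entity draws a log-normal propensity (sdlog 1.3) and
  $\Pr[Y_{ij} = 1] \propto a_i b_j \cdot \text{boost}$, boosted by
  `contrast` (default 20) within a block, scaled so the pre-truncation
  mean equals `density` (default 0.20 at the default 60 x 40 panel) with
  individual probabilities capped at 0.95 -- under the heavy-tailed
  propensities the realized positive rate is therefore lower, about 0.12
  at the defaults; every entry then flips with probability `noise`
  (default 0.005).
* Functional similarity: Beta(5,2) within blocks, Beta(2,5) across,
  symmetrized, unit diagonal; 10% of miRNAs are flagged as uncovered.
* Ontology: a shared term tree (depth 3, branching 2); each covered
  disease hangs its own leaf under its block's branch with probability
  0.8 (otherwise uniformly), occasionally with a second parent forming a
  diamond; 10% of diseases have no DAG.

Calibration rationale, fixed once: the propensity dispersion matches the
degree dispersion of the curated human dataset the method was built for
(median miRNA degree around 5 against maxima above 100 implies a
log-normal sigma near 1.3); the default density leans toward that
dataset's *per-entity degrees* (about 11 per miRNA, 14 per disease; the
default target realizes roughly 5 and 7.5 at the 60 x 40 panel) rather
than its raw 2.9% positive fraction, which at desk scale would leave most
entities with zero or one association and make every fold mask an
entity-orphaning event; and
the flip rate reflects a curated database's low annotation-error rate
(1% flips would make roughly a fifth of all positives spurious). An
earlier draft that generated the ontology independently of the planted
blocks, and planted blocks with no degree heterogeneity, produced a world
the method provably cannot learn: block membership then has zero marginal
effect on the label, and a greedy axis-aligned split search cannot enter a
pure interaction (XOR-like geometry). Degree heterogeneity plus
block-aligned similarity is precisely the structure the guilt-by-
association premise describes.

What a green test establishes: that the pipeline recovers planted
propensity-and-block structure far above chance, collapses to chance under
label randomization, and preserves the published orderings
(with-PCA above without, fresh global negatives above per-disease
negatives, fresh-negative ensemble above bagging). What it does not
establish: the published AUC magnitudes, which come from a specific real
dataset thousands of retrainings deep and are out of desk-scale reach.

## Numerical choices and limitations

* Similarity matrices are symmetrized and clipped against rounding;
  invariant tests use absolute tolerance 1e-9 (1e-12 where exactness is
  structural).
* Midpoint thresholds can round onto the upper neighbor for adjacent
  floating-point values; a split that would empty a child is rejected and
  the node becomes a leaf.
* Sampled negatives may later be scored as candidates -- all unlabeled
  pairs are ranked, as in the source method.
* The unlabeled-as-negative assumption biases scores downward for
  soon-to-be-confirmed associations; no correction is attempted.
* Config files are JSON (no YAML parser in the supported stack); matrices
  travel as labeled TSV, ontologies as child-parent edge lists.
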