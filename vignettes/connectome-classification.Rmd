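---
title: "Classifying depression from structural connectome graph metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying depression from structural connectome graph metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis this package implements

Tractography on diffusion-weighted MRI yields, for each subject, a
weighted structural connectome: a symmetric 68 × 68 matrix of fiber
counts over the bilateral Desikan–Killiany cortical parcellation.
Univariate comparisons of single whole-brain graph metrics have not
distinguished depressed from healthy individuals; the design
implemented here instead asks whether a *pattern* across nine global
graph metrics is discriminative, using a linear support vector machine
(SVM), and then asks which metric carries the signal and which
individual regions show abnormal connectivity.

The pipeline, end to end:

1. **Preprocessing.** Each subject's weight matrix is min–max
   normalized over its off-diagonal entries (removing per-subject
   fiber-count scale), thresholded so that only the strongest 25% of
   all possible edges survive (so every subject has exactly
   `floor(0.25 * 68 * 67 / 2) = 569` edges), and binarized.
2. **Graph metrics.** Nine global metrics per subject: assortativity,
   global flow coefficient, global total flow, global betweenness,
   global efficiency, modularity, characteristic path length,
   transitivity, and small-worldness.
3. **Univariate inference.** Permutation two-sample t-tests per metric
   (100,000 label shuffles by default), Benjamini–Hochberg FDR at
   q = 0.05 across the nine tests.
4. **Classification.** A class-weighted squared-slack linear SVM under
   leave-one-out cross-validation (LOOCV), evaluated by an exact
   two-sided sign test on the fold successes.
5. **Feature evaluation.** All 511 nonempty subsets of the nine
   metrics are cross-validated; per-subset sign tests; the count of
   significant subsets is tested against the 5% chance expectation by
   a two-sided binomial test; accuracies are aggregated per metric,
   and |w|-based feature ranks are averaged across folds of the
   full-feature model.
6. **Regional inference.** Degree centrality per region, permutation
   t-tests over 68 regions, FDR at q = 0.05.

## The SVM model

With features $x_i \in \mathbb{R}^d$ and labels $y_i \in \{-1, +1\}$
(−1 patient, +1 control), the classifier solves

$$\min_{w, b, v} \; \tfrac{1}{2}\langle w, w\rangle + \sum_i D_i v_i^2
\quad \text{s.t.} \quad y_i(\langle w, x_i\rangle + b) \ge 1 - v_i,\;
v_i \ge 0,$$

with per-sample penalties $D_i = N / (2 N_{G(i)})$, where $N_{G(i)}$
is the size of sample $i$'s group. Summed over a class the penalties
equal $N/2$, so an imbalanced cohort (e.g. 18 controls, 14 patients)
contributes equal total penalty mass per class. Two points deserve
emphasis because most SVM libraries differ:

* the slack penalty is **squared** (L2), not the hinge (L1) most
  library defaults use; and
* the penalties are per-sample class weights, not a single scalar C.

`cwsvm()` solves the primal directly by a damped Newton iteration on
the differentiable piecewise-quadratic objective; the iteration is
deterministic (no random initialization) and typically converges in a
handful of steps, each solving a $(d{+}1)$-dimensional linear system.
KKT residuals are stored on the fitted object. The test suite checks
the solution against an independent interior-point solution of the
dual on random problems.

```{r}
library(connectoclass)
x <- matrix(rnorm(32 * 9), 32, 9)
y <- rep(c(1, -1), c(18, 14))
fit <- cwsvm(x, y)
summary(fit)
cv <- loocv(x, y)   # per-fold standardization, training folds only
cv
```

Feature standardization inside cross-validation is on by default
(`scale = TRUE`): the nine metrics differ by orders of magnitude
(global total flow ~100, transitivity ~0.3), and an unscaled linear
SVM would be dominated by whichever feature has the largest variance.
Scaling statistics are computed from the training folds only and
applied to the held-out subject, never the reverse; a construction
test asserts that an extreme outlier in the held-out position cannot
influence its own fold's scaling. `scale = FALSE` is available for
sensitivity analysis.

## Metric conventions

Where a metric admits more than one textbook convention, the package
fixes one and documents it:

* **Flow coefficient** of a node v counts the *unlinked* neighbor
  pairs of v — those whose length-two connection through v is a
  genuine shortest path — divided by all $k_v(k_v-1)/2$ neighbor
  pairs. Counting all neighbor pairs would make the coefficient
  identically 1. Nodes of degree < 2 have flow 0. Global total flow is
  the mean count (not fraction) of such bridged pairs per node.
* **Betweenness** is unnormalized (raw shortest-path fractions summed
  over pairs); global betweenness is the node average. At 68 nodes and
  25% density, values near 60 are typical — the scale only makes sense
  unnormalized.
* **Characteristic path length** averages over reachable pairs only
  and warns on disconnected graphs. The 569-edge whole-brain graphs
  are essentially always connected; the convention only matters for
  degenerate inputs.
* **Transitivity** is the collectively normalized ratio
  3 · triangles / connected triplets, rather than the mean of per-node
  clustering coefficients, which over-weights low-degree nodes.
* **Small-worldness** is the ratio of means, not mean of ratios:
  $S = (T/\overline{T}_{null}) / (L/\overline{L}_{null})$ over 10
  degree-preserving null graphs by default. Null graphs are produced
  by double-edge swaps (10 · |E| attempted swaps), which preserve the
  degree sequence exactly.
* **Modularity** is averaged over 10 runs of a stochastic
  Louvain-style optimizer (greedy local moves, including detaching a
  node into a singleton community, over a randomized node order,
  alternated with community merges). For graphs of at most 7 nodes the
  optimizer is replaced by an exact search over the complete partition
  space (Bell(7) = 877 partitions), which is deterministic and
  provably optimal; stochastic local search cannot guarantee the
  optimum even on 6-node graphs, and the exact branch is what makes
  brute-force oracle testing of this metric meaningful. At realistic
  sizes the stochastic average is reported, which is also why the
  metric takes a seed.

Every stochastic operation takes an explicit seed; cohort-level
drivers derive per-subject sub-seeds deterministically from a master
seed, so whole runs are reproducible bit for bit.

## The sign test and its threshold

A subset of metrics is called significant when its LOOCV fold
successes reach `sign_test_threshold(n)`. The exact two-sided sign
test p-value at 22 of 32 folds is 0.0501; the conventional 22-of-32
criterion is therefore reproduced only when the p-value is rounded to
two decimals before comparison with α = 0.05. Both policies are
first-class: `round_digits = 2` (default) gives the threshold 22,
`round_digits = NULL` gives the strict threshold 23. The two-sided
convention is 2 · min(lower tail, upper tail), capped at 1.

The across-subset binomial test treats the 511 subset outcomes as
draws from Binomial(511, 0.05) under chance. The subsets share data
and are strongly correlated, so this test is anti-conservative taken
literally; it is reproduced as designed, and the synthetic null
calibration in the test suite only asserts one-sided sanity for it.

## Permutation inference

`permutation_t()` implements the literal shuffle-the-labels scheme:
the observed two-sample pooled-variance t-test p-value is compared
against the p-values of `n_perm` random label shuffles. With fixed
group sizes this ordering is equivalent to comparing |t| itself. The
reported p uses the add-one estimator (#{shuffle p ≤ observed p} + 1) /
(n_perm + 1), which cannot be exactly zero; the raw proportion is
available as `estimator = "raw"`. Welch's statistic is available via
`var_equal = FALSE`.

One practical consequence of finite permutation resolution: the
smallest attainable p is 1/(n_perm + 1), and the Benjamini–Hochberg
rank-1 cutoff across 68 regional tests is q/68 ≈ 7.4 × 10⁻⁴, so the
regional analysis needs n_perm ≳ 1400 before *any* region can survive
FDR. This is why the design's default is 100,000 shuffles, and why
reduced-n_perm test runs use at least 4,999 shuffles for
FDR-dependent checks.

## The synthetic cohort generator

No connectivity data are distributed with this package; a generator
produces cohorts whose ground truth is known, so that every stage can
be validated by parameter recovery rather than by reference outputs.

The generator builds a single weighted template shared by the cohort:
a Chung–Lu-style skeleton whose expected degrees are heterogeneous
(log-normal attractiveness, sd 0.6 on the log scale) at a configurable
edge density, with log-normal weights on present edges. Defaults are
chosen once to emulate the study conditions this design targets:
18 controls and 14 patients, 68 nodes, base density 0.40 (comfortably
above the 0.25 analysis threshold), median edge weight 50 (≈45,000
streamlines spread over ~900 template edges), and multiplicative
log-normal subject noise with sd 0.25. Clinical covariates are drawn
uniformly within clinically realistic ranges (BDI-II 22–43, GAF
35–60, onset age 3–26, years since onset 3–39 for patients; BDI-II
0–11, GAF 75–99, onset fields absent for controls), with no
covariate–topology coupling unless requested.

Group effects act on the template *before* subject noise, so an
effect size has a single unit (template weight mass):

* `nodal_effect`: a signed fractional change of the weights on all
  edges incident to a named region, applied to the patient group's
  template — the planted analogue of a regional degree abnormality;
* `global_effect`: a fraction of the patient template's edges rewired
  at random, perturbing global topology while leaving the weight
  distribution intact.

What the generator does *not* emulate: spatial embedding and
distance-dependent connection probabilities, hemispheric symmetry,
true inter-regional weight correlations, or any acquisition artifact.
Consequently, passing tests demonstrate that the pipeline recovers
planted effects under a plausible degree-heterogeneous null — not
that the method would attain any particular accuracy on real
tractography data. Because a template effect is shared by all
patients, even small global perturbations (a 1–2% rewiring) are
strong signals relative to subject noise; planted-effect test
conditions are chosen in that regime deliberately.

## Numerical and degenerate-input policies

* Constant off-diagonal weight matrices cannot be min–max normalized
  and raise an error rather than silently producing an empty or full
  graph.
* Threshold ties at the cutoff weight are broken deterministically by
  (lower node index, lower partner index) after sorting by weight
  descending, so results are identical across runs and platforms.
* Edge-count rounding is `floor`, so realized density never exceeds
  the requested sparsity. The threshold basis is all n(n−1)/2
  possible pairs by default; `basis = "nonzero"` switches to observed
  nonzero edges.
* Metrics that are undefined for a graph (assortativity of a regular
  graph, transitivity without triplets, modularity of an edgeless
  graph, small-worldness with degenerate nulls) return `NA` with an
  `undefined_metric`-classed warning; the feature table records them
  as missing per subject.
* Graphs admitting no degree-preserving swap (stars) are returned
  unchanged from the randomizer with a warning.
* Sign-test threshold rounding is explicit (see above) because the
  22-of-32 criterion is irreproducible without it.

## Problem sizes used in the shipped tests

The test suite validates calibration and recovery properties by Monte
Carlo at sizes chosen for quick execution: null-calibration cohorts
run at 30 nodes with 8 + 8 subjects over 24 replicates; the planted
nodal-effect recovery runs 5 full-size (68-node, 18 + 14) cohorts at
4,999 shuffles; small-worldness regime checks use 25 seeded runs; the
brute-force oracle comparison covers every connected graph on up to 6
nodes (one representative per isomorphism class — 142 graphs — since
all metrics are proven label-invariant separately). The acceptance
script runs full-size cohorts at 9,999 shuffles. The pipeline's
analysis defaults (100,000 shuffles, 10 modularity runs, 10 null
graphs) are unchanged by any of this.

## Known limitations

* The exhaustive 511-subset evaluation refits 511 × N SVMs; at the
  default cohort size this is ~16,000 fits and takes on the order of
  half a minute. Larger cohorts scale linearly in folds.
* The across-subset binomial test and the accuracy-vs-chance t-test
  inherit the independence idealizations of the original design;
  both are reported as designed, with the caveat documented here.
* Permutation tests shuffle labels freely and therefore assume
  exchangeability under the null; covariate-adjusted permutation
  schemes are out of scope.
* Only binarized, undirected graphs are analyzed; weighted or
  directed metric variants are deliberately absent.
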