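# connectoclass

Graph-theoretic classification of two-group structural connectome
cohorts — built for the question of whether depression leaves a
multivariate signature in whole-brain white-matter networks even when
no single network metric differs between groups.

Each subject enters as a weighted, symmetric 68 × 68 fiber-count
matrix over the bilateral Desikan–Killiany cortical atlas. The
package:

1. normalizes, sparsity-thresholds (top 25% of possible edges) and
   binarizes each matrix, so every subject has the same edge count;
2. computes nine global graph metrics per subject — assortativity,
   global flow coefficient, global total flow, global betweenness,
   global efficiency, modularity, characteristic path length,
   transitivity, and small-worldness (normalized against
   degree-preserving random null graphs);
3. compares each metric between groups by permutation t-tests with
   Benjamini–Hochberg FDR control;
4. classifies patients vs. controls with a class-weighted
   squared-slack linear SVM under leave-one-out cross-validation,

   minimize ½⟨w,w⟩ + Σᵢ Dᵢvᵢ² subject to yᵢ(⟨w,xᵢ⟩ + b) ≥ 1 − vᵢ,
   vᵢ ≥ 0, with Dᵢ = N / (2·N_G(i)),

   so both groups carry equal total penalty mass;
5. evaluates all 511 nonempty subsets of the nine metrics with exact
   sign tests per subset, a binomial test on the number of
   significant subsets, per-metric accuracy aggregation, and
   |w|-based feature-weight ranking; and
6. compares regional degree centrality between groups across all 68
   regions with permutation tests under FDR control.

Because no cohort data ship with the package, a synthetic-cohort
generator produces fiber-count matrices from a degree-heterogeneous
weighted template with plantable group effects (regional degree
shifts, global topology perturbation), so the entire pipeline is
testable by parameter recovery.

## Worked example

A full run on a synthetic cohort of 18 controls and 14 patients in
which 2% of the patient group's template edges are rewired (a purely
global topological effect):

```r
library(connectoclass)

cfg <- run_config(
  mode   = "synthetic",
  cohort = cohort_config(n_control = 18, n_mdd = 14, global_effect = 0.02),
  n_perm = 9999, seed = 42)
run <- run_pipeline(cfg)
print(run)
#> Connectome classification run
#>   cohort          : 18 controls + 14 patients, 569 edges/graph
#>   full model      : 78.12% accuracy (25/32; sign test p = 0.0021)
#>   subsets         : 415 of 511 significant (binomial p = 0)
#>   univariate FDR  : 5 of 9 metrics significant
#>   regional FDR    : 18 regions significant
```

Reading this: the nine-metric SVM classified 25 of the 32
leave-one-out folds correctly (78.12%), which an exact two-sided sign
test puts well past the 22-of-32 significance threshold; 415 of the
511 feature subsets reached that threshold, far beyond the ~26
expected by chance. Because the planted effect here rewires the
template shared by all patients, it is a strong signal — it also
moves several global metrics univariately and shifts the degrees of
the rewired regions, which is why the univariate and regional stages
fire too. A null cohort (`global_effect = 0`) instead gives
chance-level accuracy and quiet inference stages.

Which metric carried the signal, aggregated over all subsets that
contain it, alongside its mean |w| rank in the full model (rank 1 =
most important):

```r
agg <- run$aggregates
agg[order(agg$mean_rank_full_model),
    c("metric", "mean_accuracy", "n_significant", "mean_rank_full_model")]
#>                      metric mean_accuracy n_significant mean_rank_full_model
#>                transitivity         77.86           248              1.18750
#>           global_total_flow         75.90           220              1.87500
#>                  modularity         78.65           241              2.96875
#>               assortativity         75.20           213              4.28125
#>             small_worldness         75.85           212              5.06250
#>     global_flow_coefficient         76.26           226              6.00000
#>           global_efficiency         74.23           204              7.34375
#>  characteristic_path_length         74.23           204              7.62500
#>          global_betweenness         74.23           204              8.65625
```

(`mean_accuracy` in percent over the 256 subsets containing each
metric.) Random rewiring destroys clustering first, so the
clustering-sensitive metrics (transitivity, modularity) dominate both
rankings for this kind of planted effect.

Every stage is also an exported function (`preprocess()`,
`compute_feature_table()`, `cwsvm()`, `loocv()`, `run_exhaustive()`,
`regional_degree_tests()`, ...), and a command-line wrapper lives at
`inst/cli/connectoclass.R`:

```sh
Rscript inst/cli/connectoclass.R --mode synthetic --seed 1 --out-dir results/
```

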