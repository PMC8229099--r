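# methylaml

DNA-methylation analysis of pediatric acute myeloid leukemia (AML) at
desk scale: classify cytogenetic subtypes from Illumina 450k-style
beta-value matrices, validate the classifier with a label-permutation
test, find subtype-specific differentially methylated CpGs, probe
intra-subtype heterogeneity, and relate within-subtype methylation
groups to relapse-free and overall survival.

## Who this is for

Computational biologists working with array methylation data
(beta values β ∈ [0, 1] per CpG site per sample, `NA` for failed
calls) who need a complete, reproducible subtype-classification and
outcome pipeline — and a synthetic-cohort generator that makes every
stage testable when the underlying patient data are restricted-access.

## The method

1. **QC**: mask calls with detection p ≥ 0.05, drop blacklisted /
   non-autosomal probes and CpGs with > 10% missing values, flag MDS
   outliers.
2. **Unsupervised CpG selection**: the union, over 5 seeded folds, of a
   PCA route (top 20 |loading| CpGs per component, first 15 components)
   and an LVHC route (drop variance < 0.1, then the lower-variance
   member of each pair with |r| > 0.7).
3. **Classification**: nine one-vs-rest classifier banks (nearest
   centroid, naive Bayes, kNN, ridge logistic, linear SVM, decision
   tree, random forest, gradient boosting, one-hidden-layer
   perceptron), compared by nested cross-validation (outer 5-fold for
   accuracy, inner 3-fold for hyperparameters), with median imputation
   fitted inside each training split. The winner is refit and predicts
   cytogenetically undefined samples; a class probability ≥ 0.8 flags a
   sample "subtype-suspected".
4. **Validation**: 1000 label permutations; p = (C+1)/(B+1).
5. **Differential methylation**: per-subtype Mann–Whitney one-vs-rest
   with Benjamini–Hochberg correction; subtype-unique CpGs by set
   difference.
6. **Heterogeneity**: Ward clustering of NK samples into clusters A/B;
   Fisher's exact and Welch t-tests against mutations, sex, age.
7. **Survival**: per subtype, screen CpGs relapse-vs-no-relapse
   (raw p < 0.05, top 50), cluster into high/low methylation groups,
   compare endpoints by Kaplan–Meier, log-rank, and Cox proportional
   hazards (Newton–Raphson, Breslow ties).

All statistical primitives (Mann–Whitney, BH, Fisher 2×2, Welch t,
Kaplan–Meier, log-rank, Cox) are implemented in the package and tested
against independent oracles. Trees are compiled (Rcpp); everything is
deterministic given a seed. See `vignettes/methylaml-methods.Rmd` for
the full model description and design choices.

## Worked example

```r
library(methylaml)

cfg <- simulation_config(n_cpgs = 3000, seed = 42)   # Table-1-style cohort
sim <- simulate_cohort(cfg)
pp  <- preprocess_beta(sim$beta, sim$detection_p)
fs  <- select_features(pp$beta, seed = 42)
print(fs)
#> FeatureSet: 578 CpG sites (PCA 578, LVHC 0, union over 5 folds)

sheet <- sim$sheet
labelled <- sheet$timepoint == "diagnosis" &
  sheet$reported_subtype != "undefined"
ids <- sheet$sample_id[labelled]
beta_fs <- beta_matrix(unclass(pp$beta)[fs$cpg_ids, ids])

report <- nested_cv_select(beta_fs, sheet$reported_subtype[labelled],
  model_specs = default_model_specs()[c("nearest centroid",
                                        "random forest",
                                        "k-nearest neighbors")],
  seed = 42)
print(report)
#> Nested cross-validation report (outer 5 / inner 3 folds)
#>   nearest centroid         mean accuracy 1.000
#>   random forest            mean accuracy 1.000
#>   k-nearest neighbors      mean accuracy 1.000
#> Best family: nearest centroid

clf <- fit_final(beta_fs, sheet$reported_subtype[labelled],
                 model_spec(report$best_family), seed = 42)
new_ids <- sheet$sample_id[sheet$reported_subtype == "undefined" &
                           sheet$timepoint == "diagnosis"]
pred <- predict_subtypes(clf,
          beta_matrix(unclass(pp$beta)[fs$cpg_ids, new_ids]))
head(pred, 4)
#>   sample_id predicted_subtype max_probability subtype_suspected
#> 1    AML100           inv(16)               1              TRUE
#> 2    AML101            sole+8               1              TRUE
#> 3    AML102           t(8;21)               1              TRUE
#> 4    AML103               MLL               1              TRUE

sg <- run_survival_stage(beta_matrix(unclass(pp$beta)[fs$cpg_ids, ]),
                         sheet, "NK")
print(sg)
#> Survival grouping for subtype NK - 30 samples, 26 selected CpGs
#> high  low
#>   19   11
#>   RFS log-rank p = 0.02372; OS log-rank p = 0.06651
```

With strong planted signatures (Δβ = 0.4 against noise SD 0.05) the
selected features separate all eight subtypes, so several families tie
at cross-validated accuracy 1.0 and the parsimony tie-break picks the
nearest-centroid bank. The undefined samples are re-assigned to their
hidden true subtype with high confidence, and the NK survival stage
recovers the planted methylation-linked hazard (log-rank p < 0.05 for
relapse-free survival on 30 samples).

The end-to-end pipeline (all stages, one seed, artifacts + manifest in
an output directory) is

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "runs/demo")
```

or from the command line

```sh
Rscript inst/cli/methylaml.R run-all --out runs/demo --seed 1
```

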