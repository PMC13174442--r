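# crossfc

Combining transcriptomic cohorts measured on different platforms — bulk
RNA-seq, NanoString, microarray, and pseudobulked single-cell RNA-seq — is
one of the few ways to reach useful sample sizes for outcome prediction in
rare, heterogeneous cancers such as high-grade serous carcinoma (HGSC).
`crossfc` implements a harmonization-and-modeling workflow for paired
pre/post-chemotherapy designs built around three ideas:

1. **Paired log2 fold-changes as the shared feature space.**  For patient
   *i* and gene *g*, the feature is
   `log2(post_gi + c) − log2(pre_gi + c)` on a normalized (CPM/RPKM/TPM)
   scale, which cancels patient- and assay-level scale biases that defeat
   raw-expression integration.
2. **Limits of detection from a double-assay design.**  When the same
   samples are measured on two platforms, per-gene Spearman correlations,
   binned by expression (and expression range) quantiles, locate the
   expression level where cross-assay concordance starts to decline
   ("loose" cutoff) and where it drops below ρ = 0.7 ("strict" cutoff).
   Genes below these limits are background-dominated and carry
   assay-specific artifacts rather than biology.
3. **Bootstrap predictive frequency for feature stability.**  Patients are
   resampled with replacement (balanced between outcome classes, weighted
   inversely to mini-cohort size), genes ranked by one-way ANOVA F-score,
   and each gene's *predictive frequency* is the fraction of bootstraps in
   which it lands in the top-*m*.  The top 25 candidates feed regularized
   logistic / linear-SVM classifiers of the progression-free-survival
   (PFS) class (> 12 vs ≤ 12 months), with a stratified hold-out,
   leave-one-out selection of the panel size k, per-mini-cohort AUROC
   reporting, and external validation through directionality checks,
   univariate Cox regression, Kaplan–Meier median splits, and cell-type
   log2FC–PFI correlations.  Focal-gene network context is contrasted
   between pre- and post-treatment topological-overlap (TOM) networks.

A first-class synthetic cohort generator (`generate_cohort()`,
`generate_double_assay()`) emulates the whole study design — unequal
mini-cohorts on two platforms, per-assay detection floors with fluctuating
background, microarray dynamic-range compression, single-cell capture
sparsity, planted PFS biomarkers and planted assay-discriminative genes —
with a `SyntheticTruth` record so that every stage can be tested for
recovery of known ground truth.

## Worked example

```r
library(crossfc)

cfg <- generator_config(seed = 42)        # 6 mini-cohorts, 140 patients,
sim <- generate_cohort(cfg)               # 770-gene panel
meta <- sim$meta

fcs <- lapply(names(sim$cohorts), function(cn) {
  co <- sim$cohorts[[cn]]
  compute_log2fc(normalize_expression(co$pre,  "CPM"),
                 normalize_expression(co$post, "CPM"),
                 meta[meta$mini_cohort == cn, ])
})
panel  <- Reduce(intersect, lapply(fcs, rownames))
fc_all <- paired_l2fc(do.call(cbind, lapply(fcs, function(f)
  unclass(f)[panel, ])), 1, "CPM")

labels    <- pfs_class_labels(meta)                    # > 12 months?
cohort_of <- setNames(meta$mini_cohort[match(colnames(fc_all),
                      meta$patient_id)], colnames(fc_all))
sp    <- make_holdout_split(meta[meta$patient_id %in% colnames(fc_all), ],
                            labels, seed = 1)
fc_tr <- paired_l2fc(unclass(fc_all)[, sp$train], 1, "CPM")

pft  <- bootstrap_predictive_frequency(fc_tr, labels, cohort_of,
                                       B = 100, top_m = 50, seed = 2)
cand <- rank_candidates(pft, max_features = 25)
mean(names(sim$truth$planted_pfs_genes) %in% cand)
#> [1] 1

model <- fit_final(fc_tr, labels, cand, "lasso_logistic")
evaluate_model(model, fc_all, labels,
               list(train = sp$train, holdout = sp$holdout))$report
#>    subset auroc   n
#> 1   train     1 126
#> 2 holdout     1  14
```

All 15 planted PFS biomarkers are recovered in the 25-gene candidate list
and the hold-out AUROC is 1 at the default planted effect of one log2
unit; weaker effects degrade both numbers gracefully.  The same machinery
run with assay identity as the outcome reproduces the bias-probe pattern:
a hold-out AUROC near 0.9 that collapses to chance (≈ 0.5) once genes
below the estimated limits of detection are removed (`genes_below_lod()`),
because the planted assay-discriminative genes all sit below the detection
floor.

The whole workflow can also be driven as one call:

```r
man <- run_pipeline(pipeline_config(generator = cfg, outdir = "run1",
                                    seed = 42))
write_report(man, "run1/report")
```

which writes per-stage TSV/JSON outputs, a checksummed manifest (reruns
with the same config and seed are bit-identical), and a markdown report.
A thin command-line wrapper lives at
`inst/scripts/crossfc-pipeline.R`.

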