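---
title: "Methods: cross-assay harmonization of paired fold-changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-assay harmonization of paired fold-changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossfc` models a recurring situation in translational transcriptomics:
several small cohorts of paired pre/post-chemotherapy tumor samples, each
measured on a different platform (bulk RNA-seq, NanoString, microarray,
single-cell RNA-seq), that must be combined into one cohort large enough
to train an outcome classifier.  This vignette documents the statistical
procedures, the choices made where the design was genuinely open, and
what the synthetic data generator does and does not emulate.

## The feature space: paired log2 fold-changes

For each patient the pipeline computes, per gene,
`log2(post + c) − log2(pre + c)` on a normalized scale (CPM by default;
RPKM/TPM when lengths are available).  The pairing cancels any
multiplicative factor that is constant within a patient-assay pair —
library size, probe affinity, patient-level expression offsets — which is
why fold-changes travel across platforms better than expression does.
The pseudocount `c` defaults to 1 on the CPM scale: it bounds the
fold-change of a gene that leaves or enters detection and keeps the
matrix finite; the antisymmetry `fc(pre, post) = −fc(post, pre)` holds
exactly for every `c`.

Counting-mode aggregation (all isoforms, highest-expressed isoform,
probe-matched isoform, probe-matched exon) runs **before** normalization,
which runs before fold-change computation.  Aggregating after
normalization would mix per-isoform library-size corrections and is not
commutative with it; fixing the order makes the four modes comparable.
Probe-overlap ties are broken toward the lexicographically smallest
isoform id and reported, so runs are deterministic.

Within-assay scaling (percentile by midrank, or z-score) is available for
diagnostics such as PCA overlap.  Percentile is the default because it is
invariant to any strictly monotone per-gene transform, hence insensitive
to dynamic-range differences; a constant gene maps to 0.5 (percentile) or
0 (z-score).  Scaled values are deliberately *not* used as the modeling
feature space: scaling equalizes dynamic ranges by fiat, which is exactly
the assumption that fails for compressed platforms such as microarray.
Microarray cohorts therefore enter only the validation stage
(directionality, Cox, Kaplan–Meier), never training.

## Limits of detection

Given a double-assay design (the same samples on RNA-seq and NanoString),
the per-gene cross-platform Spearman correlation is computed across
samples (midrank ties; genes with fewer than 4 pairs or zero variance are
masked).  Genes are then cut into `n_bins = 10` quantile bins of median
expression — and, independently, of expression IQR — and the per-bin
median rho is scanned from the best-measured bin downward:

* **loose cutoff**: lower edge of the first bin whose median rho falls
  more than `loose_drop = 0.05` below the median rho of the top three
  bins (the "start of the decline");
* **strict cutoff**: lower edge of the first bin whose median rho drops
  below `strict_floor = 0.7` (the "clear decline").

Quantile binning makes the procedure equivariant under any monotone
rescaling of the expression axis.  When no bin qualifies, the cutoff is
0 (no filtering).  Because the strict rule anchors on the first offending
bin's *lower* edge, a decline confined to the bottom bin yields a cutoff
at the data minimum and removes nothing; the candidate-filtering step
therefore uses the **loose** cutoffs (expression and range jointly, via
`genes_below_lod()`), which is also the conservative choice for the
purpose — dropping genes whose measurements have merely *started* to
degrade.

Gene-level concordance classes use a fixed threshold of rho = 0.85 under
every preprocessing variant: `consistent_high` (all variants at or above),
`consistent_low` (all below), else `preprocessing_dependent`.  A counting
mode is declared to improve a gene's harmonization only when it raises
rho by more than 0.05 under at least two of the three normalizations —
one normalization alone is too easily moved by ties at low counts.

## Feature selection and modeling

The per-gene score is the one-way ANOVA F statistic on fold-changes
between outcome classes, computed vectorized from the closed form
`(SSB/df_B)/(SSW/df_W)`; a gene with zero within-class variance but
separated means returns `Inf` with a warning (it will top any ranking),
and an entirely constant gene returns 0.

Two selection strategies are provided.  *Consensus* intersects each
mini-cohort's top-k genes.  *Bootstrap predictive frequency* draws, per
replicate, an equal number of patients per class (the smaller class
count) with replacement, with per-patient weights proportional to
1/|mini-cohort| normalized within class — so each mini-cohort contributes
equally in expectation while class balance is preserved — then records
the top-`top_m` genes by F-score.  `top_m` defaults to 50 for panel-sized
spaces and 100 genome-wide; `B = 200` replicates are the pipeline
default.  All ties break by ascending gene id, so results are
reproducible bit-for-bit from the seed.  The candidate list takes the top
25 genes by (frequency, mean F, id) after optional LOD and panel filters;
25 caps model complexity at the sample sizes this design targets.

Three architectures are fit on standardized training fold-changes:
lasso-logistic, ridge-logistic (both `glmnet`; the regularization
strength is chosen by BIC along the default lambda path, a deterministic
in-sample criterion), and a linear-kernel SVM (cost 1), kept linear so
its weights are comparable to the logistic coefficients.  A
single-feature model falls back to unpenalized logistic regression.

The hold-out set (`max(10, 10% of N)` patients) is allocated greedily so
that outcome-class, mini-cohort, and PFS-tertile proportions each track
the full cohort within one patient; deviations forced by tiny strata are
reported.  Panel size k is chosen by leave-one-out cross-validation over
k = 1..25 and the three architectures, maximizing AUROC of the pooled
leave-one-out predictions, with ties resolved toward smaller k and the
architecture order lasso < ridge < svm (so a logistic model is reported
whenever it matches the SVM).  One numerical caveat is handled
explicitly: pooled LOO scores exclude the per-fold intercept.  Leaving a
positive case out shifts that fold's class prior down, which
systematically depresses the held-out positive's score; with
uninformative features this artifact drives AUROC far *below* 0.5.
Dropping the intercept (a per-fold constant that carries no
between-patient information) removes the artifact, and null features then
score ≈ 0.5 as they should.

AUROC is computed by trapezoidal integration over distinct score
thresholds, which equals the midrank Mann–Whitney `U/(n1·n0)` (the test
suite asserts this identity); one-class subsets are masked rather than
scored.  The PFS dichotomization is fixed at 12 months — the threshold,
not the cohort quantile, is the contract, even when a synthetic cohort's
median drifts from it.

## External validation

* **Directionality**: per mini-cohort, the difference of class medians of
  log2FC with a Welch t-test (tiers . / * / ** / *** at 0.1 / 0.05 /
  0.01 / 0.001).  The consistency class depends only on the sign vector:
  `all_agree`, `one_disagrees` (exactly one cohort off the majority), or
  `inconsistent`; it is invariant to positive rescaling per cohort.
* **Cox**: univariate proportional hazards per gene with Efron tie
  handling on standardized covariates (hazard ratios per SD);
  Benjamini–Hochberg adjustment across genes (BH is used everywhere an
  adjusted p is reported).  Monotone-likelihood fits are flagged and
  their CIs reported unbounded.  Sign-flipping a covariate yields exactly
  the reciprocal hazard ratio.
* **Kaplan–Meier**: median expression split (ties to the low group, so
  groups differ by at most one when the median is unique), two-sided
  log-rank test; constant expression is an error.
* **Cell states**: pseudobulk fold-change per cell type against
  `log(PFI + 1)` (the +1 admits PFI = 0), Spearman rho plus an OLS slope
  and p-value; patients missing a cell type are dropped per type.

## Networks

Unsigned weighted networks `a_ij = |cor_ij|^beta` with `beta = 6` (the
conventional soft-threshold default for unsigned networks) feed the
topological overlap matrix
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 − a_ij)`,
implemented with matrix products and verified against a triple-loop
oracle to 1e-12.  A focal gene's neighborhood is contrasted between
pre- and post-treatment networks by `delta = TOM_post − TOM_pre` and
`max = max(TOM_pre, TOM_post)`: genes above the 0.9 quantile of `max` are
partners; partners above the 0.9 quantile of |delta| are condition-
specific (`post_only`/`pre_only`), the rest `shared`.  The 0.9 quantiles
are our formalization of an otherwise visual classification.  Cell-type
attribution replaces metacell construction with per-cell-type pseudobulk
networks: on synthetic data where one cell type drives the focal
co-expression, the bulk focal TOM row correlates best with that type's
pseudobulk TOM row.

## The synthetic generator

Defaults encode the study conditions the pipeline targets: six bulk
mini-cohorts (three NanoString — 35, 17, 31 patients — and three RNA-seq
— 15, 20, 22), a 770-gene probe panel inside a 2000-gene space, paired
pre/post samples per patient, PFS exponential with median 12 months.
Baseline abundances are log-normal (`ln` mean 4, sd 2, CPM-like units);
patient random effects (`ln` sd 0.5) are shared between timepoints, so
they cancel in fold-change; residual per-sample noise has `ln` sd 0.3.
A balanced latent grid per cohort makes PFS classes balanced within one
patient and keeps planted fold-changes monotone in PFS.

Planted truth: 15 PFS biomarkers (signed one-log2-unit post-treatment
shifts in long-PFS patients — the "strong" preset; drawn from the upper
half of panel expression, as real biomarkers must be detectable) and 12
assay-discriminative genes placed *below* the detection floor.

The measurement model is background-limited: count assays draw Poisson
counts around `max(true, floor × e^ε)`, where the per-assay floor
(CPM-like; default 1 for RNA-seq, 5 for NanoString, reflecting probe
background) is jittered per gene and sample (`ln` sd 0.5).  Genes far
above the floor are measured faithfully; genes below it read fluctuating
background, which is what decorrelates them across platforms and gives
the detection-limit estimator a well-defined target — the floor is, by
construction, the point where signal stops driving the reading.  A
per-(cohort, gene) batch multiplier on the background is shared between
the pre and post runs, so it cancels in fold-change; the planted assay
genes additionally scale the *post*-run background in NanoString cohorts
by `2^±1`, which is what makes them discriminative on the log2FC scale
and makes the assay-identity classifier collapse once below-floor genes
are filtered.  Microarray applies a concave power (default 0.5) on the
log scale plus log-normal intensity noise — a compressed dynamic range.
Single-cell samples draw 200 cells across 4 Dirichlet-weighted types,
with multinomial capture proportional to `abundance^1.3` (capture
efficiency ∝ `abundance^0.3`), reproducing preferential capture of high
expressors.

What the generator does **not** emulate: gene–gene correlation beyond the
patient random effect (real co-expression modules are much richer, so
network results on synthetic data only exercise the machinery), real
isoform complexity (two isoforms per gene, fixed exon geometry), FFPE
degradation gradients, and clinical covariates.  Passing recovery tests
therefore demonstrates that the *procedures* behave as specified under
the assumed noise model — not that any particular real cohort satisfies
that model.

## Problem sizes and determinism

The test suite runs the full recovery studies at the scales the package
targets: 50 double-assay simulations (1000 genes × 24 paired samples) for
detection-limit recovery; 20 replicates of the full 140-patient,
770-panel design for biomarker recovery, hold-out AUROC and the
permutation null; 500 null simulations (n = 100) for Cox CI coverage and
200 (n = 200) for log-rank power; a 300-gene two-cohort smoke
configuration for end-to-end determinism.  Every stochastic function
takes an explicit seed; one master seed fans out to named sub-streams
(per mini-cohort, per stage), so cohort subsets and stage reruns
reproduce bit-identical outputs, which the pipeline verifies via md5
checksums in its manifest.

## Known limitations

* The loose/strict cutoffs depend on the 10-bin quantile grid; very
  skewed expression distributions can merge bins (duplicate quantiles are
  collapsed, widening the affected bins).
* BIC-selected regularization is conservative at very small n; the
  LOO-selected k partially compensates.
* The bias-probe mirror relies on planted below-floor offsets; an
  additive-background variant of the generator makes near-floor genes
  weakly discriminative in every cohort and the filtered classifier does
  not fully collapse — a useful reminder that LOD filtering removes only
  what the limits actually cover.
* Survival associations are planted in fold-change only; baseline
  (pre-treatment) expression is prognostically null in the generator, so
  external-cohort-style validation on pre-treatment expression alone is
  exercised only for its statistical calibration, not for recovery.
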