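---
title: "Predicting aberrant underexpression from rare variants: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aberrant underexpression from rare variants: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `abexp`, the parameters
that matter, the decisions taken where conventions were genuinely open, and
what the synthetic cohorts do and do not establish.

## The prediction problem

An underexpression outlier is a (gene, sample) observation whose RNA-seq
fragment count is far below the cohort expectation. Outlier callers fit a
negative binomial per gene and tissue, `x ~ NB(mu, theta)` with variance
`mu + mu^2/theta`, and report an adjusted p-value. The prediction task is:
given an individual's rare variants, which genes will be aberrantly
underexpressed, and in which tissues? Two properties dominate the design:

* **Extreme imbalance.** Roughly 1 in 10⁴ assessable gene-sample pairs is an
  outlier. All evaluation is precision-recall based; ROC curves are
  uninformative here.
* **Tissue specificity.** The same variant can silence a transcript that
  carries most of a gene's expression in one tissue and a minor fraction in
  another. Variant annotations are therefore weighted by tissue-specific
  isoform proportions, and the gene's per-tissue expression variability
  (BCV = 1/sqrt(theta)) enters as a feature, because a fold-change that is
  aberrant for a tightly regulated gene is unremarkable for a variable one.

## Benchmark construction

`apply_benchmark_filters()` turns an outlier-caller table into a labeled
benchmark:

* z-scores by quantile mapping, `z = qnorm(CDF_NB(x | mu, theta))`. The CDF
  is clamped to `[1e-16, 1 - 1e-16]` before the normal quantile so z stays
  finite; the clamping epsilon is exposed (`clamp_eps`) but the default is
  far out in the tail of anything a benchmark contains.
* "Lower than expected" is operationalised as `z < 0`; the FDR label plus
  the z-sign give the three classes. The convention is exposed rather than
  hard-coded into downstream code.
* Coverage filter `mu >= 450` fragments: the minimum at which a 50%
  reduction is reliably detectable at FDR 5%. Boundary semantics: 449 is
  dropped, 450 kept.
* Samples with more than 20 outliers are dropped entirely — such samples
  usually reflect a failed fit or a globally perturbed transcriptome that
  local sequence variation cannot explain. The cap counts under- plus
  overexpression outliers together (configurable), and is applied after the
  coverage filter by default; the order is configurable
  (`cap_before_mu_filter`) because either reading of the procedure is
  defensible.
* log2 fold-changes use pseudocount 0 by default, with an explicit `-Inf`
  sentinel and `l2fc_zero` flag at `x = 0` (the ratio is undefined there);
  a documented `pseudocount = 1` mode gives finite values.
* A "sample" is one RNA-seq library, i.e. one (individual, tissue) pair;
  all per-sample filters act per tissue independently.

The upstream FPKM expression filter (FPKM < 1 in ≥ 95% of samples) is
assumed already applied by the caller; `fpkm_expressed_filter()`
reimplements it for synthetic data only.

## Variant features

Rare = population AF ≤ 0.001 (missing AF counts as 0 — unobserved is rare)
and ≤ 2 cohort carriers; high-quality = GQ strictly greater than 30 and
depth ≥ 10. Structural variants are filtered on carrier count only; their
carrier ceiling shares the small-variant default (≤ 2) and is configurable,
since conventions differ between "at most 2" and "fewer than 2".

Gene assignment uses 1-based closed intervals (GTF/VCF convention):
small variants pair with genes whose transcript span ± 5000 bp contains the
position; SVs additionally pair through a strand-aware
`[TSS − 1 Mb, TSS]` window. Distant-SV features are computed but are not
part of the default feature set — in our hands they carry little signal
relative to their sparsity.

Isoform proportions (`compute_isoform_proportions`) are medians across
individuals of each transcript's share of its gene's TPM, per tissue.
A median of ratios need not sum to one across isoforms, so per-(gene,
tissue) proportions are renormalised to sum to 1 and the pre-normalisation
sum is kept in `raw_sum` for inspection. Individuals in which the gene is
silent are excluded from the median; fully silent genes yield missing
proportions, and weighted aggregation then instructs the caller to fall
back to canonical mode.

A variant "affects" an isoform iff the annotation table assigns it any
consequence on that transcript — for variants outside all exons this means
upstream/downstream terms count as affecting, matching annotation-tool
behaviour. Weighted features are maxima over variants of the summed
affected proportions, hence always in [0, 1]; canonical mode replaces the
weight with a 0/1 indicator on the canonical transcript and is identical
across tissues. CADD is max-aggregated per gene (tissue-independent);
AbSplice keeps the signed value of maximum absolute score per gene-tissue.
Multi-allelic sites and overlapping SV + SNV evidence receive no special
treatment beyond this uniform max-aggregation.

## The z-score regressor

The model is a gradient-boosted-tree ensemble regressing the quantitative
z-score (not classifying the binary label — the quantitative target carries
the severity information that ranking needs). Hyperparameters: 100 trees,
leaf-wise growth with ≤ 31 leaves, learning rate 0.1, minimum child weight
0.001, no subsampling, no explicit regularisation; seeds are part of the
configuration and identical config + seed + input reproduces identical
output.

Cross-validation is grouped by individual into 6 folds balanced on outlier
counts by a greedy rule (descending count, assign to the currently lightest
fold, ties shuffled by seed). Out-of-fold predictions are only ever emitted
for held-out individuals. For deployment, the per-fold models' predictions
are averaged — the simplest combination rule consistent with the
cross-validation scheme; it is configurable in spirit (the per-fold
boosters are retained in the model object).

Confidence classes use strict cutoffs, `z_pred < −3.84` (high) and
`< −1.64` (low). Tree ensembles are piecewise-constant: predictions are not
locally monotone in any single feature, so monotonicity is treated as a
soft diagnostic, never an invariant.

## CAT integration

When a clinically accessible tissue (CAT) has RNA-seq, a plain
maximum-likelihood logistic regression predicts the outlier label from six
predictors: expressed-in-CAT flag, CAT z (0 when not expressed), the
DNA-based prediction, and the three pairwise products. "Expressed in CAT"
means present in the CAT's outlier table — no separate TPM threshold is
introduced. The model is fit pooled across target tissues (a per-tissue
fit is a trivial restriction of the same code); the CAT itself and closely
related tissues are excluded from the targets (3 exclusions for
fibroblasts, 2 for whole blood). On complete separation the fit falls back
to a small, fixed ridge penalty (Newton iterations on the penalised
likelihood with the intercept unpenalised); the default remains
unpenalised.

## Evaluation machinery

Average precision follows the recall-weighted-precision sum with tied
scores collapsed into a single operating point — this makes AP independent
of the ordering of tied rows, which matters for binary predictors. Per-type
evaluation pools tissues within each of 27 tissue types (the 49-tissue map
ships in `inst/extdata/`) so that the many near-identical brain tissues do
not dominate comparisons; model pairs are compared with an exact two-sided
paired Wilcoxon signed-rank test (p = 1 by convention when all differences
vanish). Consequence attribution orders classes by Fisher-exact
significance against outlier status (two-sided by default, configurable);
ties in p break by a fixed impact order (NMD-like first, Downstream last).
Enrichment odds ratios come from logistic fits with Wald CIs, falling back
to a flagged Haldane–Anscombe 0.5 correction on empty cells; score cutoffs
transfer between methods by empirical quantile matching. Variant-level
evaluation against pathogenicity databases collapses predictions to the
minimum (most impactful) score across tissues, with benign and likely
benign classes merged.

## Burden association and phenotype prediction

Traits are inverse-rank-normal transformed with the `(r − 0.5)/n` offset
(the offset is a convention; this one keeps the transform symmetric).
Burden encodings follow the four schemes: LOFTEE count, per-tissue minima
across the individual's rare variants (0 without any variant), and their
min/median. Association is a likelihood-ratio test between nested Gaussian
OLS models with the error variance profiled out; the statistic is compared
to chi-square with df equal to the number of burden columns surviving
rank-deficiency pruning. Calibration is checked by permuting the phenotype
once and testing the per-gene p-values for uniformity. Phenotype
prediction splits individuals 2:1 into discovery (per-gene LRT, Bonferroni
across genes at α = 0.05 by default — the discovery threshold is exposed as
configuration) and prediction, the latter evaluated with 5-fold CV against
a covariate-only baseline, counting individuals whose absolute error moves
by more than one trait SD.

## Track-aggregate expression mapping

Precomputed sequence-model track aggregates `u` (non-negative,
p-dimensional per sequence) map to expression via
`y = beta' log10(1 + u) + intercept`, with `y = log10(1 + mean TPM)`.
Producing `u` (the deep-learning inference over long windows, shifts and
central bins) is explicitly upstream; a documented schema lets real
aggregates plug in. The ridge fit is solved by normal equations with an
unpenalised intercept — exact to the closed form, which the unit tests
check to 1e-8; `lambda = 0` uses QR and refuses rank-deficient designs.
Variant effects on the canonical transcript are reported on the
per-log10(2) scale exactly as defined (a score of 1 ≈ one predicted
doubling); the isoform-weighted score is the log2 ratio of
proportion-weighted `10^y` sums, which reduces algebraically to the
canonical score for a single isoform. Per gene/individual/tissue the signed
maximum-absolute score is kept, ties resolved by the first occurrence after
sorting. Scores default to missing outside a [−50, +200] bp TSS window,
where promoter-focused models are predictive.

## The synthetic cohorts

`simulate_cohort()` generates every input the pipeline consumes,
deterministically from one seed (sub-draws derive from the single seeded
generator). Defaults — chosen once as a desk-scale cohort a practitioner
would call realistic, and stated here as the problem sizes used throughout
the tests and the acceptance script:

* 200 individuals × 500 genes × 5 tissues (500,000 observations);
  1–3 isoforms per gene with Dirichlet tissue-specific proportions.
* NB parameters per gene-tissue: `mu` log-normal (median 900, so most genes
  pass the 450 filter while some exercise it); BCV log-normal with median
  0.2.
* ~10 rare candidate variants per individual; consequence mix dominated by
  synonymous/intron/upstream/UTR/missense with 1.2% NMD-like and 1.8%
  splice — truncating variants are a small minority of rare variants, and
  this mix realises the targeted ~1×10⁻⁴ outlier prevalence. About 8% of
  candidates deliberately fail a quality/frequency filter; a handful of
  structural deletions fully cover a gene (transcript ablation).
* Planted effect on log2FC: `−effect_size × isoform_weight ×
  min(1, BCV/0.3)`. The effect hierarchy is NMD-like (2.4) > splice (1.8)
  ≫ missense (0.25) ≥ UTR/upstream/intron, synonymous exactly 0; the BCV
  term reproduces the attenuation of fold-changes in low-variability genes.
* p-values from two-sided NB tail probabilities at the true parameters,
  Benjamini–Yekutieli adjusted per sample. This FDR stands in for a real
  outlier caller's: no autoencoder, no confounders, no estimation error in
  (mu, theta).

What passing tests on these cohorts show: the pipeline's plumbing is
correct end to end; the model recovers planted, isoform- and
BCV-modulated signal far above prevalence and above a single-score
baseline; the burden tests are calibrated. What they do not show:
performance on real cohorts, where (mu, theta, FDR) are estimated rather
than known, annotations are noisy, effects are not cleanly hierarchical,
haplotype structure and population stratification exist (the generator has
none), and isoform proportions are correlated across tissues rather than
independent. That last simplification also means simulated outlier status
is only partially shared across tissues, so the CAT-integration gain is
demonstrated in the regime its model targets — targets whose accessible
tissue mirrors their outlier status — rather than on the raw default
cohort.

`plant_tissue_specific_case()` distils the tissue-specificity mechanism
into a two-isoform, two-tissue scenario (canonical share 0.48 vs 0.04 by
default) with a frameshift confined to the canonical isoform: the planted
outlier materialises only in the high-proportion tissue.

## Known limitations

* Phasing and compound heterozygosity are not modelled; variants act
  independently and aggregate by max.
* No uncertainty estimates accompany predictions.
* The simulator's FDR is idealised (see above); absolute metric values on
  synthetic cohorts do not transfer to real data.
* Hyperparameters are fixed at the documented defaults; no search is
  performed.
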