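# probioscreen

Screening probiotic bacteria by the information content of their genomes.

## The problem

Probiotics — live microorganisms that benefit the host when ingested in
adequate amounts — are still identified through slow experimental
pipelines. `probioscreen` implements a genomic pre-screen: given annotated
bacterial genomes (GenBank flat files), it encodes each organism as 61
interpretable features and trains supervised classifiers to separate
probiotic from non-probiotic gut bacteria. The feature set is built from
three per-sequence statistics, computed for the whole genome and for the
concatenated CDS, rRNA, tRNA and ncRNA annotation:

- **Shannon entropy** `H = -Σ pᵢ log₂ pᵢ` over base frequencies (0–2 bits);
- **topological entropy**, a subword-complexity score `log₄(cₙ)/n` with the
  word length `n` chosen as the largest integer with `4ⁿ + n − 1 ≤ L`;
- **Chargaff second-parity-rule scores**: the normalized conformity
  `ct = 1 − (|A−T| + |C−G|)/L` (1 = perfect single-strand parity) and the
  unnormalized deviation `pf = |A−T| + |C−G|` (0 = perfect parity).

The workflow mirrors a published analysis regime: recursive feature
elimination under repeated 10-fold cross-validation, repeated stratified
10-fold CV over four classifier families (logistic GLM, random forest,
RBF-SVM, single-hidden-layer neural network) with within-fold imputation
and standardization, permutation feature importance, and a complete
evaluation suite (accuracy with exact Clopper–Pearson intervals,
sensitivity, specificity, precision, Cohen's Kappa, F1, MCC, rank-based
AUC, FP/FN/total error decomposition).

Because curated real cohorts are not redistributable, the package ships a
tested synthetic-cohort generator that emulates the study conditions: 44
probiotic + 33 non-probiotic training genomes plus a 12-organism held-out
block, probiotic genomes smaller with fewer CDS, and a planted tRNA
effect — higher tRNA Shannon entropy with lower Chargaff conformity in the
probiotic class.

## Worked example

```r
library(probioscreen)

# a fully annotated synthetic cohort, written as GenBank flat files
coh <- generate_cohort(cohort_spec(seed = 1))
tab <- build_dataset(coh$genomes,
                     setNames(coh$labels$outcome, coh$labels$organism_id))
train <- tab[coh$labels$role == "train", ]
test  <- tab[coh$labels$role == "test", ]

cfg <- pipeline_config(preset = "ci", seed = 1)   # desk-scale repeats
rfe <- recursive_feature_selection(train, cfg)
rfe
#> recursive feature elimination: 18 sizes tested, peak accuracy 0.987 at 30 features
#> chosen subset (4 features): tRNA_chargaff_score_pf, tRNA_chargaff_score_ct,
#>   tRNA_shannon_score, bp_genC

cv <- train_models(train, rfe$subset, cfg)
cv
#> repeated stratified 10-fold CV x 50 repeats on 4 features
#>   glm  accuracy 1.000  kappa 1.000  <- best
#>   rf   accuracy 0.982  kappa 0.963
#>   svm  accuracy 1.000  kappa 1.000
#>   nn   accuracy 1.000  kappa 1.000

head(feature_importance(cv), 4)
#>                  feature  importance
#> 3     tRNA_shannon_score 100.0000000
#> 2 tRNA_chargaff_score_ct  82.6346801
#> 1 tRNA_chargaff_score_pf   0.4713805
#> 4                bp_genC   0.0000000

comparison_report(predict_cohort(cv, test),
                  setNames(coh$labels$outcome, coh$labels$organism_id))
#>  Method Accuracy          CI Se Sp Precision Kappa F1 MCC AUC
#>     glm        1 0.735-1.000  1  1         1     1  1   1   1
#>     ...
```

Reading: the selection profile peaks near 0.99 and the one-standard-error
parsimony rule keeps four features, led by the three tRNA information
scores — the planted signal. All four families then separate the cohort
(the planted effect is calibrated so the *profile* sits in the 0.9s; the
parsimonious trio is jointly near-perfect), and every held-out organism,
including the three pathogen-like negatives, is called correctly. On real
data the same calls apply unchanged; use `preset = "full"` for
protocol-scale repeats (100 × RFE, 1000 × CV) and `read_genbank()` on
RefSeq flat files.

Single sequences score directly:

```r
shannon_entropy("ATGC")      # 2 bits — maximal information content
shannon_entropy("AAAA")      # 0
chargaff_ct("ATGC")          # 1 — perfect parity
topological_entropy("ATATAT")# 0.5
```

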