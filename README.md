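# nppred — neuropeptide precursor prediction from protein sequences

Neuropeptides are short secreted peptides (mostly 5–30 aa) that regulate
metabolism, sensation and behavior throughout the animal kingdom. They are
cut out of longer secreted proteins — neuropeptide precursors (NPPs) — by
endopeptidases acting at dibasic (KK/KR/RK/RR) and tribasic Lys/Arg
motifs. Mature peptides are short and poorly conserved, so homology search
recovers few new precursors from unannotated genomes, transcriptomes or
mass-spectrometry collections. `nppred` takes the complementary route:
classify whole sequences by their global, architecture-level properties.

The package is for anyone screening protein FASTA sets — predicted
proteomes, ORF sets, MS-derived sequences — for candidate NPPs and
secreted peptide modulators worth experimental follow-up.

## Method

Each validated sequence (20-letter alphabet; records with B, X, U, Z or
other non-canonical residues are removed and reported) is converted to a
fixed 560-dimensional feature vector:

* amino-acid composition — 20 features;
* bigram (ordered adjacent pair) frequencies, normalized by *L* − 1 —
  400 features;
* 140 physicochemical/statistical descriptors (length, molecular weight,
  pI, GRAVY, instability index, charge, basic-motif counts and
  densities, terminal-window compositions, hydropathy-profile
  statistics, and more), under the versioned catalog
  `nppred-catalog-1.0`.

Four supervised models score every vector — a random forest, gradient
boosting, a Platt-calibrated linear SVM, and a "minimal tree" restricted
to the 20 most discriminative features. A model votes positive when its
probability exceeds its threshold (0.8; 0.99 for gradient boosting,
strict inequality), and a sequence is a positive prediction when **at
least one** model votes for it. Training reports stratified 6-fold
cross-validation: accuracy, precision, recall,
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), and rank-based
AUC.

Positive predictions are ranked by the **Internal Score**, the density of
cleavage motifs over the effective length after trimming a typical 25-aa
signal peptide:

```
IS = 100 × (n_dibasic + n_tribasic) / max(L − 25, 1)
```

Positives with IS above a configurable threshold (default 2%) form the
high-quality set. An optional signal-peptide filter (built-in hydropathy
heuristic, or any external predictor via a command template) removes
non-secreted sequences up front. A synthetic precursor generator with
planted, ground-truthed cleavage motifs makes the whole pipeline
trainable and testable offline.

## Worked example

```r
library(nppred)

# train on synthetic precursor vs background sequences (60 + 60)
train  <- synth_training_set(n = 60, seed = 7)
bundle <- npp_train(train$pos_features, train$neg_features, seed = 7)
bundle
#> <nppred_bundle> four-model NPP ensemble
#>   trained on 60 positives / 60 negatives, 6 -fold CV, seed 7
#>   catalog: nppred-catalog-1.0 ( 560 features; minimal subset 20 )
#>   thresholds: random_forest > 0.8, gradient_boosting > 0.99, linear_svm > 0.8, minimal_tree > 0.8
#> # A tibble: 4 × 6
#>   model             accuracy precision recall   mcc   auc
#>   <chr>                <dbl>     <dbl>  <dbl> <dbl> <dbl>
#> 1 random_forest        1         1      1     1     1
#> 2 gradient_boosting    0.975     0.985  0.967 0.954 0.975
#> 3 linear_svm           1         1      1     1     1
#> 4 minimal_tree         0.992     1      0.983 0.984 1

# predict on fresh sequences (10 precursor-like + 10 background)
test <- synth_training_set(n = 20, seed = 8)
run  <- npp_run(dplyr::bind_rows(test$pos[1:10, ], test$neg[1:10, ]),
                bundle, sp_filter = "heuristic")
run
#> <npp_run> 20 input sequences: 0 removed (invalid residues), 2 filtered (no signal peptide), 10 positive / 8 negative
#>   high-quality (IS >= 2 %): 10

head(tidy(run)[, c("id", "prob_random_forest", "prob_gradient_boosting",
                   "n_models_agreeing", "internal_score", "high_quality")], 5)
#> # A tibble: 5 × 6
#>   id            prob_random_forest prob_gradient_boosting n_models_agreeing
#>   <chr>                      <dbl>                  <dbl>             <int>
#> 1 synthpos_0005              0.986                  0.984                 3
#> 2 synthpos_0004              0.971                  0.984                 3
#> 3 synthpos_0006              0.977                  0.984                 3
#> 4 synthpos_0001              0.929                  0.984                 3
#> 5 synthpos_0003              0.832                  0.984                 3
```

Reading the output: the cross-validation table shows each model separating
the synthetic classes nearly perfectly (the synthetic contrast is clean by
design). In the run, all 10 precursor-like sequences are called positive
and land in the high-quality set (their Internal Scores exceed the 2%
threshold), two background sequences are dropped by the signal-peptide
heuristic, and the rest are negative. Note gradient boosting's 0.984 is a
*negative* vote — it stays below that model's strict 0.99 cutoff — so
these sequences are carried by 3 agreeing models.

Per-sequence motif graphics and feature histograms:

```r
plot_sequence_motifs(test$pos[1, ])                  # red di/tribasic, green single basics
render_sequence_svg(test$pos[1, ], "seq.svg")        # standalone SVG
plot_feature_histogram("pc_instability_index",
                       train$pos_features, train$neg_features,
                       query_value = 40)             # green/red distributions, dashed query
```

A thin command-line wrapper covering the same operations ships in
`inst/cli/nppred.R` (`features`, `train`, `predict`, `synth`
subcommands).

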