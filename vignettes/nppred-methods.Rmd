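---
title: "Predicting neuropeptide precursors: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting neuropeptide precursors: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neuropeptides (NPs) are short secreted peptides — mostly 5–30 amino acids —
that act on receptors to modulate metabolism, sensation and behavior across
metazoans. They are not encoded as such: each is excised from a longer
secreted protein, the neuropeptide precursor (NPP), by endopeptidases that
cut predominantly at runs of the basic residues Lys (K) and Arg (R).
A typical precursor therefore has a recognizable architecture: an
N-terminal signal peptide (SP) of roughly 25 residues directing it into the
secretory pathway, followed by several short peptide units, each flanked by
dibasic (KK, KR, RK, RR) or tribasic cleavage motifs. Because the mature
peptides themselves are short and only weakly conserved, homology search
alone recovers few new precursors from unannotated genomes and
transcriptomes; classification from global sequence properties is the
complementary route this package implements.

`nppred` scores arbitrary protein FASTA input with a supervised
four-model ensemble over a fixed 560-dimensional descriptor vector, ranks
positive predictions by a cleavage-motif density score, and flags a
high-quality subset. It also ships a synthetic precursor generator so the
whole pipeline is trainable and testable without any external downloads.

## The feature vector

Every validated sequence (20-letter alphabet only; records containing
B, X, U, Z or any other non-canonical character are removed and reported)
maps to exactly 560 features in three groups:

* **Composition (20).** Frequency of each residue, `count / length`.
* **Bigrams (400).** Frequencies of all ordered adjacent residue pairs,
  overlapping, normalized by `L - 1`. Normalizing (rather than raw counts)
  removes the length confound from this group; length is its own
  descriptor. Sequences of length 1 get zeros.
* **Physicochemical and statistical descriptors (140).** Global indices
  (length, molecular weight, isoelectric point by bisection over the
  EMBOSS pKa set, Kyte–Doolittle GRAVY, the Guruprasad instability index,
  aromaticity, net charge at pH 7), residue-class fractions, counts and
  per-100-residue densities of K, R and of single/dibasic/tribasic motif
  sites (each density also in a variant over the effective length after a
  25-aa SP allowance), full N- and C-terminal 25-residue window
  compositions, composition and bigram entropies, maximal basic and
  hydrophobic run lengths, windowed hydropathy-profile statistics
  (window 9), terminal hydropathy and charge summaries including a
  signal-peptide core score, Chou–Fasman-style secondary-structure
  propensity fractions, basic-site spacing statistics, per-quarter basic
  and hydrophobic fractions, and lag-1..10 autocorrelations of the
  hydropathy and charge profiles.

The 140-descriptor list is a reconstruction: the categories are fixed by
what the method requires (the original tool's exact list was never
published), so the catalog is versioned (`nppred-catalog-1.0`), the version
travels with every feature table and trained model, and models refuse to
score vectors from a different catalog version. Train/predict consistency
is the contract that matters, not any particular descriptor list.

Sequences shorter than a window are summarized over the residues
available; bigrams of a single-residue sequence are zeros rather than
errors, so degenerate inputs flow through the pipeline and are flagged
rather than crashing it.

## Cleavage motifs and the Internal Score

`find_basic_sites()` scans maximal runs of {K, R}: a run of length 1 is a
single basic site, exactly 2 is one dibasic motif, and 3 or more is one
tribasic motif. Counting maximal runs once — rather than every basic pair —
makes the reported motifs disjoint and counts cleavage *opportunities*
rather than overlapping substrings; a run of 4+ still counts as one
tribasic motif (the alternative, `floor(run/2)`, was rejected for
simplicity and because such runs are rare and still mark one processing
region).

The Internal Score is the motif density over the effective length:

$$\mathrm{IS} = 100 \cdot \frac{n_\mathrm{dibasic} + n_\mathrm{tribasic}}
{\max(L - 25,\ 1)}$$

The 25-aa trim reflects the typical SP length, which is removed in the
mature secreted protein and should not dilute the density. Two
conventions are deliberately configurable because the field's usage is
ambiguous: motifs *inside* the first 25 residues are still counted in the
numerator by default (`count_nterm = FALSE` excludes them), and the
denominator floor of 1 keeps sequences of ≤ 25 aa finite (they are flagged
`below_sp_length` in run records rather than silently trusted).

```{r}
library(nppred)
s <- strrep(paste0(strrep("A", 22), "KKA"), 5)   # 125 aa, 5 dibasic motifs
internal_score(s)
```

## The four-model ensemble

`npp_train()` fits four classifiers over the same feature matrix:

| model | implementation | threshold |
|---|---|---|
| `random_forest` | `ranger` probability forest, 300 trees | > 0.8 |
| `gradient_boosting` | `xgboost`, logistic objective, depth 3, η = 0.1, 150 rounds | > 0.99 |
| `linear_svm` | `e1071` linear SVM + Platt sigmoid | > 0.8 |
| `minimal_tree` | probability forest on the top-20 features | > 0.8 |

A sequence is called positive by a model when its probability is
*strictly greater* than that model's threshold, and positive overall when
at least one model calls it — the ensemble is a sensitivity-oriented OR,
with the per-model thresholds (notably the stringent 0.99 on gradient
boosting) supplying the specificity. The number of agreeing models (0–4)
is reported per sequence as a user-facing confidence grade.

Design notes, in rough order of how much they matter:

* **Calibration.** The thresholding contract needs probabilities, not SVM
  margins. libsvm's built-in probability training is not reproducible
  from R's seed, so the package fits its own Platt sigmoid on
  *out-of-fold* decision values (inner 3-fold split) and applies it to
  the full-data SVM. Fitting the sigmoid in-sample would push
  probabilities toward 0/1 and silently change what "> 0.8" means.
* **Selection leakage.** The minimal-tree subset (impurity-ranked top
  *k*, default k = 20 of 560) is re-selected inside every
  cross-validation fold when estimating performance; selecting once on
  all data and then cross-validating inflates the minimal-tree estimate
  noticeably at these sample sizes. The subset shipped in the bundle is
  selected on the full training set.
* **Evaluation.** Stratified 6-fold cross-validation; per-fold held-out
  accuracy/precision/recall/MCC (at probability 0.5, threshold-free of
  the calling rule) and rank-based AUC, averaged over folds
  (`tidy()` on the bundle). MCC's undefined cases (any zero marginal) are
  reported as 0, and an undefined precision (no positive calls) is 0 with
  an explicit flag.
* **Determinism.** One integer seed drives fold assignment, forests,
  boosting and the calibration split; the same inputs and seed reproduce
  identical metrics and predictions. The seed is recorded in the bundle
  and its plain-text `manifest.yaml`.
* **Class balance.** Training sets are expected roughly balanced (the
  generator emits equal classes); no resampling is applied.

## The synthetic generator

`generate_positive()` emits the architecture the classifier assumes:
`[SP segment | spacer | (peptide unit | basic flank) × n | tail]`, with a
Met-initiated SP-like segment (2 basic n-region residues, a 12-residue
Leu-rich hydrophobic core, a short polar c-region, 25 aa total), 4–8
units of 5–30 aa (database-average background composition), flanks drawn
as KK/KR/RK/RR with a 10% tribasic admixture, and unit residues adjacent
to each flank forced non-basic so every planted flank is emitted as a
maximal run of exactly its planted class. Planted motif positions are
returned as ground truth in the same BED-like table format the scanner
exports, and are by construction a subset of what `find_basic_sites()`
reports (spontaneous background motifs may add sites).

`generate_negative()` offers three classes: `uniform` (database-average
composition), `nuclear` (K/R enriched 1.6× overall but with basic runs of
≥ 2 rejection-sampled away — nuclear proteins are basic-rich yet lack
clustered processing sites), and `globular` (hydrophobic-shifted). A
`sanitize_negatives` switch removes clustered basics from every class for
clean-oracle tests.

What this emulates — and what it does not: the generator reproduces the
*architecture* (SP, repeats, flank density, composition) that the
features measure, which is exactly what makes it a fair harness for the
pipeline's mechanics. It does not mimic real precursor families'
homology, amidation signals, atypical cleavage sites, or the annotation
noise of real proteomes. Synthetic separations are clean (cross-validated
AUC ≈ 1 at the default configuration), so passing tests demonstrate that
the machinery learns and applies the intended signal correctly — not that
real-proteome accuracy would match; published screens of this method
report high-80s/low-90s percent accuracy against curated databases, which
cannot be reproduced without the original training accessions.

## The pipeline and its outputs

`npp_run()` chains validation → optional SP filter → extraction → scoring
→ ranking: records are sorted by Internal Score (descending), ties broken
by the maximum model probability, then input order, so reruns are
byte-identical. The run summary is an exact partition:
`n_input = removed + sp_filtered + positive + negative`, verified on
every run.

The SP filter has three modes. `off` records nothing; `heuristic` applies
the built-in screen (a 7-residue window of mean Kyte–Doolittle hydropathy
≥ 1.0 within the first 25 residues, after at least one leading residue) —
a deliberately coarse architectural test, documented as *not* equivalent
to SignalP; `external` shells out to any predictor via a command
template, and a missing or failing command aborts the run rather than
silently proceeding unfiltered. Filtered-out sequences are excluded from
scoring by default (`score_filtered = TRUE` keeps them, with the flag
recorded).

The high-quality tab is `overall_call AND IS ≥ threshold`. The threshold
default of 2% is this package's own choice (the original tool never
published its value); it is configurable everywhere and always printed in
the summary. A density of 2 motifs per 100 effective residues corresponds
to a precursor yielding roughly one peptide per 50 aa, the low end of
genuine multi-peptide precursors. Raising the threshold can only shrink
the high-quality set (tested monotonicity).

## Visual reports

`plot_sequence_motifs()` / `render_sequence_svg()` draw the classic
precursor cartoon: a baseline proportional to length, red marks spanning
di/tribasic motifs, green marks at single basics, annotated with counts
and density. The SVG writer emits standalone markup so reports need no
graphics device. `plot_feature_histogram()` overlays the positive (green)
and negative (red) distributions of one feature in "Feature Units": both
sets centered on the pooled mean, each scaled by its *own* standard
deviation (the per-set convention was chosen so that each distribution
has unit spread and remains comparable when variances differ; the
rendering is invariant to shifting both sets by a constant). A
zero-variance set is an error naming the offending set, not a silent
division by zero. Bin count defaults to Sturges' rule.

## Problem sizes and numerical choices

The test suite and the acceptance script train on 200 + 200 synthetic
sequences with 6-fold cross-validation and evaluate on an independent
200 + 200 set — comfortably past the regime where the planted separation
saturates (the same properties hold at 40 + 40, which the unit tests use
for speed). Exhaustive oracles run where exhaustion is feasible: all
confusion matrices with counts ≤ 10, all ≥ 6561 sequences of length ≤ 8
over {A, K, R} against an independent brute-force scanner, and pairwise
O(n²) AUC on 1000 random instances. Composition/bigram sums hold to
1e−9; SVM features are standardized with an SD floor of 1e−8 (constant
columns pass through unscaled).

## Known limitations

* Precursors processed by non-canonical (non-basic) cleavage receive low
  Internal Scores and will not reach the high-quality list even when
  called positive; browsing all positives remains advisable.
* The heuristic SP filter trades accuracy for having no external
  dependency; for real screens an external predictor should be plugged
  in.
* Reported metrics on synthetic data characterize the machinery, not
  real-proteome performance (see the generator section).
* The descriptor catalog is a faithful reconstruction by category, not a
  bit-match of the original unpublished list; bundles are tied to the
  catalog version to keep that explicit.
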