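---
title: "Scoring regulatory non-coding small indels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regulatory non-coding small indels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regindel)
```

## The problem

Small insertions and deletions (sindels) in non-coding DNA can perturb
regulatory elements — promoters, enhancers, transcription-factor binding
sites — and thereby change the expression of nearby genes. Unlike coding
variants, their functional consequences cannot be read off a protein
alignment, and most in-silico scorers target single-nucleotide variants.
`regindel` implements a supervised, tissue-specific framework for
prioritizing regulatory non-coding sindels (nc-sindels), together with a
synthetic-data generator that lets the entire pipeline be exercised and
validated without any external downloads.

## Labeling from eQTL summary statistics

Labels come from cis-eQTL association tables. For each tissue:

* **Positives** are nc-sindels with indel length `< 100` bp, absolute
  distance to the nearest transcription start site `< 100` kb, and an
  FDR-adjusted association q-value `< 0.05` for at least one gene.
* **Negative candidates** satisfy the same length and distance bounds,
  are associated with at least one gene from the positive set, have
  q-value `> 0.2`, and their reference spans do not overlap any
  positive's span.
* The final negative set is **balanced and MAF-matched**: within every
  minor-allele-frequency bin of width 0.05, exactly as many negatives
  are drawn (uniformly, under a fixed seed) as there are positives.

All threshold comparisons are strict, following the verbal definitions
("less than", "larger than"); boundary records (length exactly 100,
q exactly 0.05) are excluded. Indel length is `|len(ref) − len(alt)|`,
the conventional allele-length difference.

Two interpretation choices were genuinely open and are worth recording.
First, a variant associated with several genes is collapsed to a single
record before filtering, keeping the minimum q-value across genes; on
the negative side we symmetrically require the *minimum* q across genes
to exceed 0.2, so a variant with any significant association anywhere
can never enter the negative set. Second, "non-overlap with the positive
set" is read as reference-span overlap rather than key identity — the
stricter reading, which prevents near-duplicate leakage between classes.
The MAF-matching algorithm itself is unspecified in the source
definitions; we use fixed-width binned sampling (width 0.05 by default,
configurable) because it makes the matched-histogram property exactly
assertable, rather than approximately true as with nearest-neighbor
schemes.

## Featurization

Each variant is represented by up to three feature blocks:

1. **Generic annotations** (`cadd:` prefix): a variants × 45 matrix of
   CADD-style functional annotations. Columns with ≥ 10% missing values
   are dropped (strictly below 10% is kept); remaining missing entries
   are imputed with the column median.
2. **Reference-window profiles** (`ref:`): a fixed-length window
   (`L = 1000` bp, even) is extracted around the variant so that the
   first reference-allele base sits at index `L/2`; a multi-task
   sequence model predicts `n_tracks = 919` epigenomic tracks
   (TF binding, DNase hypersensitivity, histone marks) from the one-hot
   encoded window. The one-hot channel order is (A, G, C, T):
   A→[1,0,0,0], G→[0,1,0,0], C→[0,0,1,0], T→[0,0,0,1]; N rows are
   all-zero.
3. **Alternative-window profiles** (`alt:`): the allele edit is applied
   at the anchor and the window restored to length `L` — a deletion
   pulls downstream reference bases in, an insertion pushes the tail
   out — so both windows always have identical length and an identical
   upstream half. The same predictor yields 919 more tracks, giving
   919 + 919 = 1838 profile features and a full width of
   `n_generic + 1838`.

The window anchor (variant centered, first ref base at `L/2`) is a
design choice: the symmetric placement gives both flanks equal context.
Predictor outputs are consumed as continuous probabilities in `[0, 1]`
rather than binarized tracks; thresholding would only discard signal.

### The synthetic profile predictor

Training a DanQ/DeepSEA-class network is out of scope; instead the
predictor is a pluggable interface (`ProfilePredictor`: deterministic,
`n_tracks` outputs in `[0, 1]`) with a deterministic synthetic
implementation: track *t* scores
`plogis(w_t · c / sqrt(m))`, where `c` are the window's k-mer counts
(`k = 6`), `m` the number of counted k-mers, and `w_t` a
seeded-random weight vector. This stand-in has the properties the
pipeline needs — determinism, bounded outputs, sensitivity to
single-base changes — while being transparent enough to plant signal
into (below). It is a synthetic stand-in, labeled as such, not an
emulation of any particular trained network.

## Classifier and evaluation protocols

A gradient-boosted tree ensemble (XGBoost) is trained per tissue:
500 trees, depth 6, learning rate 0.05, row subsampling 0.8, logistic
objective. These are conventional mid-size defaults — no hyperparameter
search is implied — and they are exposed in `default_hyperparams()`.
Fits use single-threaded histogram split finding (64 bins) so that
results are bit-reproducible under a fixed seed. Two baselines are
provided: a radial-kernel soft-margin SVM on the generic block only, and
a boosted logistic regression (depth-1 stumps, logistic loss) on the
profile-difference features `[|ref − alt| ; (ref − alt)/(ref + 1e-6)]`
(the ε stabilizer is ours; the transform's verbal definition does not
fix it).

Evaluation protocols:

* **Within-tissue**: stratified 5-fold cross-validation in which each
  variant is scored exactly once by a model that never saw it; the
  held-out scores are *pooled* into one vector and a single AUROC/AUPRC
  is computed on it (not averaged over folds).
* **Cross-tissue / independent-study transfer**: train on one featurized
  set, test on another; any test variant whose `chrom:pos:ref:alt` key
  appears in the training set is removed first. Exact-key identity is
  the removal criterion (span-overlap removal exists as an option).
* **Feature-set ablation**: the same CV protocol on `generic`,
  `generic+ref` and `generic+ref+alt` feature sets.

AUROC is the Mann-Whitney rank statistic (ties at half credit); AUPRC is
step-integrated average precision with a stable descending sort. Both
are asserted against brute-force pairwise/step oracles in the tests.

## Enrichment analysis

Regulatory region sets come from two sources: ChIP-seq-style peaks
(significant at FDR < 0.05, standardized to 1000 bp around the peak
midpoint) and promoter-centered chromatin interactions (intra-
chromosomal, anchor-midpoint distance ≤ 1 Mb, anchors standardized to
2 kb, significant at FDR < 0.1, tissues kept only when more than 100
significant interactions remain). Negative regions are drawn equal in
number with GC content matched bin-by-bin (width 0.05) to the positives
— the same binned-sampling machinery as MAF matching; for interactions,
GC is computed on the standardized 2-kb anchor windows (the raw anchors
are a second defensible choice; the windowed one matches what is
actually overlapped).

A variant is *in* a region class when its reference span overlaps any
interval of the class; for an interaction, hitting either anchor
suffices. The 2×2 table (n11: positives in positive regions, n12:
positives in negative regions, n21/n22 likewise for negatives) yields
the odds ratio `OR = (n11·n22)/(n12·n21)` and a one-sided (greater)
Fisher's exact p-value, computed by log-space hypergeometric summation.
The one-sided direction follows from the hypothesis being tested (are
positive nc-sindels *more* enriched in positive regions). Predicted
labels use a strict `score > 0.5` threshold, which makes the degenerate
all-scores-at-0.5 case deterministic (zero predicted positives). A
variant overlapping both region classes counts in both cells of its row
by default; an exclusive mode (positive wins) is available.

## The synthetic-data generator

`simulate_study()` emits every input the pipeline consumes — FASTA
genome, positive/candidate eQTL tables, annotation matrix, peaks,
interactions, and a machine-readable truth record — with controlled
signal:

* **Genome**: i.i.d. bases at a target GC of 0.41 (human-like), 3 Mb in
  two contigs by default.
* **Labels**: 1000 positives (q ~ U(0, 0.05)) and 4000 candidates
  (q ~ U(0.2, 1)); TSS distances U(0, 100 kb); MAF from Beta(2, 5)
  truncated to (0, 0.5], the same law for both classes so matching
  succeeds without relaxation (a deliberately mismatched mode exercises
  the deficient-bin error path).
* **Annotation signal**: 10 of 45 columns carry a +1 SD mean shift for
  positives; three designated columns get 2% missing entries and one
  gets 12%, so the missingness filter provably drops exactly that one.
* **Sequence signal**: the predictor's k-mer weights are boosted
  (factor 1 + `profile_effect`, default 5×) for the k-mers of a planted
  10-bp motif. A tandem tile of that motif is written *across the edit
  point* of every positive — so the allele edit disrupts boosted
  k-mers — and *downstream of the edit point* of every candidate — so
  the motif is present but intact. Because the predictor is
  count-based, the pure positional shift an indel causes does not move
  its output; only k-mers spanning the edit (or the window tail)
  change, which is exactly where the two classes are made to differ.
  With `profile_effect = 0` the classes are indistinguishable in
  `|ref − alt|`.
* **Region signal**: 500 non-overlapping 1-kb regulatory intervals are
  planted; negatives fall inside them with probability 0.15 and
  positives at the odds implied by the target odds ratio of 3. Because
  membership in the GC-matched negative windows is label-independent,
  the measured OR estimates the planted odds ratio directly.
* **Region files**: the planted intervals are emitted as significant
  peaks (plus non-significant decoys of varying width), and as anchors
  of significant interactions; inter-chromosomal and over-distance
  interaction rows with significant FDRs are included so the filters
  have something to remove.

What the generator does **not** emulate: linkage disequilibrium and
population structure (q-values and MAFs are drawn, not derived from
genotypes), correlated annotation blocks, sequence composition beyond
i.i.d. bases, and any realistic epigenomic track structure. Passing
tests on this generator therefore demonstrates that the machinery is
correct — filters filter, matching matches, protocols do not leak, a
planted effect of known size is recovered — not that any particular
real-data accuracy would be achieved.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  (VCF-style) positions are converted at the parser boundary
  (`read_eqtl(one_based = TRUE)` is the default).
* Scores serialize at 6 decimal places, making score-table round trips
  bit-identical.
* `odds_ratio` returns `Inf` for a zero denominator with positive
  numerator and errors when both products are zero; Fisher p of a table
  with an empty margin is 1.
* `match_maf`/GC matching fail loudly with the list of deficient bins
  rather than silently under-sampling; callers may relax the bin width.
* Out-of-window variants are skipped with a warning during window
  construction, not silently clamped.
* Single-thread fitting plus explicit seeds make every protocol result
  reproducible to the byte; re-running any generator or sampler with the
  same seed reproduces its output exactly.

## Problem sizes used in the validation suite

The packaged tests validate the metric implementations exactly
(exhaustive Fisher enumeration for all 2×2 tables with N ≤ 40; 200
random AUROC/AUPRC instances at n ≤ 30), the window contract on 500
simulated indels at L = 1000, matched sampling on 50 random draws, and
end-to-end signal recovery at the reference conditions (1000 + 1000
labeled variants, 919 tracks, 5-fold pooled CV, planted OR 3 with 500
regions). These sizes were chosen as the smallest at which the planted
effects are comfortably identifiable; the generator itself scales to
larger studies by changing `sim_config()`.

## Known limitations

* The synthetic predictor is not a trained sequence model; absolute
  score magnitudes carry no biological meaning.
* Enrichment p-values are reported raw, without multiple-testing
  correction across tissues or marks.
* No liftover, no BGZF/tabix indexing, no full VCF INFO/FORMAT parsing:
  inputs are plain tab-separated summary tables.
* Genome-wide scoring of tens of millions of variants is out of scope;
  the score-table interface covers storage and retrieval of precomputed
  scores.
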