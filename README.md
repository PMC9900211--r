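# regindel

Tissue-specific prioritization of regulatory non-coding small indels.

Small insertions and deletions (sindels) in non-coding DNA can disrupt
regulatory elements and change the expression of nearby genes, yet most
variant scorers target SNVs. `regindel` is for computational geneticists
who want a supervised, tissue-aware score for non-coding sindels
(nc-sindels) built from cis-eQTL evidence, and a fully synthetic test
bed to validate every step of such a pipeline without external data.

## What it does

1. **Labeling** — per tissue, positives are nc-sindels with indel length
   < 100 bp, |distance to TSS| < 100 kb and association q-value < 0.05;
   negatives have q > 0.2, share the positive gene pool, do not overlap
   any positive, and are drawn balanced with a minor-allele-frequency
   histogram exactly matched to the positives (binned sampling,
   width 0.05).
2. **Featurization** — each variant gets (i) generic functional
   annotations (columns with ≥ 10% missing dropped, the rest
   median-imputed) and (ii) epigenomic profiles predicted by a
   multi-task sequence model from a 1000-bp reference window and a
   length-matched alternative window carrying the allele edit:
   919 + 919 = 1838 profile features. The profile predictor is a
   pluggable interface with a deterministic synthetic k-mer
   implementation.
3. **Classification** — per-tissue XGBoost (500 trees, depth 6,
   η = 0.05), scored by pooled stratified 5-fold cross-validation
   (AUROC = rank concordance, AUPRC = average precision), cross-tissue
   and independent-study transfer with exact-key overlap removal, and
   two baselines (radial SVM on annotations; boosted logistic
   regression on profile differences).
4. **Enrichment** — odds ratio `OR = (n11·n22)/(n12·n21)` and one-sided
   Fisher's exact test of true and predicted (score > 0.5) labels in
   regulatory regions: 1000-bp standardized ChIP-seq peaks (FDR < 0.05)
   and 2-kb promoter-capture Hi-C anchor windows (FDR < 0.1,
   intra-chromosomal, ≤ 1 Mb), against GC-matched negative regions.
5. **Simulation** — `simulate_study()` generates genome, eQTL tables,
   annotations, peaks and interactions with planted, parameterized
   signal (annotation effect in SD units, motif-disruption sequence
   signal, region odds ratio), so recovery of known truth is testable
   end to end.

## Worked example

```r
library(regindel)

cfg <- sim_config(genome_length = 6e5, n_contigs = 2, n_pos = 150,
                  n_neg_candidates = 600, n_regions = 60, n_tracks = 50,
                  L = 1000, seed = 42)
study <- simulate_study(cfg)

lset <- build_labeled_set("SimTissue", study$pos_records,
                          study$cand_records, seed = 42)
#> <labeled_set> tissue=SimTissue: 150 positives, 150 negatives

annots <- filter_and_impute(study$annotations)
pred   <- study_predictor(study)
fs     <- featurize_labeled_set(lset, study$genome, annots, pred)
dim(fs$X)   # 300 variants x (44 generic + 2*50 profile) features
#> [1] 300 144

res <- cv_pooled(fs$X, fs$y, k = 5, seed = 42, tissue = "SimTissue")
#> <eval_result> cv SimTissue->SimTissue: AUROC 0.9776, AUPRC 0.9804 (n=300)

regions <- build_peak_sets(study$peaks, study$genome, seed = 42)
vars <- rbind(lset$positives[, c("chrom","pos","ref","alt")],
              lset$negatives[, c("chrom","pos","ref","alt")])
enrich_report(vars, fs$y, res$scores, regions)
#>   label label_source n11 n12 n21 n22 odds_ratio      p_value
#> 1               true  50   6  20  15       6.25 0.0005556969
#> 2          predicted  45   7  25  14       3.60 0.0119646994
```

The pooled AUROC of 0.98 reflects recovery of the planted annotation
and motif-disruption signal; the odds ratios say that label-positive
(and predicted-positive) indels sit in the planted regulatory regions
far more often than the GC-matched background expects, with one-sided
Fisher p-values well below 0.05. (At this small example size the OR
estimate is noisy; at the reference scale of 1000+1000 variants it
concentrates near the planted value of 3.)

A command-line front-end mirroring these steps (subcommands `simulate`,
`build-trainset`, `featurize`, `train`, `eval`, `predict`, `enrich`,
`scores`) is installed at `inst/scripts/regindel`.

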