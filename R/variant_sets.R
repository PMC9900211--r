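#' Select positive nc-sindels from eQTL records
#'
#' Positives are small non-coding indels with a significant cis-eQTL
#' association: indel length < `max_len` bp, absolute distance to the
#' transcription start site < `max_tss` bp, and q-value < `q_max` for at
#' least one associated gene. All comparisons are strict. A variant
#' associated with several genes counts once; its minimum q-value across
#' genes decides, and the record carrying that minimum is kept.
#'
#' @param records eQTL record data frame (see [read_eqtl()]).
#' @param max_len Maximum indel length in bp (exclusive).
#' @param max_tss Maximum |distance to TSS| in bp (exclusive).
#' @param q_max q-value threshold (exclusive).
#' @return Subset of `records`, one row per selected variant.
#' @export
select_positives <- function(records, max_len = 100, max_tss = 1e5, q_max = 0.05) {
  if (nrow(records) == 0L) return(records)
  keep <- indel_length(records) >= 1 &
    indel_length(records) < max_len &
    records$tss_distance < max_tss
  r <- records[keep, , drop = FALSE]
  r <- collapse_min_q(r)
  out <- r[r$q_value < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one row per variant key: the row with the minimum q-value across genes
collapse_min_q <- function(r) {
  if (nrow(r) == 0L) return(r)
  key <- variant_key(r)
  ord <- order(key, r$q_value)
  r <- r[ord, , drop = FALSE]
  r[!duplicated(key[ord]), , drop = FALSE]
}

#' Select negative-candidate nc-sindels
#'
#' Candidates for the negative set are small indels that (i) do not
#' overlap (by reference span) any positive variant, (ii) satisfy the
#' same length and TSS-distance bounds as positives, (iii) are associated
#' with at least one gene from the positive set, and (iv) have minimum
#' q-value across genes > `q_min` (no significant association anywhere).
#'
#' @param records eQTL record data frame (typically from a second study
#'   release).
#' @param positives Output of [select_positives()].
#' @inheritParams select_positives
#' @param q_min q-value floor (exclusive).
#' @return Subset of `records`, one row per candidate variant.
#' @export
select_negative_candidates <- function(records, positives, max_len = 100,
                                       max_tss = 1e5, q_min = 0.2) {
  if (nrow(records) == 0L) return(records)
  pos_genes <- unique(positives$gene)
  keep <- indel_length(records) >= 1 &
    indel_length(records) < max_len &
    records$tss_distance < max_tss
  r <- records[keep, , drop = FALSE]
  # the q floor applies to a variant's minimum q over *all* its genes:
  # any significant association anywhere disqualifies it as a negative
  key <- variant_key(r)
  minq <- tapply(r$q_value, key, min)
  r <- r[minq[key] > q_min & r$gene %in% pos_genes, , drop = FALSE]
  r <- collapse_min_q(r)
  if (nrow(r) > 0L && nrow(positives) > 0L) {
    hit <- overlaps_any(variant_span(r), variant_span(positives))
    r <- r[!hit, , drop = FALSE]
  }
  rownames(r) <- NULL
  r
}

#' Binned matched sampling
#'
#' Shared machinery for MAF matching and GC matching: values are binned
#' into fixed-width bins `[k*w, (k+1)*w)` and, per bin, as many
#' candidates as there are reference values are drawn uniformly without
#' replacement. Errors if any bin has fewer candidates than needed,
#' listing the deficient bins.
#'
#' @param ref_values Numeric vector defining the target histogram.
#' @param cand_values Numeric vector for the candidate pool.
#' @param bin_width Bin width `w`.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param what Label used in error messages ("MAF", "GC", ...).
#' @return Integer indices into the candidate pool, length
#'   `length(ref_values)`.
#' @export
matched_sample <- function(ref_values, cand_values, bin_width, seed,
                           what = "value") {
  stopifnot(length(ref_values) > 0L, length(cand_values) > 0L, bin_width > 0)
  rb <- floor(ref_values / bin_width)
  cb <- floor(cand_values / bin_width)
  need <- table(rb)
  have <- table(factor(cb, levels = names(need)))
  deficient <- names(need)[as.integer(have) < as.integer(need)]
  if (length(deficient) > 0L) {
    lo <- as.numeric(deficient) * bin_width
    stop(sprintf(
      "deficient %s bin(s) for matched sampling: %s (consider a larger bin width)",
      what,
      paste(sprintf("[%.3g,%.3g) need %d have %d", lo, lo + bin_width,
                    as.integer(need[deficient]),
                    as.integer(have[deficient])), collapse = "; ")))
  }
  withr::with_seed(seed, {
    idx <- unlist(lapply(names(need), function(b) {
      pool <- which(cb == as.numeric(b))
      k <- as.integer(need[[b]])
      if (length(pool) == 1L) pool else sample(pool, k)
    }), use.names = FALSE)
  })
  sort(idx)
}

#' MAF-matched balanced sampling of negatives
#'
#' Draws a subset of candidates whose per-bin minor-allele-frequency
#' histogram equals the positives' exactly at the configured bin width,
#' yielding a balanced negative set (`|negatives| == |positives|`).
#'
#' @param candidates Output of [select_negative_candidates()].
#' @param positives Output of [select_positives()].
#' @param bin_width MAF bin width (default 0.05).
#' @param seed Integer seed.
#' @return Subset of `candidates` with matched MAF spectrum.
#' @export
match_maf <- function(candidates, positives, bin_width = 0.05, seed = 1L) {
  if (nrow(positives) == 0L) stop("empty positive set")
  if (nrow(candidates) == 0L) stop("empty candidate set")
  idx <- matched_sample(positives$maf, candidates$maf, bin_width, seed,
                        what = "MAF")
  out <- candidates[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a tissue-specific labeled nc-sindel set
#'
#' Runs positive selection, negative-candidate selection and MAF-matched
#' balancing, returning a `labeled_set`: disjoint positive and negative
#' eQTL records for one tissue. Deterministic under `seed`.
#'
#' @param tissue Tissue label.
#' @param pos_records eQTL records from the positive-source study.
#' @param neg_records eQTL records from the negative-source study.
#' @param bin_width MAF bin width for matching.
#' @param seed Integer seed.
#' @param max_len,max_tss,q_max,q_min Selection thresholds (see
#'   [select_positives()] and [select_negative_candidates()]).
#' @return A `labeled_set` object: list with `tissue`, `positives`,
#'   `negatives` (eQTL record data frames).
#' @export
build_labeled_set <- function(tissue, pos_records, neg_records,
                              bin_width = 0.05, seed = 1L,
                              max_len = 100, max_tss = 1e5,
                              q_max = 0.05, q_min = 0.2) {
  pos <- select_positives(pos_records, max_len, max_tss, q_max)
  if (nrow(pos) == 0L) stop("empty positive set for tissue ", tissue)
  cand <- select_negative_candidates(neg_records, pos, max_len, max_tss, q_min)
  neg <- match_maf(cand, pos, bin_width, seed)
  labeled_set(tissue, pos, neg)
}

#' Construct a labeled_set (with invariant checks)
#' @param tissue Tissue label.
#' @param positives,negatives Variant-bearing data frames.
#' @param balanced Whether to require `|negatives| == |positives|`.
#' @return A `labeled_set` object.
#' @export
labeled_set <- function(tissue, positives, negatives, balanced = TRUE) {
  pk <- variant_key(positives)
  nk <- variant_key(negatives)
  if (length(intersect(pk, nk)) > 0L) {
    stop("positive and negative variant keys are not disjoint")
  }
  if (balanced && nrow(positives) != nrow(negatives)) {
    stop("labeled set is not balanced: ", nrow(positives), " positives vs ",
         nrow(negatives), " negatives")
  }
  structure(list(tissue = tissue, positives = positives, negatives = negatives),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat("<labeled_set> tissue=", x$tissue, ": ", nrow(x$positives),
      " positives, ", nrow(x$negatives), " negatives\n", sep = "")
  invisible(x)
}

#' Select pathogenic/benign nc-sindels from a ClinVar-style table
#'
#' Positives are records with `ClinicalSignificance` exactly
#' `"Pathogenic"`, negatives exactly `"Benign"`; both are restricted to
#' indel length < `max_len`, variant type in
#' `{Insertion, Deletion, Indel, Duplication}`, and review status in
#' `{"multiple submitters, no conflicts", "reviewed by expert panel"}`.
#' No class balancing is applied; empty classes are allowed (with a
#' message).
#'
#' @param records Data frame from [read_clinvar()].
#' @param max_len Maximum indel length in bp (exclusive).
#' @return A `labeled_set` (unbalanced).
#' @export
select_clinvar_sindels <- function(records, max_len = 100) {
  types_ok <- c("Insertion", "Deletion", "Indel", "Duplication")
  review_ok <- c("multiple submitters, no conflicts", "reviewed by expert panel")
  keep <- indel_length(records) >= 1 &
    indel_length(records) < max_len &
    records$variant_type %in% types_ok &
    records$review_status %in% review_ok
  r <- records[keep, , drop = FALSE]
  pos <- r[r$clinical_significance == "Pathogenic", , drop = FALSE]
  neg <- r[r$clinical_significance == "Benign", , drop = FALSE]
  if (nrow(pos) == 0L) message("ClinVar selection: no pathogenic nc-sindels passed the filters")
  if (nrow(neg) == 0L) message("ClinVar selection: no benign nc-sindels passed the filters")
  rownames(pos) <- rownames(neg) <- NULL
  labeled_set("clinvar", pos, neg, balanced = FALSE)
}
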