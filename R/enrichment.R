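#' Read a peak table (BED3 + FDR)
#'
#' Tab-delimited `chrom`, `start`, `end` (0-based half-open), `fdr`.
#' A header line is detected and skipped if present.
#'
#' @param path Path to the file.
#' @return Data frame with columns `chrom`, `start`, `end`, `fdr`.
#' @export
read_peaks <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- is.na(suppressWarnings(as.numeric(first[2])))
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("chrom", "start", "end", "fdr")
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  tab$fdr <- as.numeric(tab$fdr)
  if (any(tab$fdr < 0 | tab$fdr > 1)) stop("peak FDR outside [0, 1] in ", path)
  tab
}

#' Read a chromatin-interaction table
#'
#' Tab-delimited with header `chrom1, start1, end1, chrom2, start2,
#' end2, fdr, itype` (anchors 0-based half-open; `itype` is `PE` or
#' `PP`).
#'
#' @param path Path to the file.
#' @return Data frame of interactions.
#' @export
read_interactions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "fdr", "itype")
  if (!all(req %in% names(tab))) {
    stop("interaction table must have columns ", paste(req, collapse = ", "))
  }
  if (!all(tab$itype %in% c("PE", "PP"))) stop("itype must be PE or PP")
  if (any(tab$fdr < 0 | tab$fdr > 1)) stop("interaction FDR outside [0, 1]")
  tab
}

#' Standardize peaks to fixed-width windows
#'
#' `width`-bp window centered on the peak midpoint
#' (`floor((start+end)/2)` +/- `width/2`); out-of-bounds windows are
#' dropped with a warning.
#'
#' @param peaks Peak data frame (or any interval data frame).
#' @param width Window width (default 1000 bp).
#' @param genome Optional `genome_seq` for bounds checking.
#' @return Interval data frame of standardized windows.
#' @export
standardize_peak <- function(peaks, width = 1000L, genome = NULL) {
  center_window(peaks, width, genome)
}

#' Standardize interaction anchors to fixed-width windows
#'
#' @param anchors Interval data frame of anchors.
#' @param width Window width (default 2000 bp: 1 kb each side of the
#'   anchor midpoint).
#' @param genome Optional `genome_seq` for bounds checking.
#' @return Interval data frame of anchor windows.
#' @export
anchor_window <- function(anchors, width = 2000L, genome = NULL) {
  center_window(anchors, width, genome)
}

#' Construct a region set
#' @param positive,negative Interval data frames.
#' @param kind `"peak"` or `"interaction"`.
#' @param label Provenance label (tissue, mark or interaction type).
#' @return A `region_set` object.
#' @export
region_set <- function(positive, negative, kind, label = "") {
  structure(list(positive = positive, negative = negative,
                 kind = kind, label = label),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", x$kind, " '", x$label, "': ", nrow(x$positive),
      " positive / ", nrow(x$negative), " negative interval(s)\n", sep = "")
  invisible(x)
}

#' Build positive/negative interaction region sets
#'
#' Filters to intra-chromosomal interactions with anchor-midpoint
#' distance at most `max_dist`, formats each anchor into a `width`-bp
#' window around its midpoint, labels interactions with FDR < `fdr_pos`
#' as positive (requiring more than `min_pos` of them, else the tissue
#' is excluded and `NULL` returned with a warning), and samples an equal
#' number of negatives from FDR > `fdr_neg` candidates with GC content
#' (computed on the concatenated anchor windows) matched bin-by-bin to
#' the positives.
#'
#' @param interactions Data frame from [read_interactions()].
#' @param genome A `genome_seq`.
#' @param fdr_pos,fdr_neg FDR cutoffs for positives / negative
#'   candidates.
#' @param max_dist Maximum anchor-midpoint distance in bp.
#' @param min_pos Minimum (exclusive) number of significant interactions
#'   for a set to be returned.
#' @param width Anchor window width.
#' @param gc_bin GC bin width for matched sampling.
#' @param seed Integer seed.
#' @param label Provenance label.
#' @return Named list (`PE`, `PP`) of `region_set` objects (entries may
#'   be `NULL` when a type is excluded). Region intervals carry an `id`
#'   column pairing the two anchors of each interaction.
#' @export
build_interaction_sets <- function(interactions, genome, fdr_pos = 0.1,
                                   fdr_neg = 0.5, max_dist = 1e6,
                                   min_pos = 100L, width = 2000L,
                                   gc_bin = 0.05, seed = 1L, label = "") {
  intra <- interactions$chrom1 == interactions$chrom2
  mid1 <- floor((interactions$start1 + interactions$end1) / 2)
  mid2 <- floor((interactions$start2 + interactions$end2) / 2)
  keep <- intra & abs(mid1 - mid2) <= max_dist
  ia <- interactions[keep, , drop = FALSE]

  out <- list(PE = NULL, PP = NULL)
  for (ty in c("PE", "PP")) {
    x <- ia[ia$itype == ty, , drop = FALSE]
    if (nrow(x) == 0L) next
    m1 <- floor((x$start1 + x$end1) / 2)
    m2 <- floor((x$start2 + x$end2) / 2)
    w1 <- data.frame(chrom = x$chrom1, start = m1 - width / 2,
                     end = m1 + width / 2, stringsAsFactors = FALSE)
    w2 <- data.frame(chrom = x$chrom2, start = m2 - width / 2,
                     end = m2 + width / 2, stringsAsFactors = FALSE)
    lens <- contig_lengths(genome)
    ok <- w1$start >= 0 & w2$start >= 0 &
      w1$end <= lens[w1$chrom] & w2$end <= lens[w2$chrom]
    if (any(!ok)) warning(sum(!ok), " ", ty, " interaction(s) with out-of-bounds anchor window(s) dropped")
    x <- x[ok, , drop = FALSE]; w1 <- w1[ok, , drop = FALSE]; w2 <- w2[ok, , drop = FALSE]
    if (nrow(x) == 0L) next
    gc <- (gc_content(fetch_seqs(genome, w1)) + gc_content(fetch_seqs(genome, w2))) / 2
    is_pos <- x$fdr < fdr_pos
    if (sum(is_pos) <= min_pos) {
      warning(sprintf("%s: only %d significant interactions (need > %d); excluded",
                      ty, sum(is_pos), min_pos))
      next
    }
    is_cand <- x$fdr > fdr_neg
    idx <- matched_sample(gc[is_pos], gc[is_cand], gc_bin, seed, what = "GC")
    cand_rows <- which(is_cand)[idx]
    out[[ty]] <- region_set(
      positive = anchors_long(w1, w2, which(is_pos)),
      negative = anchors_long(w1, w2, cand_rows),
      kind = "interaction",
      label = paste0(label, if (nzchar(label)) ":" else "", ty))
  }
  out
}

# two anchor windows per interaction, stacked long with an id column
anchors_long <- function(w1, w2, rows) {
  a <- rbind(w1[rows, c("chrom", "start", "end")],
             w2[rows, c("chrom", "start", "end")])
  a$id <- rep(seq_along(rows), 2L)
  rownames(a) <- NULL
  a
}

fetch_seqs <- function(genome, iv) {
  vapply(seq_len(nrow(iv)),
         function(i) fetch_range(genome, iv$chrom[i], iv$start[i], iv$end[i]),
         character(1))
}

#' Build positive/negative peak region sets
#'
#' Positives are `width`-bp standardized windows of peaks with FDR <
#' `fdr_pos`. Negatives are an equal number of random `width`-bp genomic
#' windows, disjoint from every positive window, whose GC-content
#' histogram matches the positives' bin-by-bin at width `gc_bin`
#' (rejection sampling, deterministic under `seed`).
#'
#' @param peaks Peak data frame from [read_peaks()].
#' @param genome A `genome_seq`.
#' @param fdr_pos FDR cutoff for significant peaks.
#' @param width Standardized window width.
#' @param gc_bin GC bin width.
#' @param seed Integer seed.
#' @param max_tries Sampling attempts per needed window before giving
#'   up.
#' @param label Provenance label.
#' @return A `region_set`.
#' @export
build_peak_sets <- function(peaks, genome, fdr_pos = 0.05, width = 1000L,
                            gc_bin = 0.05, seed = 1L, max_tries = 1000L,
                            label = "") {
  sig <- peaks[peaks$fdr < fdr_pos, , drop = FALSE]
  if (nrow(sig) == 0L) stop("empty positive set: no peaks below FDR ", fdr_pos)
  pos <- standardize_peak(sig, width, genome)
  if (nrow(pos) == 0L) stop("empty positive set after bounds filtering")
  need <- table(floor(gc_content(fetch_seqs(genome, pos)) / gc_bin))
  lens <- contig_lengths(genome)
  lens <- lens[lens >= width]
  if (length(lens) == 0L) stop("genome too small to place matched windows")
  neg <- vector("list", sum(need))
  got <- setNames(rep(0L, length(need)), names(need))
  withr::with_seed(seed, {
    total <- 0L
    tries <- 0L
    budget <- max_tries * sum(need)
    while (total < sum(need)) {
      tries <- tries + 1L
      if (tries > budget) {
        stop("genome too small to place enough GC-matched windows; deficient GC bin(s): ",
             paste(names(need)[got < as.integer(need)], collapse = ", "))
      }
      chrom <- names(lens)[sample.int(length(lens), 1L, prob = lens)]
      start <- sample.int(lens[[chrom]] - width + 1L, 1L) - 1L
      w <- ginterval(chrom, start, start + width)
      if (any(overlaps_any(w, pos))) next
      b <- as.character(floor(gc_content(fetch_range(genome, chrom, start, start + width)) / gc_bin))
      if (is.na(got[b]) || got[b] >= as.integer(need[b])) next
      got[b] <- got[b] + 1L
      total <- total + 1L
      neg[[total]] <- w
    }
  })
  negatives <- do.call(rbind, neg)
  rownames(negatives) <- NULL
  region_set(pos[, c("chrom", "start", "end")], negatives, "peak", label)
}

#' Count the 2x2 variant-by-region contingency table
#'
#' A variant is "in" a region class when its reference span overlaps any
#' interval of that class (for interaction sets: either anchor window —
#' hitting one anchor suffices). By default a variant overlapping both
#' classes counts in both cells of its row; with `exclusive = TRUE` the
#' positive class wins.
#'
#' @param pos_vars,neg_vars Variant data frames (label-positive and
#'   label-negative variants).
#' @param regions A `region_set`.
#' @param exclusive Whether a double-hit counts only as positive-region.
#' @return A `contingency_table`: named integer vector
#'   `(n11, n12, n21, n22)` — positives-in-positive-regions,
#'   positives-in-negative-regions, negatives-in-positive-regions,
#'   negatives-in-negative-regions.
#' @export
count_contingency <- function(pos_vars, neg_vars, regions, exclusive = FALSE) {
  stopifnot(inherits(regions, "region_set"))
  tally <- function(v) {
    if (nrow(v) == 0L) return(c(0L, 0L))
    sp <- variant_span(v)
    in_pos <- overlaps_any(sp, regions$positive)
    in_neg <- overlaps_any(sp, regions$negative)
    if (exclusive) in_neg <- in_neg & !in_pos
    c(sum(in_pos), sum(in_neg))
  }
  p <- tally(pos_vars)
  n <- tally(neg_vars)
  structure(c(n11 = p[1], n12 = p[2], n21 = n[1], n22 = n[2]),
            class = "contingency_table")
}

as_counts <- function(t) {
  if (is.list(t)) t <- unlist(t)
  t <- as.numeric(t)
  stopifnot(length(t) == 4L, all(t >= 0), all(t == round(t)))
  t
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (n11 * n22) / (n12 * n21)`. Returns `Inf` when the denominator
#' is zero but the numerator is positive; a table with both products
#' zero has no defined OR (error).
#'
#' @param t A `contingency_table` or length-4 vector
#'   `(n11, n12, n21, n22)`.
#' @return Odds ratio in `[0, Inf]`.
#' @examples
#' odds_ratio(c(10, 5, 5, 10)) # 4
#' @export
odds_ratio <- function(t) {
  t <- as_counts(t)
  num <- t[1] * t[4]
  den <- t[2] * t[3]
  if (den == 0) {
    if (num == 0) stop("odds ratio undefined: n11*n22 and n12*n21 are both zero")
    return(Inf)
  }
  num / den
}

#' One-sided Fisher's exact test (greater) on a 2x2 table
#'
#' Exact p-value under the hypergeometric null with the observed
#' margins: the probability of `n11` at least as large as observed,
#' testing enrichment of positive variants in positive regions. Computed
#' by log-space summation of hypergeometric point masses.
#'
#' @param t A `contingency_table` or length-4 vector
#'   `(n11, n12, n21, n22)`.
#' @return p-value in `(0, 1]`; a table with an empty margin gives 1.
#' @export
fisher_one_sided <- function(t) {
  t <- as_counts(t)
  n11 <- t[1]
  K <- t[1] + t[2]           # label-positive variants
  nn <- t[1] + t[3]          # variants in positive regions
  N <- sum(t)
  if (N == 0 || K == 0 || nn == 0 || K == N || nn == N) return(1)
  kk <- n11:min(K, nn)
  p <- sum(exp(stats::dhyper(kk, K, N - K, nn, log = TRUE)))
  min(p, 1)
}

#' Enrichment report for true and predicted labels
#'
#' Builds two contingency tables over the same variants — one
#' partitioned by the true labels, one by thresholded prediction scores
#' (`score > threshold` is a predicted positive, strictly) — and reports
#' the odds ratio and one-sided Fisher p for each.
#'
#' @param vars Variant data frame, aligned with `true_labels` and
#'   `scores`.
#' @param true_labels Binary labels.
#' @param scores Prediction scores in `[0, 1]`.
#' @param regions A `region_set`.
#' @param threshold Prediction threshold (default 0.5, strict `>`).
#' @param exclusive Passed to [count_contingency()].
#' @return Data frame with one row per `label_source`
#'   (`"true"`, `"predicted"`): `n11..n22`, `odds_ratio`, `p_value`.
#' @export
enrich_report <- function(vars, true_labels, scores, regions,
                          threshold = 0.5, exclusive = FALSE) {
  true_labels <- as.integer(true_labels)
  stopifnot(nrow(vars) == length(true_labels),
            length(scores) == length(true_labels))
  pred_labels <- as.integer(scores > threshold)
  one <- function(lab, source) {
    ct <- count_contingency(vars[lab == 1L, , drop = FALSE],
                            vars[lab == 0L, , drop = FALSE],
                            regions, exclusive)
    orv <- tryCatch(odds_ratio(ct), error = function(e) NA_real_)
    data.frame(label = regions$label, label_source = source,
               n11 = ct[1], n12 = ct[2], n21 = ct[3], n22 = ct[4],
               odds_ratio = orv, p_value = fisher_one_sided(ct),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(one(true_labels, "true"), one(pred_labels, "predicted"))
}
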