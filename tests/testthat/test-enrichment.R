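# exact enumeration oracle for the one-sided Fisher test, via binomial
# coefficients only (independent of dhyper)
fisher_oracle <- function(n11, n12, n21, n22) {
  N <- n11 + n12 + n21 + n22
  K <- n11 + n12
  n <- n11 + n21
  if (N == 0 || K == 0 || n == 0 || K == N || n == N) return(1)
  kk <- max(0, K + n - N):min(K, n)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= n11])
}

test_that("peak standardization centers a fixed-width window on the midpoint", {
  g <- genome_seq(c(c1 = rand_seq(20000)))
  p <- data.frame(chrom = "c1", start = 10000, end = 10400, fdr = 0.01)
  w <- standardize_peak(p, 1000, g)
  expect_equal(c(w$start, w$end), c(9700, 10700))
  # already standardized: unchanged
  p2 <- data.frame(chrom = "c1", start = 5000, end = 6000, fdr = 0.01)
  w2 <- standardize_peak(p2, 1000, g)
  expect_equal(c(w2$start, w2$end), c(5000, 6000))
  # short contig: dropped with a warning
  gs <- genome_seq(c(c1 = rand_seq(900)))
  expect_warning(w3 <- standardize_peak(data.frame(chrom = "c1", start = 100,
                                                   end = 700, fdr = 0.01),
                                        1000, gs), "dropped")
  expect_equal(nrow(w3), 0L)
})

test_that("anchor windows span 1 kb each side of the anchor midpoint", {
  g <- genome_seq(c(c1 = rand_seq(20000)))
  a <- ginterval("c1", 5000, 7000)
  w <- anchor_window(a, 2000, g)
  expect_equal(c(w$start, w$end), c(5000, 7000))
  w2 <- anchor_window(ginterval("c1", 5000, 5002), 2000, g)
  expect_equal(c(w2$start, w2$end), c(4001, 6001))
  expect_warning(anchor_window(ginterval("c1", 0, 10), 2000, g), "dropped")
})

test_that("interaction sets apply distance, chromosome, FDR and count filters", {
  st <- small_study()
  ia <- read_interactions_df <- st$interactions
  sets <- suppressWarnings(
    build_interaction_sets(ia, st$genome, min_pos = 10, seed = 2))
  for (ty in c("PE", "PP")) {
    rs <- sets[[ty]]
    expect_s3_class(rs, "region_set")
    # balanced: equal numbers of interactions on both sides (2 anchors each)
    expect_identical(nrow(rs$negative), nrow(rs$positive))
    expect_true(all(rs$positive$end - rs$positive$start == 2000))
    # GC histograms of per-interaction mean anchor GC match exactly
    gc_of <- function(iv) {
      g <- gc_content(vapply(seq_len(nrow(iv)), function(i) {
        fetch_range(st$genome, iv$chrom[i], iv$start[i], iv$end[i])
      }, character(1)))
      tapply(g, iv$id, mean)
    }
    expect_equal(table(floor(gc_of(rs$positive) / 0.05)),
                 table(floor(gc_of(rs$negative) / 0.05)))
  }
  # inter-chromosomal significant rows never make it into the positives
  ic <- ia[ia$chrom1 != ia$chrom2, ]
  expect_gt(nrow(ic), 0)
  expect_true(all(ic$fdr < 0.1))   # they would qualify if not filtered
  # distance > 1e6 rows are exercised only on genomes long enough
  # min_pos exclusion: raise the bar beyond the significant count
  w <- testthat::capture_warnings(
    none <- build_interaction_sets(ia, st$genome, min_pos = 1e4, seed = 2))
  expect_match(w, "excluded", all = TRUE)
  expect_length(w, 2)
  expect_null(none$PE)
  expect_null(none$PP)
})

test_that("far-distance interactions are removed before labeling", {
  cfg <- sim_config(genome_length = 2.6e6, n_contigs = 2, n_pos = 10,
                    n_neg_candidates = 40, n_regions = 30, n_tracks = 4,
                    kmer_k = 4, L = 200, n_int_sig = 15, n_int_cand = 40,
                    n_int_interchrom = 4, n_int_far = 10,
                    n_nonsig_peaks = 10, seed = 21)
  st <- simulate_study(cfg)
  far <- st$interactions[st$interactions$chrom1 == st$interactions$chrom2 &
                           abs(floor((st$interactions$start1 + st$interactions$end1) / 2) -
                                 floor((st$interactions$start2 + st$interactions$end2) / 2)) > 1e6, ]
  expect_gt(nrow(far), 0)
  expect_true(all(far$fdr < 0.1))
  sets <- suppressWarnings(
    build_interaction_sets(st$interactions, st$genome, min_pos = 5, seed = 1))
  # all surviving positive anchors come from pairs within 1 Mb
  for (ty in c("PE", "PP")) {
    pos <- sets[[ty]]$positive
    d <- tapply(seq_len(nrow(pos)), pos$id, function(i) {
      abs(diff(floor((pos$start[i] + pos$end[i]) / 2)))
    })
    expect_true(all(unlist(d) <= 1e6 + 2000))
  }
})

test_that("peak sets are GC-matched, disjoint from positives and reproducible", {
  st <- small_study()
  rs <- build_peak_sets(st$peaks, st$genome, seed = 4)
  expect_identical(nrow(rs$negative), nrow(rs$positive))
  expect_false(any(overlaps_any(rs$negative, rs$positive)))
  gc_pos <- gc_content(vapply(seq_len(nrow(rs$positive)), function(i) {
    fetch_range(st$genome, rs$positive$chrom[i], rs$positive$start[i],
                rs$positive$end[i])
  }, character(1)))
  gc_neg <- gc_content(vapply(seq_len(nrow(rs$negative)), function(i) {
    fetch_range(st$genome, rs$negative$chrom[i], rs$negative$start[i],
                rs$negative$end[i])
  }, character(1)))
  expect_equal(table(floor(gc_pos / 0.05)), table(floor(gc_neg / 0.05)))
  rs2 <- build_peak_sets(st$peaks, st$genome, seed = 4)
  expect_identical(rs$negative, rs2$negative)
  rs3 <- build_peak_sets(st$peaks, st$genome, seed = 5)
  expect_false(identical(rs$negative, rs3$negative))
  # no significant peaks
  none <- st$peaks; none$fdr <- 0.5
  expect_error(build_peak_sets(none, st$genome), "empty positive set")
})

test_that("contingency counting uses span overlap and the either-anchor rule", {
  rs <- region_set(positive = data.frame(chrom = "c1", start = 100, end = 200),
                   negative = data.frame(chrom = "c1", start = 500, end = 600),
                   kind = "peak")
  pv <- variants("c1", 150, "ACG", "A")
  ct <- count_contingency(pv, pv[0, ], rs)
  expect_equal(unclass(ct), c(n11 = 1L, n12 = 0L, n21 = 0L, n22 = 0L))
  # half-open boundary: a variant starting at the window end is outside
  edge <- variants("c1", 200, "AC", "A")
  ct2 <- count_contingency(edge, edge[0, ], rs)
  expect_equal(ct2[["n11"]], 0L)
  # last covered base
  inb <- variants("c1", 199, "AC", "A")
  expect_equal(count_contingency(inb, inb[0, ], rs)[["n11"]], 1L)
  # either anchor suffices for interactions
  irs <- region_set(
    positive = data.frame(chrom = "c1", start = c(100, 900),
                          end = c(300, 1100), id = c(1L, 1L)),
    negative = data.frame(chrom = "c1", start = 2000, end = 2200, id = 1L),
    kind = "interaction")
  anchor2_hit <- variants("c1", 1000, "AT", "A")
  expect_equal(count_contingency(anchor2_hit, anchor2_hit[0, ], irs)[["n11"]], 1L)
})

test_that("double-hit handling counts both classes unless exclusive", {
  rs <- region_set(positive = data.frame(chrom = "c1", start = 100, end = 200),
                   negative = data.frame(chrom = "c1", start = 150, end = 250),
                   kind = "peak")
  v <- variants("c1", 160, "ACG", "A")
  both <- count_contingency(v, v[0, ], rs)
  expect_equal(unclass(both)[1:2], c(n11 = 1L, n12 = 1L))
  excl <- count_contingency(v, v[0, ], rs, exclusive = TRUE)
  expect_equal(unclass(excl)[1:2], c(n11 = 1L, n12 = 0L))
})

test_that("odds ratio follows the cross-product formula with scale invariance", {
  expect_equal(odds_ratio(c(10, 5, 5, 10)), 4.0)
  expect_equal(odds_ratio(c(0, 5, 5, 10)), 0.0)
  expect_identical(odds_ratio(c(3, 0, 5, 10)), Inf)
  expect_error(odds_ratio(c(0, 0, 5, 0)), "undefined")
  for (k in c(1, 2, 7)) {
    expect_equal(odds_ratio(k * c(10, 5, 5, 10)), 4.0)
  }
})

test_that("one-sided Fisher p matches enumeration exactly", {
  expect_equal(fisher_one_sided(c(3, 1, 1, 3)), 17 / 70)
  expect_equal(fisher_one_sided(c(0, 0, 0, 0)), 1.0)
  # every table with N <= 12 here; the full N <= 40 sweep runs in the
  # acceptance suite
  for (N in 2:12) {
    for (n11 in 0:N) for (n12 in 0:(N - n11)) for (n21 in 0:(N - n11 - n12)) {
      n22 <- N - n11 - n12 - n21
      expect_equal(fisher_one_sided(c(n11, n12, n21, n22)),
                   fisher_oracle(n11, n12, n21, n22))
    }
  }
})

test_that("one-sided Fisher p agrees with stats::fisher.test", {
  withr::with_seed(17, {
    for (i in 1:25) {
      t <- rpois(4, lambda = sample(3:40, 1))
      ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                               alternative = "greater")
      expect_equal(fisher_one_sided(t), ft$p.value, tolerance = 1e-12)
    }
  })
})

test_that("enrichment reports are consistent between truth and perfect predictions", {
  st <- small_study()
  rs <- build_peak_sets(st$peaks, st$genome, seed = 4)
  v <- rbind(st$pos_records, st$cand_records)[, c("chrom", "pos", "ref", "alt")]
  y <- c(rep(1L, nrow(st$pos_records)), rep(0L, nrow(st$cand_records)))
  rep1 <- enrich_report(v, y, ifelse(y == 1, 0.9, 0.1), rs)
  expect_identical(rep1$n11[1], rep1$n11[2])
  expect_identical(rep1$odds_ratio[1], rep1$odds_ratio[2])
  # all scores exactly at the threshold: zero predicted positives (strict >)
  rep2 <- enrich_report(v, y, rep(0.5, length(y)), rs)
  expect_equal(rep2$n11[rep2$label_source == "predicted"], 0L, ignore_attr = TRUE)
  # conservation: row sums count variants overlapping either region class
  sp <- variant_span(v[y == 1, ])
  either <- sum(overlaps_any(sp, rs$positive)) + sum(overlaps_any(sp, rs$negative))
  expect_equal(rep1$n11[1] + rep1$n12[1], either, ignore_attr = TRUE)
})
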