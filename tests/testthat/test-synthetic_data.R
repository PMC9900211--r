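test_that("simulated genomes hit the GC target and are seed-reproducible", {
  cfg <- sim_config(genome_length = 1e5, n_contigs = 1, gc_target = 0.5,
                    seed = 31)
  g <- simulate_genome(cfg)
  expect_true(abs(gc_content(g[["chr1"]]) - 0.5) < 0.02)
  g2 <- simulate_genome(cfg)
  expect_identical(unclass(g), unclass(g2))
  # GC limit: an all-A/T genome
  g0 <- simulate_genome(sim_config(genome_length = 2e4, n_contigs = 1,
                                   gc_target = 0, seed = 1))
  expect_equal(gc_content(g0[["chr1"]]), 0)
})

test_that("the generator audit holds: files re-read reproduce the truth", {
  out <- withr::local_tempdir()
  st <- simulate_study(small_sim_config(seed = 12), out_dir = out)
  # FASTA round trip
  expect_identical(unclass(load_fasta(st$files$genome)), unclass(st$genome))
  # eQTL round trips preserve records exactly at numeric precision
  pos <- read_eqtl(st$files$pos_eqtl)
  expect_identical(variant_key(pos), variant_key(st$pos_records))
  expect_equal(pos$maf, st$pos_records$maf, tolerance = 1e-12)
  cand <- read_eqtl(st$files$cand_eqtl)
  expect_identical(variant_key(cand), variant_key(st$cand_records))
  # annotation matrix round trip (keys and missingness pattern)
  ann <- read_annotations(st$files$annotations)
  expect_identical(rownames(ann), rownames(st$annotations))
  expect_identical(is.na(ann), is.na(st$annotations))
  # labels in the truth match the emitted files
  expect_identical(st$truth$labels$variant_key,
                   c(variant_key(st$pos_records), variant_key(st$cand_records)))
  # determinism of the whole study
  st2 <- simulate_study(small_sim_config(seed = 12))
  expect_identical(st2$truth$labels, st$truth$labels)
  expect_identical(unclass(st2$genome), unclass(st$genome))
})

test_that("planted positives are recovered exactly by the positive selector", {
  st <- small_study()
  sel <- select_positives(st$pos_records)
  expect_setequal(variant_key(sel), variant_key(st$pos_records))
  # and all candidates qualify as negative candidates (same-law MAF, q > 0.2)
  cand <- select_negative_candidates(st$cand_records, sel)
  expect_identical(nrow(cand), nrow(st$cand_records))
})

test_that("variant placement respects genome content and window margins", {
  st <- small_study()
  g <- st$genome
  all_rec <- rbind(st$pos_records, st$cand_records)
  # reference alleles agree with the (motif-planted) genome
  for (i in sample(nrow(all_rec), 25)) {
    expect_identical(
      fetch_range(g, all_rec$chrom[i], all_rec$pos[i],
                  all_rec$pos[i] + nchar(all_rec$ref[i])),
      all_rec$ref[i])
  }
  # MAF truncation and q-value laws
  expect_true(all(all_rec$maf > 0 & all_rec$maf <= 0.5))
  expect_true(all(st$pos_records$q_value < 0.05))
  expect_true(all(st$cand_records$q_value > 0.2))
  expect_true(all(all_rec$tss_distance < 1e5))
  # indel sizes within 1..10
  expect_true(all(indel_length(all_rec) >= 1 & indel_length(all_rec) <= 10))
  # spans are mutually disjoint
  sp <- variant_span(all_rec)
  expect_false(any(vapply(seq_len(nrow(sp)), function(i) {
    any(overlaps(sp[i, ], sp[-i, ]))
  }, logical(1))))
})

test_that("region membership of planted variants implies the configured OR", {
  st <- small_study()
  tr <- st$truth$labels
  # realized membership equals the planted flag
  sp <- variant_span(rbind(st$pos_records, st$cand_records))
  realized <- overlaps_any(sp, st$truth$regions)
  expect_identical(realized, tr$in_region)
  ct <- table(factor(tr$label, c(1, 0)), factor(tr$in_region, c(TRUE, FALSE)))
  or_hat <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  expect_gt(or_hat, 1)   # direction; the calibrated band is checked at scale
})

test_that("the designated high-missingness annotation column is dropped", {
  st <- small_study()
  expect_gt(mean(is.na(st$annotations[, "annot45"])), 0.10)
  kept <- filter_and_impute(st$annotations)
  expect_false("annot45" %in% colnames(kept))
  expect_true(all(c("annot41", "annot42", "annot43") %in% colnames(kept)))
})

test_that("informative annotation columns carry the planted mean shift", {
  st <- small_study()
  lab <- st$truth$labels$label
  info <- st$truth$informative
  shifts <- colMeans(st$annotations[lab == 1, info, drop = FALSE], na.rm = TRUE) -
    colMeans(st$annotations[lab == 0, info, drop = FALSE], na.rm = TRUE)
  expect_true(all(shifts > 0.5))   # planted at 1.0 SD
  other <- setdiff(colnames(st$annotations), info)
  null_shifts <- colMeans(st$annotations[lab == 1, other, drop = FALSE], na.rm = TRUE) -
    colMeans(st$annotations[lab == 0, other, drop = FALSE], na.rm = TRUE)
  expect_true(all(abs(null_shifts) < 0.5))
})

test_that("motif disruption makes profile differences label-informative", {
  st <- small_study()
  ls <- build_labeled_set("T", st$pos_records, st$cand_records, seed = 3)
  p <- study_predictor(st)
  v <- rbind(ls$positives[, c("chrom", "pos", "ref", "alt")],
             ls$negatives[, c("chrom", "pos", "ref", "alt")])
  y <- c(rep(1, nrow(ls$positives)), rep(0, nrow(ls$negatives)))
  w <- build_windows(st$genome, v, L = 1000)
  pr <- predict_window_profiles(w, p)
  d <- rowMeans(abs(pr$ref - pr$alt))
  expect_gt(mean(d[y == 1]), 1.5 * mean(d[y == 0]))
})

test_that("with zero planted effects the profile difference carries no signal", {
  cfg <- small_sim_config(seed = 41, profile_effect = 0, annot_effect = 0)
  st <- simulate_study(cfg)
  p <- study_predictor(st)
  v <- rbind(st$pos_records[1:40, ], st$cand_records[1:40, ])
  y <- rep(c(1, 0), each = 40)
  w <- build_windows(st$genome, v[, c("chrom", "pos", "ref", "alt")], L = 1000)
  pr <- predict_window_profiles(w, p)
  d <- rowMeans(abs(pr$ref - pr$alt))
  expect_gt(stats::t.test(d[y == 1], d[y == 0])$p.value, 0.01)
})

test_that("the mismatched-MAF mode triggers the deficient-bin error", {
  st <- simulate_study(small_sim_config(seed = 51, maf_mismatch = TRUE))
  pos <- select_positives(st$pos_records)
  cand <- select_negative_candidates(st$cand_records, pos)
  expect_error(match_maf(cand, pos, 0.05, 1), "deficient MAF bin")
})

test_that("emitted peaks reproduce the planted significant regions", {
  st <- small_study()
  sig <- st$peaks[st$peaks$fdr < 0.05, ]
  expect_identical(nrow(sig), nrow(st$truth$regions))
  rs <- build_peak_sets(st$peaks, st$genome, seed = 1)
  expect_identical(nrow(rs$positive), nrow(st$truth$regions))
})
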