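#' Configuration for a synthetic regulatory-indel study
#'
#' Bundles every knob of the synthetic-data generator. The defaults are
#' the package's reference study conditions: a 3-Mb two-contig genome at
#' human-like GC, 1000 positive and 4000 candidate-negative nc-sindels,
#' 10 informative annotation columns at a 1-SD mean shift, a strong
#' planted motif-disruption signal, and a planted region odds ratio of
#' 3.
#'
#' @param genome_length Total genome length in bp (split evenly across
#'   contigs).
#' @param n_contigs Number of contigs.
#' @param gc_target Genome-wide GC fraction in `(0, 1)` (boundary values
#'   give pure A/T or G/C genomes).
#' @param n_pos Number of planted positive nc-sindels.
#' @param n_neg_candidates Number of negative-candidate nc-sindels.
#' @param annot_effect Mean shift (in SD units) of informative
#'   annotation columns for positives.
#' @param n_informative_annots Number of informative columns among the
#'   45 generic annotations.
#' @param profile_effect Weight boost of the planted motif's k-mers in
#'   the synthetic predictor; 0 disables the sequence-level signal.
#' @param maf_law Beta-distribution shape parameters for MAF draws
#'   (truncated to `(0, 0.5]`).
#' @param region_or Target odds ratio of positive-vs-negative variant
#'   placement inside planted regulatory regions.
#' @param p0_region Baseline probability that a negative variant falls
#'   inside a planted region.
#' @param n_regions,region_width Number and width (bp) of planted
#'   regulatory regions.
#' @param n_tracks,kmer_k,L Synthetic-predictor configuration: output
#'   tracks, k-mer size, and sequence-window length.
#' @param n_nonsig_peaks Extra non-significant peaks emitted alongside
#'   the planted ones.
#' @param n_int_sig,n_int_cand Significant / negative-candidate
#'   interactions per interaction type (PE, PP).
#' @param n_int_interchrom,n_int_far Filter-exercising interactions:
#'   inter-chromosomal pairs and intra-chromosomal pairs beyond the 1-Mb
#'   distance cutoff.
#' @param maf_mismatch If `TRUE`, candidate MAFs are drawn from a
#'   deliberately mismatched law so that MAF matching fails with a
#'   deficient-bin error (for testing that error path).
#' @param seed Integer seed; the whole generator is deterministic given
#'   the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 3e6, n_contigs = 2L, gc_target = 0.41,
                       n_pos = 1000L, n_neg_candidates = 4000L,
                       annot_effect = 1.0, n_informative_annots = 10L,
                       profile_effect = 4, maf_law = c(2, 5),
                       region_or = 3, p0_region = 0.15,
                       n_regions = 500L, region_width = 1000L,
                       n_tracks = 919L, kmer_k = 6L, L = 1000L,
                       n_nonsig_peaks = 300L,
                       n_int_sig = 150L, n_int_cand = 600L,
                       n_int_interchrom = 60L, n_int_far = 60L,
                       maf_mismatch = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_target >= 0, cfg$gc_target <= 1, cfg$region_or >= 1,
            cfg$n_pos >= 0, cfg$n_neg_candidates >= 0,
            cfg$genome_length >= 10 * cfg$L,
            cfg$n_informative_annots <= 40L)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc_target`, split evenly into
#' `n_contigs` contigs named `chr1, chr2, ...`. Deterministic under the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `genome_seq`.
#' @export
simulate_genome <- function(cfg) {
  clen <- floor(cfg$genome_length / cfg$n_contigs)
  probs <- c(A = (1 - cfg$gc_target) / 2, C = cfg$gc_target / 2,
             G = cfg$gc_target / 2, T = (1 - cfg$gc_target) / 2)
  contigs <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_contigs), function(i) {
      paste(sample(names(probs), clen, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
  names(contigs) <- paste0("chr", seq_len(cfg$n_contigs))
  genome_seq(contigs)
}

# non-overlapping planted regulatory intervals on a margin-respecting grid
plant_regions <- function(cfg, genome, seed) {
  lens <- contig_lengths(genome)
  margin <- cfg$L / 2 + 20
  slot <- cfg$region_width + 1500
  grid <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(margin, lens[[ch]] - margin - cfg$region_width, by = slot)
    data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
  }))
  if (nrow(grid) < cfg$n_regions) {
    stop("genome too short for ", cfg$n_regions, " planted regions")
  }
  pick <- withr::with_seed(seed, sort(sample.int(nrow(grid), cfg$n_regions)))
  out <- grid[pick, , drop = FALSE]
  out$end <- out$start + cfg$region_width
  rownames(out) <- NULL
  out
}

#' Write tandem motif copies into a genome
#'
#' The sequence-level signal planting step: at each site, `copies`
#' back-to-back copies of `motif` are written into the genome. Placing a
#' tile across a variant's edit point makes that variant's alternative
#' window disrupt motif k-mers; combined with a motif-boosted synthetic
#' predictor this makes `|ref - alt|` profile differences
#' label-informative.
#'
#' @param genome A `genome_seq`.
#' @param sites Data frame with columns `chrom`, `start` (tile start,
#'   0-based).
#' @param motif Nucleotide string.
#' @param copies Number of tandem copies per tile.
#' @return The modified `genome_seq`.
#' @export
plant_profile_signal <- function(genome, sites, motif, copies = 3L) {
  tile <- strsplit(paste(rep(motif, copies), collapse = ""), "")[[1]]
  chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (ch in unique(sites$chrom)) {
    v <- chars[[ch]]
    if (is.null(v)) stop("unknown contig: ", ch)
    for (s in sites$start[sites$chrom == ch]) {
      if (s < 0 || s + length(tile) > length(v)) {
        stop("motif tile out of bounds on ", ch)
      }
      v[(s + 1):(s + length(tile))] <- tile
    }
    chars[[ch]] <- v
  }
  genome_seq(vapply(chars, paste, character(1), collapse = ""))
}

rbeta_trunc <- function(n, shape, seed_env_active = TRUE) {
  x <- rbeta(n, shape[1], shape[2])
  while (any(bad <- x <= 0 | x > 0.5)) {
    x[bad] <- rbeta(sum(bad), shape[1], shape[2])
  }
  x
}

#' Simulate an eQTL study with planted signal
#'
#' Places `n_pos` positive and `n_neg_candidates` candidate-negative
#' small indels (length difference 1-10 bp) on the genome, with:
#' * q-values `U(0, 0.05)` for positives and `U(0.2, 1)` for candidates;
#' * TSS distances `U(0, 100kb)`; MAF from the truncated Beta law
#'   (shared by both classes so MAF matching succeeds);
#' * genes drawn so candidates share the positive gene pool;
#' * region membership: positives fall inside planted regulatory
#'   regions at the rate implied by `region_or` over the baseline
#'   `p0_region`;
#' * sequence signal: a motif tile is written near every variant —
#'   across the edit point for positives (so the allele edit disrupts
#'   motif k-mers) and safely downstream for candidates (motif present,
#'   not disrupted).
#'
#' All variant reference spans are mutually disjoint (>= 200 bp apart).
#'
#' @param cfg A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param regions Optional planted-region intervals (generated from the
#'   config when omitted).
#' @return List with `pos_records`, `cand_records` (eQTL record data
#'   frames), the motif-modified `genome`, and a `truth` list (labels,
#'   region memberships, motif, planted regions, MAF histogram).
#' @export
simulate_eqtl_study <- function(cfg, genome, regions = NULL) {
  if (is.null(regions)) regions <- plant_regions(cfg, genome, cfg$seed + 1L)
  lens <- contig_lengths(genome)
  margin <- cfg$L / 2 + 20
  n_total <- cfg$n_pos + cfg$n_neg_candidates
  label <- rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg_candidates))

  o0 <- cfg$p0_region / (1 - cfg$p0_region)
  o1 <- cfg$region_or * o0
  p1 <- o1 / (1 + o1)

  bucket <- 200L
  occ <- lapply(lens, function(l) logical(ceiling(l / bucket) + 2L))
  reg_by_chrom <- split(regions, regions$chrom)

  in_any_region <- function(ch, lo, hi) {
    r <- reg_by_chrom[[ch]]
    if (is.null(r)) return(FALSE)
    any(r$start < hi & lo < r$end)
  }

  withr::with_seed(cfg$seed + 2L, {
    chrom <- character(n_total); pos <- numeric(n_total)
    in_region <- logical(n_total)
    for (i in seq_len(n_total)) {
      p_in <- if (label[i] == 1L) p1 else cfg$p0_region
      want_in <- runif(1) < p_in
      placed <- FALSE
      for (try in 1:300) {
        if (want_in) {
          r <- regions[sample.int(nrow(regions), 1L), ]
          ch <- r$chrom
          p <- r$start + sample.int(r$end - r$start - 85L, 1L) + 24L
        } else {
          ch <- names(lens)[sample.int(length(lens), 1L, prob = lens)]
          p <- margin + sample.int(lens[[ch]] - 2 * margin, 1L) - 1L
          if (in_any_region(ch, p - 1, p + 13)) next
        }
        b <- floor((p - 120):(p + 120) / bucket) + 1L
        b <- unique(b[b >= 1L])
        if (any(occ[[ch]][b])) next
        occ[[ch]][b] <- TRUE
        chrom[i] <- ch; pos[i] <- p; in_region[i] <- want_in
        placed <- TRUE
        break
      }
      if (!placed) stop("genome too short to place all requested variants")
    }

    # motif + tiles: across the edit point for positives, downstream
    # otherwise. With profile_effect == 0 nothing is planted at all:
    # even unboosted, disrupting a tandem repeat is distinguishable from
    # disrupting background sequence, so a clean null needs no tiles.
    motif <- paste(sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
                   collapse = "")
    if (cfg$profile_effect > 0) {
      tile_start <- ifelse(label == 1L, pos - 15, pos + 80)
      genome <- plant_profile_signal(
        genome, data.frame(chrom = chrom, start = tile_start), motif)
    }

    # alleles read from the finalized genome
    is_del <- runif(n_total) < 0.5
    d <- sample.int(10L, n_total, replace = TRUE)
    ref <- alt <- character(n_total)
    for (i in seq_len(n_total)) {
      if (is_del[i]) {
        ref[i] <- fetch_range(genome, chrom[i], pos[i], pos[i] + d[i] + 1L)
        alt[i] <- substr(ref[i], 1L, 1L)
      } else {
        ref[i] <- fetch_range(genome, chrom[i], pos[i], pos[i] + 1L)
        alt[i] <- paste0(ref[i], paste(sample(c("A", "C", "G", "T"), d[i],
                                              replace = TRUE), collapse = ""))
      }
    }

    genes <- sprintf("g%03d", sample.int(300L, n_total, replace = TRUE))
    pos_genes <- unique(genes[label == 1L])
    genes[label == 0L] <- sample(pos_genes, cfg$n_neg_candidates, replace = TRUE)

    maf <- rbeta_trunc(n_total, cfg$maf_law)
    if (cfg$maf_mismatch) {
      maf[label == 0L] <- runif(cfg$n_neg_candidates, 1e-4, 0.15)
    }
    q <- ifelse(label == 1L, runif(n_total, 0, 0.05), runif(n_total, 0.2, 1))
    tss <- floor(runif(n_total, 0, 1e5))
  })

  rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = genes, tss_distance = tss, q_value = q, maf = maf,
                    stringsAsFactors = FALSE)
  keys <- variant_key(rec)
  truth <- list(
    labels = data.frame(variant_key = keys, label = label,
                        in_region = in_region, maf = maf,
                        stringsAsFactors = FALSE),
    regions = regions, motif = motif,
    maf_hist_pos = table(floor(maf[label == 1L] / 0.05)),
    predictor = list(n_tracks = cfg$n_tracks, k = cfg$kmer_k, L = cfg$L,
                     motif = motif, motif_boost = cfg$profile_effect))
  list(pos_records = rec[label == 1L, , drop = FALSE],
       cand_records = rec[label == 0L, , drop = FALSE],
       genome = genome, truth = truth)
}

#' Simulate the generic-annotation matrix
#'
#' Emits 45 annotation columns for the given variants. The first
#' `n_informative_annots` columns are drawn `N(annot_effect, 1)` for
#' positives and `N(0, 1)` otherwise; the rest are `N(0, 1)` for all.
#' To exercise the missingness filter, three designated columns
#' (`annot41`-`annot43`) get 2% missing entries and one (`annot45`)
#' gets 12%, so exactly that one is dropped at the 10% threshold.
#'
#' @param cfg A [sim_config()].
#' @param labels Data frame with `variant_key` and `label` columns
#'   (`truth$labels` of [simulate_eqtl_study()]).
#' @return List with the annotation `matrix` (keys as rownames) and
#'   `truth` (informative and missingness-designated column names).
#' @export
simulate_annotations <- function(cfg, labels) {
  n <- nrow(labels)
  cols <- sprintf("annot%02d", 1:45)
  info <- cols[seq_len(cfg$n_informative_annots)]
  m <- withr::with_seed(cfg$seed + 3L, {
    m <- matrix(rnorm(n * 45L), n, 45L, dimnames = list(labels$variant_key, cols))
    m[, info] <- m[, info] + cfg$annot_effect * labels$label
    for (cc in c("annot41", "annot42", "annot43")) {
      m[sample.int(n, max(1L, round(0.02 * n))), cc] <- NA
    }
    m[sample.int(n, round(0.12 * n)), "annot45"] <- NA
    m
  })
  list(matrix = m,
       truth = list(informative = info,
                    low_missing = c("annot41", "annot42", "annot43"),
                    high_missing = "annot45"))
}

#' Simulate peak and interaction region files
#'
#' Peaks: the planted regulatory regions are emitted as significant
#' peaks (FDR < 0.05) plus `n_nonsig_peaks` random non-significant ones
#' of varying width. Interactions (per type PE/PP): significant pairs
#' (FDR < 0.1) anchor on planted regions of the same contig within 1 Mb;
#' negative candidates (FDR > 0.5) anchor on random loci; plus
#' filter-exercising inter-chromosomal and over-distance rows carrying
#' significant FDRs that the distance/intra-chromosomal filters must
#' remove.
#'
#' @param cfg A [sim_config()].
#' @param genome A `genome_seq`.
#' @param truth Truth list from [simulate_eqtl_study()] (for the planted
#'   regions).
#' @return List with data frames `peaks` and `interactions`.
#' @export
simulate_regions <- function(cfg, genome, truth) {
  lens <- contig_lengths(genome)
  regions <- truth$regions
  withr::with_seed(cfg$seed + 4L, {
    peaks <- rbind(
      data.frame(chrom = regions$chrom, start = regions$start,
                 end = regions$end,
                 fdr = runif(nrow(regions), 0, 0.045),
                 stringsAsFactors = FALSE),
      {
        ch <- names(lens)[sample.int(length(lens), cfg$n_nonsig_peaks,
                                     replace = TRUE, prob = lens)]
        w <- sample(200:800, cfg$n_nonsig_peaks, replace = TRUE)
        st <- vapply(seq_len(cfg$n_nonsig_peaks), function(i) {
          600 + sample.int(lens[[ch[i]]] - w[i] - 1200L, 1L)
        }, numeric(1))
        data.frame(chrom = ch, start = st, end = st + w,
                   fdr = runif(cfg$n_nonsig_peaks, 0.06, 1),
                   stringsAsFactors = FALSE)
      })

    mid <- floor((regions$start + regions$end) / 2)
    sig_pair <- function(n) {
      out <- matrix(NA_integer_, n, 2L)
      for (i in seq_len(n)) {
        repeat {
          a <- sample.int(nrow(regions), 2L)
          if (regions$chrom[a[1]] == regions$chrom[a[2]] &&
              abs(mid[a[1]] - mid[a[2]]) <= 1e6 && a[1] != a[2]) break
        }
        out[i, ] <- a
      }
      out
    }
    rand_anchor_pair <- function(n, dmin = 2e4, dmax = 9e5) {
      dmax <- min(dmax, min(lens) - 6000)
      if (dmin >= dmax) dmin <- floor(dmax / 2)
      if (n == 0L || dmax <= dmin) {
        return(data.frame(chrom1 = character(0), start1 = numeric(0),
                          end1 = numeric(0), chrom2 = character(0),
                          start2 = numeric(0), end2 = numeric(0),
                          stringsAsFactors = FALSE))
      }
      ch <- names(lens)[sample.int(length(lens), n, replace = TRUE, prob = lens)]
      d <- floor(runif(n, dmin, dmax))
      m1 <- vapply(seq_len(n), function(i) {
        1100 + sample.int(lens[[ch[i]]] - d[i] - 2400L, 1L)
      }, numeric(1))
      data.frame(chrom1 = ch, start1 = m1 - 500, end1 = m1 + 500,
                 chrom2 = ch, start2 = m1 + d - 500, end2 = m1 + d + 500,
                 stringsAsFactors = FALSE)
    }
    one_type <- function(ty) {
      sp <- sig_pair(cfg$n_int_sig)
      sig <- data.frame(chrom1 = regions$chrom[sp[, 1]],
                        start1 = regions$start[sp[, 1]],
                        end1 = regions$end[sp[, 1]],
                        chrom2 = regions$chrom[sp[, 2]],
                        start2 = regions$start[sp[, 2]],
                        end2 = regions$end[sp[, 2]],
                        stringsAsFactors = FALSE)
      sig$fdr <- runif(cfg$n_int_sig, 0, 0.09)
      cand <- rand_anchor_pair(cfg$n_int_cand)
      cand$fdr <- runif(cfg$n_int_cand, 0.51, 1)
      n_ic <- if (length(lens) > 1L) ceiling(cfg$n_int_interchrom / 2) else 0L
      junk_ic <- rand_anchor_pair(n_ic)
      if (n_ic > 0L) {
        junk_ic$chrom2 <- vapply(junk_ic$chrom1, function(c1) {
          sample(setdiff(names(lens), c1), 1L)
        }, character(1))
      }
      junk_ic$fdr <- runif(nrow(junk_ic), 0, 0.09)
      n_far <- if (min(lens) > 1.2e6 + 6000) ceiling(cfg$n_int_far / 2) else 0L
      junk_far <- rand_anchor_pair(n_far, dmin = 1.1e6,
                                   dmax = min(1.4e6, min(lens) - 6000))
      junk_far$fdr <- runif(nrow(junk_far), 0, 0.09)
      out <- rbind(sig, cand, junk_ic, junk_far)
      out$itype <- ty
      out
    }
    interactions <- rbind(one_type("PE"), one_type("PP"))
  })
  list(peaks = peaks, interactions = interactions)
}

#' Run the full synthetic-study generator
#'
#' Orchestrates [simulate_genome()], region planting,
#' [simulate_eqtl_study()], [simulate_annotations()] and
#' [simulate_regions()], optionally writing every pipeline input file
#' (FASTA genome, positive/candidate eQTL TSVs, annotation TSV, peaks
#' TSV, interactions TSV, truth JSON) to a directory.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `genome`, `pos_records`, `cand_records`,
#'   `annotations` (matrix), `peaks`, `interactions`, `truth`, and
#'   `files` (paths, when `out_dir` is given).
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(cfg)
  eq <- simulate_eqtl_study(cfg, genome)
  ann <- simulate_annotations(cfg, eq$truth$labels)
  reg <- simulate_regions(cfg, eq$genome, eq$truth)
  truth <- c(eq$truth, ann$truth)
  res <- list(genome = eq$genome, pos_records = eq$pos_records,
              cand_records = eq$cand_records, annotations = ann$matrix,
              peaks = reg$peaks, interactions = reg$interactions,
              truth = truth, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genome = file.path(out_dir, "genome.fa"),
      pos_eqtl = file.path(out_dir, "eqtl_positive_source.tsv"),
      cand_eqtl = file.path(out_dir, "eqtl_negative_source.tsv"),
      annotations = file.path(out_dir, "annotations.tsv"),
      peaks = file.path(out_dir, "peaks.tsv"),
      interactions = file.path(out_dir, "interactions.tsv"),
      truth = file.path(out_dir, "truth.json"))
    write_fasta(res$genome, files$genome)
    write_eqtl(res$pos_records, files$pos_eqtl)
    write_eqtl(res$cand_records, files$cand_eqtl)
    write_annotations(res$annotations, files$annotations)
    write.table(res$peaks, files$peaks, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(res$interactions, files$interactions, sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(motif = truth$motif, informative = truth$informative,
           labels = truth$labels, regions = truth$regions,
           predictor = truth$predictor),
      files$truth, auto_unbox = TRUE, digits = NA)
    res$files <- files
  }
  res
}

#' Predictor matching a simulated study's planted signal
#'
#' Convenience constructor: builds the synthetic profile predictor whose
#' motif-boosted weights correspond to the study's planted motif.
#'
#' @param study Output of [simulate_study()] (or a truth list).
#' @return A `profile_predictor`.
#' @export
study_predictor <- function(study) {
  pr <- if (!is.null(study$truth)) study$truth$predictor else study$predictor
  make_synthetic_predictor(n_tracks = pr$n_tracks, k = pr$k,
                           seed = study$config$seed %||% 1L,
                           L = pr$L, motif = pr$motif,
                           motif_boost = pr$motif_boost)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
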