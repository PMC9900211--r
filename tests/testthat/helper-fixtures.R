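# Shared fixtures, built in code. The small study is memoized per test run.

toy_genome <- function(seqs = c(c1 = "ACGTACGTACGTACGT")) {
  genome_seq(seqs)
}

# eQTL record rows built by hand
eqtl_row <- function(chrom = "c1", pos = 100, ref = "AC", alt = "A",
                     gene = "g1", tss = 50000, q = 0.01, maf = 0.2) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             tss_distance = tss, q_value = q, maf = maf,
             stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 11, ...) {
  sim_config(genome_length = 4e5, n_contigs = 2L, n_pos = 60L,
             n_neg_candidates = 300L, n_regions = 40L, n_tracks = 12L,
             kmer_k = 6L, L = 1000L, n_int_sig = 20L, n_int_cand = 60L,
             n_int_interchrom = 6L, n_int_far = 6L, n_nonsig_peaks = 30L,
             seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# memoized small study shared across test files
small_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(small_sim_config())
  }
  .fixture_env$study
}

# random nucleotide string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
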