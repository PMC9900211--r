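#' Create a deterministic synthetic epigenomic-profile predictor
#'
#' A desk-scale stand-in for a trained multi-task sequence model (e.g. a
#' DanQ-style network predicting 919 chromatin tracks). Track `t`'s score
#' for a sequence is a logistic transform of a seeded-random-weighted sum
#' of the sequence's k-mer counts, so outputs are deterministic given
#' `(n_tracks, k, seed)`, lie in `[0, 1]`, and respond to single-base
#' changes. Optionally, all k-mers contained in a `motif` have their
#' weights scaled by `1 + motif_boost`, making motif-disrupting edits
#' disproportionately visible in the predicted profiles; this is the hook
#' the synthetic-data generator uses to plant sequence-level signal.
#'
#' @param n_tracks Number of output tracks (default 919, the reference
#'   configuration: 690 TF-binding + 125 DNase + 104 histone tracks).
#' @param k k-mer size (1..8).
#' @param seed Integer seed for the weight draw.
#' @param L Expected input sequence length in bp.
#' @param motif Optional nucleotide string whose constituent k-mers get
#'   boosted weights.
#' @param motif_boost Multiplier increment for motif k-mer weights.
#' @return A `profile_predictor` object with fields `n_tracks`, `k`,
#'   `seed`, `L`, `name` and a `predict(onehot)` function mapping a
#'   one-hot encoded length-`L` sequence to `n_tracks` values in
#'   `[0, 1]`.
#' @export
make_synthetic_predictor <- function(n_tracks = 919L, k = 6L, seed = 1L,
                                     L = 1000L, motif = NULL,
                                     motif_boost = 0) {
  stopifnot(n_tracks >= 1L, k >= 1L, k <= 8L, L >= k)
  n_kmers <- 4L^k
  W <- withr::with_seed(seed, matrix(rnorm(n_kmers * n_tracks), nrow = n_kmers))
  if (!is.null(motif) && motif_boost != 0) {
    stopifnot(nchar(motif) >= k)
    idx <- unique(kmer_codes(motif, k)) + 1L
    idx <- idx[!is.na(idx)]
    W[idx, ] <- W[idx, ] * (1 + motif_boost)
  }
  colnames(W) <- sprintf("t%03d", seq_len(n_tracks))
  obj <- list(name = sprintf("synthetic-kmer(k=%d,seed=%d)", k, seed),
              n_tracks = as.integer(n_tracks), k = as.integer(k),
              seed = as.integer(seed), L = as.integer(L),
              motif = motif, motif_boost = motif_boost, W = W)
  obj$predict <- function(onehot) {
    stopifnot(is.matrix(onehot), ncol(onehot) == 4L)
    seq <- decode_one_hot(onehot)
    codes <- kmer_codes(seq, obj$k)
    codes <- codes[!is.na(codes)]
    if (length(codes) == 0L) {
      return(setNames(rep(0.5, obj$n_tracks), colnames(obj$W)))
    }
    tab <- tabulate(codes + 1L, nbins = nrow(obj$W))
    nz <- which(tab > 0L)
    z <- as.numeric(crossprod(obj$W[nz, , drop = FALSE], tab[nz]))
    plogis(z / sqrt(length(codes)))
  }
  structure(obj, class = "profile_predictor")
}

#' @export
print.profile_predictor <- function(x, ...) {
  cat("<profile_predictor> ", x$name, ", ", x$n_tracks, " tracks, L=", x$L,
      "\n", sep = "")
  invisible(x)
}

# bases from a one-hot matrix; all-zero rows decode to N
decode_one_hot <- function(onehot) {
  hit <- max.col(onehot, ties.method = "first")
  hit[rowSums(onehot) == 0] <- 5L
  paste(c("A", "G", "C", "T", "N")[hit], collapse = "")
}

# base-4 integer codes of all k-mers of seq; windows containing N are NA
kmer_codes <- function(seq, k) {
  d <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(d)
  if (n < k) return(integer(0))
  if (k == 1L) return(d)
  m <- stats::embed(d, k)                  # row i = digits (i+k-1, ..., i)
  as.integer(m %*% 4L^(seq_len(k) - 1L))   # NA propagates through N windows
}

#' Predict epigenomic profiles for a sequence
#'
#' One-hot encodes `seq` and applies the predictor's contract; output is
#' a named vector of `n_tracks` values in `[0, 1]`, deterministic for a
#' given predictor and sequence.
#'
#' @param p A `profile_predictor`.
#' @param seq Nucleotide string of length `p$L`.
#' @return Numeric vector of length `p$n_tracks`.
#' @export
predict_profiles <- function(p, seq) {
  stopifnot(inherits(p, "profile_predictor"))
  if (nchar(seq) != p$L) {
    stop("sequence length ", nchar(seq), " != predictor window length ", p$L)
  }
  p$predict(one_hot(seq))
}
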