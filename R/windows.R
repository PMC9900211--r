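#' Extract the fixed-length reference window of a variant
#'
#' Returns the `L`-bp reference sequence centered on the variant: the
#' window `[pos - L/2, pos - L/2 + L)`, so the variant's first reference
#' base sits at 0-based index `L/2` of the returned string.
#'
#' @param genome A `genome_seq`.
#' @param v A single-row variant data frame.
#' @param L Window length in bp (even; default 1000).
#' @return A nucleotide string of length `L`.
#' @export
extract_ref_window <- function(genome, v, L = 1000L) {
  stopifnot(L %% 2 == 0, nrow(v) == 1L)
  start <- v$pos - L / 2
  fetch_range(genome, v$chrom, start, start + L)
}

#' Build the length-matched alternative window of a variant
#'
#' Applies the allele edit at the window anchor and restores length `L`:
#' upstream reference `[pos - L/2, pos)`, then the alternative allele,
#' then downstream reference starting at `pos + len(ref)`, truncated to
#' exactly `L`. For a deletion this pulls additional downstream bases in
#' (the downstream sequence shifts upstream); for an insertion the tail
#' is trimmed (downstream shift). The upstream `L/2` bases always equal
#' the reference window's.
#'
#' @inheritParams extract_ref_window
#' @return A nucleotide string of length `L`.
#' @export
build_alt_window <- function(genome, v, L = 1000L) {
  stopifnot(L %% 2 == 0, nrow(v) == 1L)
  up_start <- v$pos - L / 2
  if (up_start < 0) stop("window out of contig bounds (upstream)")
  upstream <- fetch_range(genome, v$chrom, up_start, v$pos)
  alt <- v$alt
  need <- L - nchar(upstream) - nchar(alt)
  down <- ""
  if (need > 0) {
    dstart <- v$pos + nchar(v$ref)
    clen <- contig_lengths(genome)[[v$chrom]]
    if (dstart + need > clen) {
      stop("insufficient downstream sequence for alternative window")
    }
    down <- fetch_range(genome, v$chrom, dstart, dstart + need)
  }
  substr(paste0(upstream, alt, down), 1L, L)
}

#' Build reference/alternative sequence windows for a variant table
#'
#' Variants whose window falls outside their contig (or whose reference
#' allele disagrees with the genome) are skipped with a warning, matching
#' how boundary variants are handled upstream of featurization.
#'
#' @param genome A `genome_seq`.
#' @param v Variant data frame.
#' @param L Window length in bp (even).
#' @return Data frame with columns `variant_key`, `ref_seq`, `alt_seq`
#'   and attribute `L`.
#' @export
build_windows <- function(genome, v, L = 1000L) {
  keys <- variant_key(v)
  ref_seq <- alt_seq <- character(nrow(v))
  ok <- logical(nrow(v))
  msgs <- character(0)
  for (i in seq_len(nrow(v))) {
    row <- v[i, , drop = FALSE]
    res <- tryCatch({
      rs <- extract_ref_window(genome, row, L)
      anchored <- substr(rs, L / 2 + 1L, L / 2 + nchar(row$ref))
      if (anchored != row$ref) {
        stop("reference allele mismatch at ", keys[i],
             " (genome has ", anchored, ")")
      }
      list(ref = rs, alt = build_alt_window(genome, row, L))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msgs <- c(msgs, conditionMessage(res))
    } else {
      ref_seq[i] <- res$ref
      alt_seq[i] <- res$alt
      ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) skipped during window construction: ",
            paste(utils::head(msgs, 3), collapse = "; "),
            if (length(msgs) > 3) " ...")
  }
  out <- data.frame(variant_key = keys[ok], ref_seq = ref_seq[ok],
                    alt_seq = alt_seq[ok], stringsAsFactors = FALSE)
  attr(out, "L") <- L
  out
}

#' One-hot encode a nucleotide sequence
#'
#' Channel order is (A, G, C, T): `A -> (1,0,0,0)`, `G -> (0,1,0,0)`,
#' `C -> (0,0,1,0)`, `T -> (0,0,0,1)`. An `N` yields an all-zero row.
#'
#' @param seq A nucleotide string over `{A,C,G,T,N}`.
#' @return Numeric matrix of shape `nchar(seq) x 4`.
#' @export
one_hot <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  lut <- rbind(A = c(1, 0, 0, 0), G = c(0, 1, 0, 0),
               C = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
               N = c(0, 0, 0, 0))
  bad <- !(bases %in% rownames(lut))
  if (any(bad)) stop("illegal character(s) in sequence: ",
                     paste(unique(bases[bad]), collapse = ", "))
  m <- lut[bases, , drop = FALSE]
  dimnames(m) <- list(NULL, c("A", "G", "C", "T"))
  m
}
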