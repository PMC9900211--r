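#' Load a genome from a FASTA file
#'
#' Reads a (possibly multi-record, multi-line) FASTA file into a
#' `genome_seq` object: a named list of uppercase nucleotide strings over
#' the alphabet `{A,C,G,T,N}`. Lowercase input is uppercased; any other
#' character is an error.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A `genome_seq` object (named character vector of contig
#'   sequences).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", "ACGT"), fa)
#' g <- load_fasta(fa)
#' contig_lengths(g)
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal characters (outside A/C/G/T/N) in contig(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in FASTA")
  genome_seq(seqs)
}

#' Construct a genome_seq from named sequences
#'
#' @param contigs Named character vector of uppercase nucleotide strings.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(contigs) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)), all(nzchar(names(contigs))))
  if (any(nchar(contigs) < 1L)) stop("every contig must have length >= 1")
  if (any(grepl("[^ACGTN]", contigs))) stop("contig alphabet must be {A,C,G,T,N}")
  structure(as.list(contigs), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x), " contig(s), ",
      format(sum(contig_lengths(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome A `genome_seq`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome, nchar, integer(1))
}

contig_seq <- function(genome, chrom) {
  s <- genome[[chrom]]
  if (is.null(s)) stop("unknown contig: ", chrom)
  s
}

#' Fetch a sequence for a genomic interval
#'
#' Coordinates are 0-based, half-open; the returned string has length
#' `end - start`. Out-of-bounds intervals are an error (no clamping).
#'
#' @param genome A `genome_seq`.
#' @param iv A `ginterval` (or any list/data.frame row with `chrom`,
#'   `start`, `end`).
#' @return A nucleotide string of length `end - start`.
#' @export
fetch <- function(genome, iv) {
  fetch_range(genome, iv$chrom[1], iv$start[1], iv$end[1])
}

#' Fetch by explicit coordinates
#'
#' Vectorized over `start`/`end` (a single `chrom` at a time).
#'
#' @inheritParams fetch
#' @param chrom Contig name.
#' @param start,end 0-based half-open coordinates.
#' @return Character vector of sequences.
#' @export
fetch_range <- function(genome, chrom, start, end) {
  s <- contig_seq(genome, chrom)
  n <- nchar(s)
  if (any(start < 0) || any(end > n) || any(end <= start)) {
    stop(sprintf("interval out of bounds on %s (length %d)", chrom, n))
  }
  substring(s, start + 1L, end)
}

#' GC content of nucleotide sequences
#'
#' Fraction of G + C bases over the full sequence length; `N` counts
#' toward the length but not toward G + C.
#'
#' @param seq Character vector of nonempty nucleotide strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTAT"))
#' @export
gc_content <- function(seq) {
  if (length(seq) == 0L) return(numeric(0))
  n <- nchar(seq)
  if (any(n == 0L)) stop("gc_content: empty sequence")
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
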