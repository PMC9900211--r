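#' Construct genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' in the package-wide 0-based half-open convention.
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer-valued coordinates, `start >= 0`, `end > start`.
#' @return A data frame of class `c("ginterval", "data.frame")`.
#' @export
ginterval <- function(chrom, start, end) {
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start),
                    end = as.numeric(end),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0)) stop("interval start must be >= 0")
  if (any(out$end <= out$start)) stop("interval end must be > start (half-open)")
  class(out) <- c("ginterval", "data.frame")
  out
}

#' Pairwise interval overlap
#'
#' Two half-open intervals overlap iff they are on the same contig and
#' `a.start < b.end && b.start < a.end`; adjacent intervals do not
#' overlap. Vectorized with the usual recycling.
#'
#' @param a,b Interval data frames (see [ginterval()]).
#' @return Logical vector.
#' @examples
#' overlaps(ginterval("c1", 0, 10), ginterval("c1", 10, 20)) # FALSE
#' overlaps(ginterval("c1", 0, 10), ginterval("c1", 9, 20))  # TRUE
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Convert intervals to GRanges (1-based closed) for overlap machinery
#' @noRd
as_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
}

#' Does each query interval overlap any subject interval?
#'
#' Set-level counterpart of [overlaps()], backed by
#' `GenomicRanges::findOverlaps()`.
#'
#' @param query,subject Interval data frames.
#' @return Logical vector along the rows of `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}

#' Midpoint-centered fixed-width window around an interval
#'
#' The window is `[mid - width/2, mid + width/2)` with
#' `mid = floor((start + end) / 2)`. Windows that fall outside their
#' contig are dropped with a warning when a genome is supplied.
#'
#' @param iv Interval data frame.
#' @param width Window width in bp (even).
#' @param genome Optional `genome_seq` used for bounds checking.
#' @return Interval data frame of standardized windows (other columns of
#'   `iv` are carried through).
#' @export
center_window <- function(iv, width, genome = NULL) {
  stopifnot(width %% 2 == 0)
  mid <- floor((iv$start + iv$end) / 2)
  out <- iv
  out$start <- mid - width / 2
  out$end <- mid + width / 2
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    if (!all(out$chrom %in% names(lens))) {
      stop("unknown contig(s): ",
           paste(setdiff(unique(out$chrom), names(lens)), collapse = ", "))
    }
    ok <- out$start >= 0 & out$end <= lens[out$chrom]
    if (any(!ok)) {
      warning(sum(!ok), " window(s) outside contig bounds dropped")
      out <- out[ok, , drop = FALSE]
    }
  } else if (any(out$start < 0)) {
    warning(sum(out$start < 0), " window(s) with negative start dropped")
    out <- out[out$start >= 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
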