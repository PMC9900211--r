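#' Construct a table of variants
#'
#' Variants are rows of a data frame with columns `chrom`, `pos` (0-based
#' coordinate of the first reference base), `ref`, `alt` and an optional
#' `vid`. Alleles must be nonempty strings over `{A,C,G,T}` with
#' `ref != alt`.
#'
#' @param chrom Contig names.
#' @param pos 0-based positions.
#' @param ref,alt Allele strings.
#' @param vid Optional source identifiers.
#' @return A validated variant data frame.
#' @export
variants <- function(chrom, pos, ref, alt, vid = NA_character_) {
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    ref = toupper(as.character(ref)),
                    alt = toupper(as.character(alt)),
                    vid = as.character(vid), stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

validate_variants <- function(v) {
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(v))) {
    stop("variant table must have columns ", paste(req, collapse = ", "))
  }
  if (any(v$pos < 0)) stop("variant pos must be >= 0")
  if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) stop("alleles must be nonempty")
  if (any(grepl("[^ACGT]", v$ref)) || any(grepl("[^ACGT]", v$alt))) {
    stop("allele alphabet must be {A,C,G,T}")
  }
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  invisible(v)
}

#' Indel length of variants
#'
#' Absolute difference of allele lengths, `|len(ref) - len(alt)|`.
#' Small indels have length >= 1; equal-length variants (SNVs, MNVs) get 0
#' and are rejected by sindel-specific operations.
#'
#' @param v Variant data frame.
#' @return Integer vector.
#' @export
indel_length <- function(v) {
  abs(nchar(v$ref) - nchar(v$alt))
}

#' Reference span of variants
#'
#' The half-open interval `[pos, pos + len(ref))` covered by the
#' reference allele; used for overlap-based filters and region counting.
#'
#' @param v Variant data frame.
#' @return Interval data frame with one row per variant.
#' @export
variant_span <- function(v) {
  ginterval(v$chrom, v$pos, v$pos + nchar(v$ref))
}

#' Canonical variant keys
#'
#' Deterministic `"chrom:pos:ref:alt"` identity strings (0-based pos);
#' equal variants map to equal keys.
#'
#' @param v Variant data frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(v) {
  sprintf("%s:%d:%s:%s", v$chrom, as.integer(v$pos), v$ref, v$alt)
}
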