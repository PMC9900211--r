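#' Read an eQTL summary-statistics table
#'
#' Tab-delimited with header columns `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `tss_distance`, `q_value`, `maf`. One row per variant-gene
#' association; a variant may appear on several rows (one per gene).
#' TSS distances are stored as absolute values.
#'
#' @param path Path to a TSV file.
#' @param one_based Whether the `pos` column is 1-based (VCF-style,
#'   the default); positions are converted to the internal 0-based
#'   convention on read.
#' @return Data frame of eQTL records (variant columns + `gene`,
#'   `tss_distance`, `q_value`, `maf`).
#' @export
read_eqtl <- function(path, one_based = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "gene", "tss_distance", "q_value", "maf")
  if (!all(req %in% names(tab))) {
    stop("eQTL table must have columns ", paste(req, collapse = ", "))
  }
  tab <- tab[, req, drop = FALSE]
  tab$pos <- as.numeric(tab$pos) - if (one_based) 1L else 0L
  tab$tss_distance <- abs(as.numeric(tab$tss_distance))
  tab$q_value <- as.numeric(tab$q_value)
  tab$maf <- as.numeric(tab$maf)
  if (any(tab$q_value < 0 | tab$q_value > 1, na.rm = TRUE)) {
    stop("q_value outside [0, 1] in ", path)
  }
  if (any(tab$maf <= 0 | tab$maf > 0.5, na.rm = TRUE)) {
    stop("maf outside (0, 0.5] in ", path)
  }
  validate_variants(tab)
  tab
}

#' Write an eQTL summary table (1-based positions)
#' @param tab eQTL record data frame (internal 0-based positions).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eqtl <- function(tab, path) {
  out <- tab[, c("chrom", "pos", "ref", "alt", "gene",
                 "tss_distance", "q_value", "maf"), drop = FALSE]
  out$pos <- as.integer(out$pos) + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ClinVar-style variant summary table
#'
#' Expects the tab-delimited column names of ClinVar's
#' `variant_summary.txt`: `Type`, `ClinicalSignificance`, `ReviewStatus`,
#' `Chromosome`, `Start` (1-based), `ReferenceAllele`, `AlternateAllele`.
#'
#' @param path Path to a TSV file.
#' @return Data frame with internal variant columns plus `variant_type`,
#'   `clinical_significance`, `review_status`.
#' @export
read_clinvar <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("Type", "ClinicalSignificance", "ReviewStatus", "Chromosome",
           "Start", "ReferenceAllele", "AlternateAllele")
  if (!all(req %in% names(tab))) {
    stop("ClinVar table must have columns ", paste(req, collapse = ", "))
  }
  out <- data.frame(chrom = as.character(tab$Chromosome),
                    pos = as.numeric(tab$Start) - 1L,
                    ref = toupper(tab$ReferenceAllele),
                    alt = toupper(tab$AlternateAllele),
                    variant_type = tab$Type,
                    clinical_significance = tab$ClinicalSignificance,
                    review_status = tab$ReviewStatus,
                    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}
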