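#' Read a generic-annotation matrix
#'
#' Tab-delimited; first column `variant_key`, remaining columns numeric
#' with empty cells (or `NA`) for missing values.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with variant keys as row names.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"))
  if (names(tab)[1] != "variant_key") {
    stop("annotation table must have 'variant_key' as its first column")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$variant_key
  m
}

#' Write a generic-annotation matrix
#' @param m Numeric matrix with variant keys as row names.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(m, path) {
  out <- data.frame(variant_key = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Filter high-missingness annotations and impute the rest
#'
#' Keeps columns whose missing fraction is strictly below
#' `max_missing_frac` (a column missing exactly 10% of its values is
#' dropped at the default), then replaces remaining missing entries by
#' the column median over observed values. Column order is preserved.
#'
#' @param m Numeric annotation matrix (variants x annotations).
#' @param max_missing_frac Missingness threshold for keeping a column
#'   (exclusive; default 0.10).
#' @return Matrix with no missing entries and a subset of the columns.
#' @export
filter_and_impute <- function(m, max_missing_frac = 0.10) {
  stopifnot(is.matrix(m), nrow(m) > 0L, ncol(m) > 0L)
  miss_frac <- colMeans(is.na(m))
  keep <- miss_frac < max_missing_frac
  if (!any(keep)) stop("all annotation columns exceed the missingness threshold")
  out <- m[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    nas <- is.na(out[, j])
    if (any(nas)) out[nas, j] <- median(out[!nas, j])
  }
  out
}
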