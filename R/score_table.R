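#' Read a precomputed functional-score table
#'
#' Tab-delimited with header columns `variant_key`, `tissue`, `score`.
#' Scores must lie in `[0, 1]` and each `(variant_key, tissue)` pair may
#' appear only once.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `variant_key`, `tissue`, `score`.
#' @export
read_score_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("variant_key", "tissue", "score")
  if (!all(req %in% names(tab))) {
    stop("score table must have columns ", paste(req, collapse = ", "))
  }
  tab <- tab[, req, drop = FALSE]
  tab$score <- as.numeric(tab$score)
  if (anyNA(tab$score)) stop("malformed score value(s) in ", path)
  if (any(tab$score < 0 | tab$score > 1)) stop("score(s) outside [0, 1] in ", path)
  if (anyDuplicated(tab[, c("variant_key", "tissue")])) {
    stop("duplicate (variant_key, tissue) row(s) in ", path)
  }
  tab
}

#' Write a functional-score table
#'
#' Scores are serialized at 6 decimal places so that write/read round
#' trips are exact.
#'
#' @param tab Data frame with columns `variant_key`, `tissue`, `score`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  req <- c("variant_key", "tissue", "score")
  stopifnot(all(req %in% names(tab)))
  if (any(tab$score < 0 | tab$score > 1)) stop("score(s) outside [0, 1]")
  if (anyDuplicated(tab[, c("variant_key", "tissue")])) {
    stop("duplicate (variant_key, tissue) row(s)")
  }
  out <- data.frame(variant_key = tab$variant_key, tissue = tab$tissue,
                    score = sprintf("%.6f", tab$score),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retrieve scores for variant keys
#'
#' Keys absent from the table yield no rows (an empty result, not an
#' error), mirroring lookup in a precomputed score deposition.
#'
#' @param tab Score table (see [read_score_table()]).
#' @param keys Character vector of variant keys.
#' @param tissue Optional tissue label to restrict to.
#' @return Subset of `tab` rows matching the query.
#' @export
query_scores <- function(tab, keys, tissue = NULL) {
  sel <- tab$variant_key %in% keys
  if (!is.null(tissue)) sel <- sel & tab$tissue == tissue
  out <- tab[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
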