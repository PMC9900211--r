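#' Write / read a featurized set as TSV
#'
#' Portable text serialization of a `featurized_set`: columns
#' `variant_key`, `label`, then one column per feature (block prefixes
#' preserved in the header).
#'
#' @param fs A `featurized_set` (see [featurize_labeled_set()]).
#' @param path TSV path.
#' @return `path` invisibly (write); a `featurized_set` (read).
#' @export
write_feature_table <- function(fs, path) {
  stopifnot(inherits(fs, "featurized_set"))
  out <- data.frame(variant_key = fs$keys, label = fs$y, fs$X,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param tissue Tissue label to attach on read.
#' @export
read_feature_table <- function(path, tissue = "unspecified") {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("variant_key", "label") %in% names(tab)))
  X <- as.matrix(tab[, setdiff(names(tab), c("variant_key", "label")),
                     drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- tab$variant_key
  structure(list(X = X, y = as.integer(tab$label), keys = tab$variant_key,
                 tissue = tissue),
            class = "featurized_set")
}
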