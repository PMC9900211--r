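#' Predict profile matrices for a set of sequence windows
#'
#' Applies a profile predictor to every reference and alternative window,
#' giving two aligned variants-by-tracks matrices.
#'
#' @param windows Window data frame from [build_windows()].
#' @param p A `profile_predictor`.
#' @return List with matrices `ref` and `alt` (rownames = variant keys).
#' @export
predict_window_profiles <- function(windows, p) {
  n <- nrow(windows)
  ref <- matrix(NA_real_, n, p$n_tracks,
                dimnames = list(windows$variant_key, colnames(p$W)))
  alt <- ref
  for (i in seq_len(n)) {
    ref[i, ] <- predict_profiles(p, windows$ref_seq[i])
    alt[i, ] <- predict_profiles(p, windows$alt_seq[i])
  }
  list(ref = ref, alt = alt)
}

#' Absolute + relative profile-difference features
#'
#' The feature transform used by the boosted-logistic-regression
#' baseline: the absolute difference `|ref - alt|` concatenated with the
#' relative difference `(ref - alt) / (ref + eps)` of the predicted
#' profiles.
#'
#' @param ref,alt Aligned profile matrices (variants x tracks).
#' @param eps Stabilizer for the relative difference denominator.
#' @return Matrix of width `2 * n_tracks` with `absdiff:`/`reldiff:`
#'   column prefixes.
#' @export
diff_features <- function(ref, alt, eps = 1e-6) {
  stopifnot(identical(dim(ref), dim(alt)))
  ad <- abs(ref - alt)
  rd <- (ref - alt) / (ref + eps)
  colnames(ad) <- paste0("absdiff:", colnames(ref))
  colnames(rd) <- paste0("reldiff:", colnames(ref))
  cbind(ad, rd)
}

#' Assemble the classifier feature matrix
#'
#' Combines the (already filtered/imputed) generic-annotation block with
#' predicted epigenomic-profile blocks for the reference and/or
#' alternative windows, according to `feature_set`:
#' * `"generic"` — generic annotations only (width `n_generic`);
#' * `"generic+ref"` — plus reference-window profiles
#'   (`n_generic + n_tracks`);
#' * `"generic+ref+alt"` — plus both windows' profiles
#'   (`n_generic + 2 * n_tracks`), the full model;
#' * `"diff"` — profile-difference features only (`2 * n_tracks`), the
#'   baseline transform of [diff_features()].
#'
#' Column names carry block prefixes (`cadd:`, `ref:`, `alt:`,
#' `absdiff:`, `reldiff:`); row order follows `windows`.
#'
#' @param annots Numeric annotation matrix (variant keys as row names),
#'   typically from [filter_and_impute()].
#' @param windows Window data frame from [build_windows()].
#' @param p A `profile_predictor` (unused for `feature_set = "generic"`).
#' @param feature_set One of `"generic"`, `"generic+ref"`,
#'   `"generic+ref+alt"`, `"diff"`.
#' @param profiles Optional precomputed result of
#'   [predict_window_profiles()] to avoid re-prediction.
#' @return Numeric matrix with attributes `feature_set` and
#'   `block_sizes`.
#' @export
assemble_features <- function(annots, windows, p = NULL,
                              feature_set = c("generic+ref+alt", "generic",
                                              "generic+ref", "diff"),
                              profiles = NULL) {
  feature_set <- match.arg(feature_set)
  keys <- windows$variant_key
  missing_keys <- setdiff(keys, rownames(annots))
  if (feature_set != "diff" && length(missing_keys) > 0L) {
    stop("variant key(s) absent from annotation matrix: ",
         paste(utils::head(missing_keys, 3), collapse = ", "),
         if (length(missing_keys) > 3) " ...")
  }
  need_profiles <- feature_set != "generic"
  if (need_profiles && is.null(profiles)) {
    if (is.null(p)) stop("a profile predictor is required for feature set ", feature_set)
    profiles <- predict_window_profiles(windows, p)
  }
  blocks <- list()
  if (feature_set != "diff") {
    g <- annots[keys, , drop = FALSE]
    colnames(g) <- paste0("cadd:", colnames(g))
    blocks$generic <- g
  }
  if (feature_set %in% c("generic+ref", "generic+ref+alt")) {
    r <- profiles$ref[keys, , drop = FALSE]
    colnames(r) <- paste0("ref:", colnames(profiles$ref))
    blocks$profile_ref <- r
  }
  if (feature_set == "generic+ref+alt") {
    a <- profiles$alt[keys, , drop = FALSE]
    colnames(a) <- paste0("alt:", colnames(profiles$alt))
    blocks$profile_alt <- a
  }
  if (feature_set == "diff") {
    blocks$profile_diff <- diff_features(profiles$ref[keys, , drop = FALSE],
                                         profiles$alt[keys, , drop = FALSE])
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- keys
  if (anyNA(X)) stop("assembled feature matrix contains missing values")
  attr(X, "feature_set") <- feature_set
  attr(X, "block_sizes") <- vapply(blocks, ncol, integer(1))
  X
}
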