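#' Default gradient-boosting hyperparameters
#'
#' Mid-size defaults used throughout: 500 trees of depth 6, learning
#' rate 0.05, row subsampling 0.8, logistic objective, single thread
#' (for bit-reproducibility), histogram split finding with 64 bins.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(nrounds = 500L, max_depth = 6L, eta = 0.05, subsample = 0.8,
       objective = "binary:logistic", nthread = 1L,
       tree_method = "hist", max_bin = 64L)
}

#' Train a per-tissue gradient-boosted classifier
#'
#' Fits an XGBoost tree ensemble on a feature matrix and binary labels.
#' Deterministic under a fixed seed and single-thread setting.
#'
#' @param X Numeric feature matrix with column names (see
#'   [assemble_features()]).
#' @param y Binary labels (0/1), both classes present.
#' @param hyperparams Named list overriding [default_hyperparams()].
#' @param seed Integer seed.
#' @param tissue Tissue label stored with the model.
#' @return A `tissue_model` object.
#' @export
train_model <- function(X, y, hyperparams = list(), seed = 1L,
                        tissue = "unspecified") {
  y <- as.integer(y)
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (nrow(X) == 0L) stop("empty feature matrix")
  if (length(unique(y)) < 2L) stop("both classes must be present to train")
  if (is.null(colnames(X))) stop("feature matrix must have column names")
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  params <- list(objective = hp$objective, max_depth = hp$max_depth,
                 eta = hp$eta, subsample = hp$subsample,
                 nthread = hp$nthread, tree_method = hp$tree_method,
                 max_bin = hp$max_bin, seed = seed)
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = hp$nrounds, verbose = 0))
  structure(list(tissue = tissue, booster = booster,
                 feature_names = colnames(X), hyperparams = hp,
                 seed = seed, feature_set = attr(X, "feature_set")),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model> tissue=", x$tissue, ", ", length(x$feature_names),
      " features, ", x$hyperparams$nrounds, " trees\n", sep = "")
  invisible(x)
}

#' Score variants with a fitted model
#'
#' Generic over the package's model classes (gradient-boosted tissue
#' models and the two baselines). The feature matrix must carry exactly
#' the feature names seen at fit time, in the same order; a mismatch is
#' an error, never a silent misprediction.
#'
#' @param m A fitted model.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, one per row of `X`.
#' @export
predict_scores <- function(m, X, ...) UseMethod("predict_scores")

check_feature_names <- function(m, X) {
  if (!identical(colnames(X), m$feature_names)) {
    stop("feature names of X do not match the model's ",
         "(same names, same order required)")
  }
}

#' @rdname predict_scores
#' @export
predict_scores.tissue_model <- function(m, X, ...) {
  check_feature_names(m, X)
  as.numeric(predict(m$booster, xgboost::xgb.DMatrix(X)))
}

#' Save / load a fitted tissue model
#'
#' The model is serialized to a single portable file holding the raw
#' booster bytes plus feature names and training metadata.
#'
#' @param m A `tissue_model`.
#' @param path File path.
#' @return `path` invisibly (save); a `tissue_model` (load).
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "tissue_model"))
  obj <- list(tissue = m$tissue, raw = xgboost::xgb.save.raw(m$booster),
              feature_names = m$feature_names, hyperparams = m$hyperparams,
              seed = m$seed, feature_set = m$feature_set)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(tissue = obj$tissue,
                 booster = xgboost::xgb.load.raw(obj$raw),
                 feature_names = obj$feature_names,
                 hyperparams = obj$hyperparams, seed = obj$seed,
                 feature_set = obj$feature_set),
            class = "tissue_model")
}
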