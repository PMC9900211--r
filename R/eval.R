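#' Construct an evaluation result
#'
#' @param protocol Protocol label (`"cv"`, `"cross_tissue"`, ...).
#' @param train_tissue,test_tissue Tissue labels.
#' @param scores Pooled score vector.
#' @param labels Binary labels aligned with `scores`.
#' @param extra Named list of protocol-specific extras.
#' @return An `eval_result` with `auroc`, `auprc`, `n_test`.
#' @export
eval_result <- function(protocol, train_tissue, test_tissue, scores, labels,
                        extra = list()) {
  structure(c(list(protocol = protocol, train_tissue = train_tissue,
                   test_tissue = test_tissue,
                   auroc = auroc(scores, labels),
                   auprc = auprc(scores, labels),
                   n_test = length(scores),
                   scores = scores, labels = as.integer(labels)),
              extra),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s %s->%s: AUROC %.4f, AUPRC %.4f (n=%d)\n",
              x$protocol, x$train_tissue, x$test_tissue,
              x$auroc, x$auprc, x$n_test))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Permutes each class independently and deals indices round-robin, so
#' every fold contains both classes whenever each class has at least `k`
#' members.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `1..k`, one per element of `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (any(table(y) < k)) {
    stop("each class needs at least k = ", k, " members for stratified folds")
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

#' Pooled k-fold cross-validation
#'
#' Stratified k-fold CV in which each row is scored exactly once by a
#' model whose training fold excluded it; the held-out scores of all
#' folds are concatenated into a single pooled vector and AUROC/AUPRC
#' are computed on that vector (not averaged across folds).
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 5).
#' @param trainer Function `(X, y, seed) -> model` answering
#'   [predict_scores()]; defaults to the gradient-boosted tissue model
#'   with [default_hyperparams()].
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param tissue Tissue label for the result.
#' @param protocol Protocol label recorded in the result.
#' @return An `eval_result` whose `scores` follow the row order of `X`;
#'   `extra` field `folds` records the fold assignment.
#' @export
cv_pooled <- function(X, y, k = 5L, trainer = NULL, seed = 1L,
                      tissue = "unspecified", protocol = "cv") {
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < k) stop("need at least k = ", k, " rows for ", k, "-fold CV")
  if (is.null(trainer)) {
    trainer <- function(X, y, seed) train_model(X, y, seed = seed, tissue = tissue)
  }
  fold <- stratified_folds(y, k, seed)
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    m <- trainer(X[!test, , drop = FALSE], y[!test], seed + f)
    scores[test] <- predict_scores(m, X[test, , drop = FALSE])
  }
  stopifnot(!anyNA(scores))
  eval_result(protocol, tissue, tissue, scores, y, extra = list(folds = fold))
}

#' Featurize a labeled set
#'
#' Builds windows, predicts profiles and assembles the feature matrix
#' for the positives and negatives of a [labeled_set()], returning the
#' matrix, labels and variant keys aligned by row.
#'
#' @param lset A `labeled_set`.
#' @param genome A `genome_seq`.
#' @param annots Filtered/imputed annotation matrix.
#' @param p A `profile_predictor`.
#' @param feature_set Passed to [assemble_features()].
#' @param L Window length.
#' @return List with `X`, `y`, `keys`, `tissue` (class
#'   `featurized_set`).
#' @export
featurize_labeled_set <- function(lset, genome, annots, p,
                                  feature_set = "generic+ref+alt",
                                  L = 1000L) {
  stopifnot(inherits(lset, "labeled_set"))
  v <- rbind(lset$positives[, c("chrom", "pos", "ref", "alt")],
             lset$negatives[, c("chrom", "pos", "ref", "alt")])
  y <- c(rep(1L, nrow(lset$positives)), rep(0L, nrow(lset$negatives)))
  win <- build_windows(genome, v, L)
  kept <- match(win$variant_key, variant_key(v))
  X <- assemble_features(annots, win, p, feature_set)
  structure(list(X = X, y = y[kept], keys = win$variant_key,
                 tissue = lset$tissue),
            class = "featurized_set")
}

#' Cross-tissue (or cross-study) transfer evaluation
#'
#' Trains on one featurized set and tests on another. Test rows whose
#' variant key appears in the training set are removed before scoring,
#' preventing leakage of shared labeled variants; `n_test` reflects the
#' post-removal count.
#'
#' @param train_set,test_set `featurized_set` objects with identical
#'   feature names.
#' @param trainer Optional trainer as in [cv_pooled()].
#' @param seed Integer seed.
#' @param protocol Protocol label.
#' @return An `eval_result`; `extra` field `removed` counts the shared
#'   variants dropped from the test set.
#' @export
cross_tissue_eval <- function(train_set, test_set, trainer = NULL, seed = 1L,
                              protocol = "cross_tissue") {
  stopifnot(inherits(train_set, "featurized_set"),
            inherits(test_set, "featurized_set"))
  if (!identical(colnames(train_set$X), colnames(test_set$X))) {
    stop("train and test sets must share identical feature names")
  }
  if (is.null(trainer)) {
    trainer <- function(X, y, seed) {
      train_model(X, y, seed = seed, tissue = train_set$tissue)
    }
  }
  shared <- test_set$keys %in% train_set$keys
  if (all(shared)) stop("test set is empty after overlap removal")
  keep <- !shared
  m <- trainer(train_set$X, train_set$y, seed)
  scores <- predict_scores(m, test_set$X[keep, , drop = FALSE])
  eval_result(protocol, train_set$tissue, test_set$tissue,
              scores, test_set$y[keep],
              extra = list(removed = sum(shared),
                           test_keys = test_set$keys[keep]))
}

# --- baselines ---------------------------------------------------------------

#' Train the kernel-SVM baseline on generic annotations
#'
#' Radial-basis soft-margin SVM over the generic-annotation block only,
#' representing annotation-driven SVM scorers. Continuous decision
#' values (mapped through the logistic function) serve as scores.
#'
#' @param X Feature matrix (generic block).
#' @param y Binary labels.
#' @param seed Integer seed.
#' @param cost Soft-margin cost parameter.
#' @return An `svm_baseline_model`.
#' @export
train_svm_baseline <- function(X, y, seed = 1L, cost = 1) {
  y <- factor(as.integer(y), levels = c(0L, 1L))
  fit <- withr::with_seed(seed, e1071::svm(X, y, kernel = "radial",
                                           cost = cost, scale = TRUE))
  structure(list(fit = fit, feature_names = colnames(X), seed = seed),
            class = "svm_baseline_model")
}

#' @rdname predict_scores
#' @export
predict_scores.svm_baseline_model <- function(m, X, ...) {
  check_feature_names(m, X)
  dv <- attr(predict(m$fit, X, decision.values = TRUE), "decision.values")
  # decision values are oriented toward the first class in the colname
  sgn <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
  plogis(sgn * as.numeric(dv[, 1]))
}

#' SVM-on-generic-annotations baseline, pooled CV
#'
#' Runs the same pooled k-fold protocol as [cv_pooled()] with the
#' kernel-SVM baseline restricted to generic annotations.
#'
#' @param X_generic Feature matrix containing only the generic block.
#' @param y Binary labels.
#' @param k Folds.
#' @param seed Integer seed.
#' @return An `eval_result` (protocol `"cv_svm_generic"`).
#' @export
baseline_svm_generic <- function(X_generic, y, k = 5L, seed = 1L) {
  cv_pooled(X_generic, y, k,
            trainer = function(X, y, s) train_svm_baseline(X, y, s),
            seed = seed, protocol = "cv_svm_generic")
}

#' Train the boosted-logistic-regression baseline on profile differences
#'
#' Gradient boosting with depth-1 stumps and logistic loss over the
#' absolute + relative ref/alt profile-difference features — the classic
#' sequence-model scoring recipe.
#'
#' @param X Difference-feature matrix (see [diff_features()]).
#' @param y Binary labels.
#' @param seed Integer seed.
#' @param nrounds,eta Boosting rounds and learning rate.
#' @return A `tissue_model` (stump ensemble).
#' @export
train_boosted_lr <- function(X, y, seed = 1L, nrounds = 300L, eta = 0.1) {
  train_model(X, y,
              hyperparams = list(nrounds = nrounds, max_depth = 1L,
                                 eta = eta, subsample = 1),
              seed = seed, tissue = "boosted_lr")
}

#' Boosted-LR-on-profile-differences baseline, pooled CV
#'
#' Builds `[ |ref - alt| ; (ref - alt) / (ref + eps) ]` difference
#' features from aligned profile blocks and runs pooled k-fold CV with a
#' boosted logistic regression (shallow-stump gradient boosting).
#'
#' @param ref,alt Aligned profile matrices (variants x tracks).
#' @param y Binary labels.
#' @param k Folds.
#' @param seed Integer seed.
#' @param eps Stabilizer for the relative difference.
#' @return An `eval_result` (protocol `"cv_boosted_lr_diff"`).
#' @export
baseline_boosted_lr_diff <- function(ref, alt, y, k = 5L, seed = 1L,
                                     eps = 1e-6) {
  X <- diff_features(ref, alt, eps)
  cv_pooled(X, y, k,
            trainer = function(X, y, s) train_boosted_lr(X, y, s),
            seed = seed, protocol = "cv_boosted_lr_diff")
}
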