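# brute-force oracles, independent of the implementations they check
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
auprc_oracle <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  tp <- 0; fp <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) { tp <- tp + 1; s <- s + tp / (tp + fp) } else fp <- fp + 1
  }
  s / sum(y)
}

test_that("AUROC equals pairwise concordance, with half-credit ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "both classes")
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(4:30, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 2)      # coarse grid to exercise ties
      expect_equal(auroc(s, y), auroc_oracle(s, y))
    }
  })
})

test_that("AUPRC equals step-integrated average precision", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(0.8, 0.2), c(0, 1)), 0.5)
  expect_equal(auprc(c(0.3, 0.6), c(1, 1)), 1.0)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "positive")
  withr::with_seed(6, {
    for (i in 1:50) {
      n <- sample(4:30, 1)
      y <- c(1, rbinom(n - 1, 1, 0.4))
      s <- round(runif(n), 2)
      expect_equal(auprc(s, y), auprc_oracle(s, y))
    }
  })
})

test_that("rank metrics agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    y <- c(rep(1, 20), rep(0, 20))
    s <- runif(40)
    expect_equal(auroc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  })
})

toy_separable <- function(n = 40, seed = 2) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(f1 = y * 3 + rnorm(n, sd = 0.1), f2 = rnorm(n))
    list(X = X, y = y)
  })
}

test_that("training separates separable data and rejects degenerate input", {
  d <- toy_separable()
  m <- train_model(d$X, d$y, hyperparams = list(nrounds = 30), seed = 1)
  s <- predict_scores(m, d$X)
  expect_equal(auroc(s, d$y), 1.0)
  expect_true(all(s[d$y == 1] > max(s[d$y == 0])))
  expect_error(train_model(d$X, rep(1L, nrow(d$X))), "both classes")
  expect_error(train_model(d$X[0, , drop = FALSE], integer(0)), "empty")
})

test_that("prediction is deterministic and order-sensitive about feature names", {
  d <- toy_separable()
  m <- train_model(d$X, d$y, hyperparams = list(nrounds = 30), seed = 1)
  expect_identical(predict_scores(m, d$X), predict_scores(m, d$X))
  Xperm <- d$X[, c("f2", "f1")]
  expect_error(predict_scores(m, Xperm), "feature names")
  # same seed, retrain: identical model output
  m2 <- train_model(d$X, d$y, hyperparams = list(nrounds = 30), seed = 1)
  expect_identical(predict_scores(m2, d$X), predict_scores(m, d$X))
})

test_that("models survive a save/load round trip", {
  d <- toy_separable()
  m <- train_model(d$X, d$y, hyperparams = list(nrounds = 30), seed = 1,
                   tissue = "Lung")
  f <- withr::local_tempfile(fileext = ".model")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$tissue, "Lung")
  expect_identical(predict_scores(m2, d$X), predict_scores(m, d$X))
})

test_that("pooled CV scores every row exactly once and is reproducible", {
  withr::with_seed(3, {
    n <- 100
    y <- rep(c(0L, 1L), each = 50)
    X <- cbind(f1 = y + rnorm(n), f2 = rnorm(n))
  })
  tr <- function(X, y, s) train_model(X, y, hyperparams = list(nrounds = 20), seed = s)
  res <- cv_pooled(X, y, k = 5, trainer = tr, seed = 7)
  expect_identical(res$n_test, 100L)
  expect_false(anyNA(res$scores))
  expect_identical(sort(unique(res$folds)), 1:5)
  # stratification: both classes in every fold
  for (f in 1:5) expect_identical(sort(unique(y[res$folds == f])), c(0L, 1L))
  res2 <- cv_pooled(X, y, k = 5, trainer = tr, seed = 7)
  expect_identical(res$scores, res2$scores)
  expect_identical(res$auroc, res2$auroc)
  expect_error(cv_pooled(X[1:4, ], y[1:4], k = 5, trainer = tr), "at least k")
})

test_that("CV on label-shuffled data gives chance-level AUROC", {
  withr::with_seed(11, {
    n <- 200
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c(0L, 1L), each = n / 2)
  })
  tr <- function(X, y, s) train_model(X, y, hyperparams = list(nrounds = 30), seed = s)
  res <- cv_pooled(X, y, k = 5, trainer = tr, seed = 13)
  expect_gt(res$auroc, 0.35)
  expect_lt(res$auroc, 0.65)
})

featurized_stub <- function(keys, y, X, tissue) {
  structure(list(X = X, y = y, keys = keys, tissue = tissue),
            class = "featurized_set")
}

test_that("cross-tissue evaluation removes shared variant keys from the test set", {
  d <- toy_separable(n = 200, seed = 4)
  keys_tr <- sprintf("c1:%d:AC:A", 1:200)
  keys_te <- sprintf("c1:%d:AC:A", 191:390)   # 10 shared keys
  tr_set <- featurized_stub(keys_tr, d$y, d$X, "A")
  te <- toy_separable(n = 200, seed = 5)
  te_set <- featurized_stub(keys_te, te$y, te$X, "B")
  trainer <- function(X, y, s) train_model(X, y, hyperparams = list(nrounds = 20), seed = s)
  res <- cross_tissue_eval(tr_set, te_set, trainer, seed = 1)
  expect_identical(res$n_test, 190L)
  expect_identical(res$removed, 10L)
  expect_length(intersect(res$test_keys, keys_tr), 0)

  # disjoint keys: nothing removed
  te_set2 <- featurized_stub(sprintf("c2:%d:AC:A", 1:200), te$y, te$X, "B")
  expect_identical(cross_tissue_eval(tr_set, te_set2, trainer, seed = 1)$n_test, 200L)

  # identical sets: empty test set is an error
  expect_error(cross_tissue_eval(tr_set, tr_set, trainer), "empty")
  # mismatched feature names
  bad <- te_set2; colnames(bad$X) <- c("f2", "f1")
  expect_error(cross_tissue_eval(tr_set, bad, trainer), "feature names")
})

test_that("the SVM baseline separates separable data deterministically", {
  d <- toy_separable(n = 60, seed = 9)
  res <- baseline_svm_generic(d$X, d$y, k = 5, seed = 2)
  expect_equal(res$auroc, 1.0)
  res2 <- baseline_svm_generic(d$X, d$y, k = 5, seed = 2)
  expect_identical(res$scores, res2$scores)
})

test_that("the boosted-LR baseline uses 2x n_tracks difference features", {
  withr::with_seed(10, {
    n <- 60; nt <- 7L
    ref <- matrix(runif(n * nt), n, nt, dimnames = list(NULL, paste0("t", 1:nt)))
    y <- rep(c(0L, 1L), each = n / 2)
    alt <- ref
    alt[y == 1, ] <- alt[y == 1, ] + 0.3   # label-informative difference
  })
  res <- baseline_boosted_lr_diff(ref, alt, y, k = 5, seed = 3)
  expect_gt(res$auroc, 0.9)
  expect_identical(ncol(diff_features(ref, alt)), 2L * nt)
  # ref == alt: no information, chance-level
  res0 <- baseline_boosted_lr_diff(ref, ref, y, k = 5, seed = 3)
  expect_gt(res0$auroc, 0.3)
  expect_lt(res0$auroc, 0.7)
})
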