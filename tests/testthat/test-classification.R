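test_that("z-score normalization fits on training rows only", {
  z <- zscore_normalize(data.frame(f = c(1, 2, 3)))
  expect_equal(z$train$f, c(-1, 0, 1))

  # idempotence on already-normalized data
  z2 <- zscore_normalize(z$train)
  expect_equal(z2$train$f, z$train$f, tolerance = 1e-12)

  expect_error(zscore_normalize(data.frame(good = 1:5, bad = rep(2, 5))),
    "bad")

  # no leakage: scaling statistics ignore the test rows entirely
  set.seed(61)
  tr <- data.frame(a = rnorm(20), b = rnorm(20))
  te <- data.frame(a = rnorm(5), b = rnorm(5))
  z3 <- zscore_normalize(tr, te)
  z4 <- zscore_normalize(tr, te * 100)
  expect_identical(z3$center, z4$center)
  expect_identical(z3$scale, z4$scale)
  expect_equal(z3$center, vapply(tr, mean, 0))
})

test_that("compute_metrics reproduces hand-evaluated formulas", {
  perfect <- compute_metrics(TP = 5, FP = 0, TN = 5, FN = 0)
  expect_equal(perfect$balanced_accuracy, 100)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$mcc, 1)
  expect_length(perfect$undefined, 0)

  # no positive-class cases at all: sensitivity and BA undefined
  nopos <- compute_metrics(TP = 0, FP = 2, TN = 7, FN = 0)
  expect_true(is.na(nopos$sensitivity))
  expect_true(is.na(nopos$balanced_accuracy))
  expect_false(is.na(nopos$specificity))
  expect_true(all(c("sensitivity", "balanced_accuracy") %in%
    nopos$undefined))

  m <- compute_metrics(TP = 3, FP = 2, TN = 4, FN = 1)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$balanced_accuracy, 50 * (0.75 + 2 / 3))
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 0.8)
  expect_equal(m$mcc, 10 / sqrt(600))

  expect_error(compute_metrics(0, 0, 0, 0), "zero")
})

test_that("label swap exchanges sens/spec and PPV/NPV, preserves BA and |MCC|", {
  set.seed(62)
  for (i in 1:25) {
    cc <- rpois(4, 4)
    if (sum(cc) == 0) next
    a <- compute_metrics(TP = cc[1], FP = cc[2], TN = cc[3], FN = cc[4])
    b <- compute_metrics(TP = cc[3], FP = cc[4], TN = cc[1], FN = cc[2])
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$ppv, b$npv)
    expect_equal(a$balanced_accuracy, b$balanced_accuracy)
    if (!is.na(a$mcc) && !is.na(b$mcc)) {
      expect_equal(abs(a$mcc), abs(b$mcc), tolerance = 1e-12)
    }
  }
})

make_clusters <- function(n = 100, delta = 6, seed = 63) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(2 * n), ncol = 2),
      matrix(rnorm(2 * n, mean = delta), ncol = 2)
    )
    data.frame(f1 = x[, 1], f2 = x[, 2],
      y = rep(c("low_stress", "high_stress"), each = n))
  })
}

test_that("all three classifier families separate well-separated clusters", {
  d <- make_clusters()
  idx <- withr::with_seed(64, sample(nrow(d)))
  train <- d[idx[1:140], ]
  test <- d[idx[141:200], ]
  z <- zscore_normalize(train[, 1:2], test[, 1:2])
  for (kind in c("knn", "svm", "ann")) {
    model <- train_classifier(kind, z$train, train$y, seed = 65)
    pred <- predict(model, z$test)
    cc <- table(truth = test$y, pred = factor(pred,
      c("high_stress", "low_stress")))
    m <- compute_metrics(TP = cc["high_stress", "high_stress"],
      FP = cc["low_stress", "high_stress"],
      TN = cc["low_stress", "low_stress"],
      FN = cc["high_stress", "low_stress"])
    expect_gte(m$balanced_accuracy, 95)
  }
})

test_that("kNN with k = 1 memorises its training set", {
  d <- make_clusters(n = 30, delta = 2, seed = 66)
  z <- zscore_normalize(d[, 1:2])
  model <- train_classifier("knn", z$train, d$y, k = 1)
  expect_equal(predict(model, z$train), d$y)
})

test_that("ANN training is deterministic under a fixed seed", {
  d <- make_clusters(n = 40, seed = 67)
  z <- zscore_normalize(d[, 1:2])
  m1 <- train_classifier("ann", z$train, d$y, seed = 68)
  m2 <- train_classifier("ann", z$train, d$y, seed = 68)
  expect_identical(m1$W, m2$W)
  expect_identical(predict(m1, z$train), predict(m2, z$train))
})

test_that("classifiers reject single-class training data", {
  d <- make_clusters(n = 10)
  one <- d[d$y == "low_stress", ]
  expect_error(train_classifier("knn", one[, 1:2], one$y), "single class")
})

# feature table with a perfectly separating hr column, 10 subjects
separable_features <- function(n_per_subj = 6, seed = 69) {
  withr::with_seed(seed, {
    rows <- lapply(1:10, function(s) {
      cls <- if (s <= 5) "low_stress" else "high_stress"
      hr <- rnorm(n_per_subj, if (cls == "low_stress") 60 else 85, 1)
      data.frame(subject = sprintf("s%02d", s),
        window_index = seq_len(n_per_subj),
        r_value_mv = rnorm(n_per_subj, 1, 0.05),
        hr_bpm = hr,
        pnn50 = runif(n_per_subj),
        binen = rnorm(n_per_subj, 0.6, 0.05),
        label = cls)
    })
    do.call(rbind, rows)
  })
}

test_that("grouped cross-validation separates subjects and aggregates", {
  ft <- separable_features()
  cv <- cross_validate(ft, kind = "knn", n_folds = 5, seed = 70)

  # 10 subjects over 5 folds: exactly 2 subjects per fold
  expect_equal(as.integer(table(cv$folds)), rep(2L, 5))
  expect_length(cv$fold_metrics, 5)

  # windows of one subject never straddle folds (fold map is per subject)
  expect_setequal(names(cv$folds), unique(ft$subject))

  # a perfectly separating feature: 100 +- 0
  expect_equal(unname(cv$mean["balanced_accuracy"]), 100)
  expect_equal(unname(cv$sd["balanced_accuracy"]), 0)

  # too few subjects in a class
  bad <- ft[ft$subject %in% c("s01", "s06", "s07"), ]
  expect_error(cross_validate(bad, kind = "knn", n_folds = 2, seed = 1),
    "subjects per class")
})

test_that("undefined fold metrics are excluded and counted", {
  # force a fold whose test windows are all low stress: with 5 low-stress
  # subjects and 1 high-stress subject over 3 folds, some folds have no
  # positive test case -> sensitivity undefined there
  ft <- separable_features()
  ft <- ft[ft$subject %in% c(sprintf("s%02d", 1:5), "s06", "s07"), ]
  cv <- cross_validate(ft, kind = "knn", n_folds = 3, seed = 71)
  expect_true(any(cv$n_undefined > 0))
  expect_false(any(is.na(cv$mean)))
})
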