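# Stress-level classification and evaluation: z-score normalization,
# confusion-matrix metrics (balanced accuracy, sensitivity, specificity,
# PPV, NPV, MCC), three classifiers (kNN, RBF-SVM, two-hidden-layer tanh
# ANN) and subject-grouped cross-validation.
#
# The positive class is the HIGHER stress level throughout.

POSITIVE_CLASS <- "high_stress"
NEGATIVE_CLASS <- "low_stress"

#' Z-score normalization fitted on training rows only
#'
#' Subtracts the training mean and divides by the training standard
#' deviation (sample SD, `n - 1` denominator) for every feature column;
#' the same fitted statistics are applied to the test rows, so no test
#' information leaks into the transform.
#'
#' @param train Numeric data.frame/matrix of training features (>= 2 rows).
#' @param test Optional test features with the same columns.
#' @return List with `train`, `test` (NULL if not supplied), `center` and
#'   `scale` (named per feature).
#' @export
zscore_normalize <- function(train, test = NULL) {
  train <- as.data.frame(train)
  if (nrow(train) < 2L) stop("need >= 2 training rows", call. = FALSE)
  ctr <- vapply(train, mean, 0)
  scl <- vapply(train, stats::sd, 0)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop("zero-variance feature(s): ",
      paste(names(train)[zero], collapse = ", "), call. = FALSE)
  }
  apply_z <- function(df) {
    as.data.frame(Map(function(col, m, s) (col - m) / s, df, ctr, scl),
      col.names = names(df))
  }
  list(
    train = apply_z(train),
    test = if (!is.null(test)) apply_z(as.data.frame(test)),
    center = ctr, scale = scl
  )
}

#' Binary-classification metrics from confusion counts
#'
#' Computes balanced accuracy (percent), sensitivity, specificity, positive
#' and negative predictive value, and the Matthews correlation coefficient.
#' A metric whose denominator is zero is reported as `NA_real_` (the
#' explicit undefined marker), never as an exception; balanced accuracy is
#' undefined whenever sensitivity or specificity is.
#'
#' @param TP,FP,TN,FN Non-negative integer counts, total > 0. TP counts
#'   cases correctly identified as the higher stress level.
#' @return A list of class `metrics_report`: `counts`, `balanced_accuracy`
#'   (percent), `sensitivity`, `specificity`, `ppv`, `npv`, `mcc`, and
#'   `undefined` (character vector of undefined metric names).
#' @examples
#' compute_metrics(TP = 3, FP = 2, TN = 4, FN = 1)
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all confusion counts are zero", call. = FALSE)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(TP, TP + FN)
  spec <- frac(TN, TN + FP)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else 50 * (sens + spec)
  ppv <- frac(TP, TP + FP)
  npv <- frac(TN, TN + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) NA_real_ else (TN * TP - FN * FP) / mcc_den
  out <- list(
    counts = counts,
    balanced_accuracy = ba, sensitivity = sens, specificity = spec,
    ppv = ppv, npv = npv, mcc = mcc
  )
  out$undefined <- names(which(vapply(
    out[c("balanced_accuracy", "sensitivity", "specificity",
      "ppv", "npv", "mcc")], is.na, TRUE)))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v, pct = FALSE) {
    if (is.na(v)) "undefined" else if (pct) sprintf("%.2f%%", v)
    else sprintf("%.4f", v)
  }
  cat("<metrics_report>  TP =", x$counts["TP"], " FP =", x$counts["FP"],
    " TN =", x$counts["TN"], " FN =", x$counts["FN"], "\n")
  cat("  Balanced accuracy:", fmt(x$balanced_accuracy, TRUE), "\n")
  cat("  Sensitivity:", fmt(x$sensitivity),
    " Specificity:", fmt(x$specificity), "\n")
  cat("  PPV:", fmt(x$ppv), " NPV:", fmt(x$npv),
    " MCC:", fmt(x$mcc), "\n")
  invisible(x)
}

# ---------------------------------------------------------------- kNN ----

knn_fit <- function(x, y, k = NULL, literal_k = FALSE) {
  n <- nrow(x)
  if (is.null(k)) {
    k <- if (literal_k) n else max(1L, 2L * (round(sqrt(n)) %/% 2L) + 1L)
  }
  structure(list(x = as.matrix(x), y = y, k = as.integer(min(k, n))),
    class = "cecg_knn")
}

#' @export
predict.cecg_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1L, function(row) {
    d <- sqrt(colSums((t(object$x) - row)^2))
    nb <- order(d)[seq_len(object$k)]
    votes <- table(object$y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else object$y[nb[1L]]  # tie -> nearest
  })
}

# ---------------------------------------------------------------- SVM ----

# Simplified SMO (Platt-style) for a soft-margin kernel SVM.
smo_fit <- function(K, y, C = 1, tol = 1e-3, max_passes = 10,
                    max_iter = 5000) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f <- function(i) sum(alpha * y * K[, i]) + b
  passes <- 0L
  iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- f(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-6) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2
          else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

svm_fit <- function(x, y, kernel = c("rbf", "linear"), C = 1, gamma = NULL,
                    seed = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)  # unit-scale on z-scored inputs
  yy <- ifelse(y == POSITIVE_CLASS, 1, -1)
  kmat <- function(a, b) {
    if (kernel == "linear") return(a %*% t(b))
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    exp(-gamma * pmax(d2, 0))
  }
  fit <- with_seed_or_here(seed, smo_fit(kmat(x, x), yy, C = C))
  structure(
    list(x = x, y = yy, alpha = fit$alpha, b = fit$b,
      kernel = kernel, gamma = gamma, kmat = kmat),
    class = "cecg_svm"
  )
}

#' @export
predict.cecg_svm <- function(object, newdata, ...) {
  K <- object$kmat(as.matrix(newdata), object$x)
  score <- as.numeric(K %*% (object$alpha * object$y)) + object$b
  ifelse(score >= 0, POSITIVE_CLASS, NEGATIVE_CLASS)
}

# ---------------------------------------------------------------- ANN ----

# Two-hidden-layer feed-forward network, tanh activations throughout,
# MSE loss on +-1 targets, full-batch backpropagation with learning
# rate 0.5, early stop on a training-loss plateau.
ann_fit <- function(x, y, hidden = c(20L, 20L), lr = 0.5, epochs = 500L,
                    seed = NULL, plateau_tol = 1e-7, plateau_patience = 25L) {
  x <- as.matrix(x)
  t_out <- ifelse(y == POSITIVE_CLASS, 1, -1)
  d <- ncol(x)
  sizes <- c(d, hidden, 1L)
  with_seed_or_here(seed, {
    W <- list(); B <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
        sizes[l], sizes[l + 1L])
      B[[l]] <- numeric(sizes[l + 1L])
    }
    n <- nrow(x)
    best <- Inf
    stale <- 0L
    loss_hist <- numeric(0)
    for (ep in seq_len(epochs)) {
      a1 <- tanh(sweep(x %*% W[[1]], 2, B[[1]], `+`))
      a2 <- tanh(sweep(a1 %*% W[[2]], 2, B[[2]], `+`))
      a3 <- tanh(sweep(a2 %*% W[[3]], 2, B[[3]], `+`))
      err <- as.numeric(a3) - t_out
      loss <- mean(err^2)
      loss_hist <- c(loss_hist, loss)
      if (loss < best - plateau_tol) {
        best <- loss; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= plateau_patience) break
      }
      d3 <- (2 / n) * err * (1 - as.numeric(a3)^2)
      d2 <- (d3 %o% as.numeric(W[[3]])) * (1 - a2^2)
      d1 <- (d2 %*% t(W[[2]])) * (1 - a1^2)
      W[[3]] <- W[[3]] - lr * t(a2) %*% d3
      B[[3]] <- B[[3]] - lr * sum(d3)
      W[[2]] <- W[[2]] - lr * t(a1) %*% d2
      B[[2]] <- B[[2]] - lr * colSums(d2)
      W[[1]] <- W[[1]] - lr * t(x) %*% d1
      B[[1]] <- B[[1]] - lr * colSums(d1)
    }
    structure(list(W = W, B = B, loss = loss_hist), class = "cecg_ann")
  })
}

#' @export
predict.cecg_ann <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  a1 <- tanh(sweep(x %*% object$W[[1]], 2, object$B[[1]], `+`))
  a2 <- tanh(sweep(a1 %*% object$W[[2]], 2, object$B[[2]], `+`))
  a3 <- tanh(sweep(a2 %*% object$W[[3]], 2, object$B[[3]], `+`))
  ifelse(as.numeric(a3) >= 0, POSITIVE_CLASS, NEGATIVE_CLASS)
}

# ----------------------------------------------------------- frontend ----

#' Train a stress classifier
#'
#' Three model families are available, all predicting
#' `"high_stress"`/`"low_stress"` from normalized features:
#' \describe{
#'   \item{knn}{Euclidean k-nearest neighbours; `k = round(sqrt(n))`
#'     forced odd by default (`literal_k = TRUE` instead sets
#'     `k = n_train`, which degenerates to the majority class).}
#'   \item{svm}{soft-margin kernel SVM solved by simplified SMO; RBF kernel
#'     with `gamma = 1/n_features` and `C = 1` by default
#'     (`kernel = "linear"` available).}
#'   \item{ann}{two-hidden-layer feed-forward network, 20 tanh units per
#'     hidden layer, MSE loss, full-batch backpropagation with learning
#'     rate 0.5, up to 500 epochs with early stop on a training-loss
#'     plateau; initialization is seed-controlled.}
#' }
#'
#' @param kind One of `"knn"`, `"svm"`, `"ann"`.
#' @param x Normalized numeric feature table (rows = windows).
#' @param y Character labels, both classes present.
#' @param seed Integer seed for stochastic trainers, or NULL.
#' @param k,literal_k kNN neighbourhood size and the literal `k = n_train`
#'   mode (ignored by the other families).
#' @param ... Extra parameters for the family (`kernel`, `C`, `gamma`;
#'   `hidden`, `lr`, `epochs`).
#' @return A fitted model with a `predict()` method returning labels.
#' @export
train_classifier <- function(kind = c("knn", "svm", "ann"), x, y,
                             seed = NULL, k = NULL, literal_k = FALSE, ...) {
  kind <- match.arg(kind)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (!all(y %in% c(POSITIVE_CLASS, NEGATIVE_CLASS))) {
    stop("labels must be 'high_stress'/'low_stress'", call. = FALSE)
  }
  switch(kind,
    knn = knn_fit(x, y, k = k, literal_k = literal_k),
    svm = svm_fit(x, y, seed = seed, ...),
    ann = ann_fit(x, y, seed = seed, ...)
  )
}

# Internal: confusion counts with positive class = high stress.
confusion_counts <- function(truth, pred) {
  c(
    TP = sum(truth == POSITIVE_CLASS & pred == POSITIVE_CLASS),
    FP = sum(truth == NEGATIVE_CLASS & pred == POSITIVE_CLASS),
    TN = sum(truth == NEGATIVE_CLASS & pred == NEGATIVE_CLASS),
    FN = sum(truth == POSITIVE_CLASS & pred == NEGATIVE_CLASS)
  )
}

# Internal: partition subjects into n_folds groups, spreading each class's
# subjects round-robin so every training set sees both classes.
make_subject_folds <- function(subjects, labels, n_folds, seed = NULL) {
  sub_lab <- tapply(as.character(labels), subjects, function(l) l[1])
  folds <- stats::setNames(integer(length(sub_lab)), names(sub_lab))
  with_seed_or_here(seed, {
    nxt <- 0L
    for (cls in unique(sub_lab)) {
      subs <- sample(names(sub_lab)[sub_lab == cls])
      for (s in subs) {
        folds[s] <- nxt %% n_folds + 1L
        nxt <- nxt + 1L
      }
    }
  })
  folds
}

#' Subject-grouped cross-validation
#'
#' Splits subjects (never windows) across `n_folds` folds, fits the
#' normalization and the classifier on the training folds only, predicts
#' the held-out subjects' windows, and aggregates the per-fold metrics as
#' mean and SD. Undefined per-fold metrics are excluded from the aggregate
#' and counted in `n_undefined`.
#'
#' @param features A `cecg_features` data.frame (columns `subject`,
#'   `label`, and the four feature columns).
#' @param kind Classifier family, see [train_classifier()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and trainers.
#' @param feature_cols Feature column names.
#' @param ... Passed to [train_classifier()].
#' @return A list of class `cv_result`: `fold_metrics` (list of
#'   `metrics_report`), `mean`, `sd`, `n_undefined` per metric, and
#'   `folds` (the subject-to-fold map).
#' @export
cross_validate <- function(features, kind = "ann", n_folds = 5, seed = NULL,
                           feature_cols = c("r_value_mv", "hr_bpm",
                             "pnn50", "binen"),
                           ...) {
  stopifnot(all(c("subject", "label", feature_cols) %in% names(features)))
  labels <- as.character(features$label)
  subjects <- as.character(features$subject)
  per_class_subjects <- tapply(subjects, labels, function(s) length(unique(s)))
  if (any(per_class_subjects < 2)) {
    stop("need >= 2 subjects per class for a grouped split; got ",
      paste(names(per_class_subjects), per_class_subjects,
        sep = ": ", collapse = ", "), call. = FALSE)
  }
  folds <- make_subject_folds(subjects, labels, n_folds, seed)
  xmat <- features[, feature_cols, drop = FALSE]
  fold_metrics <- list()
  for (f in sort(unique(folds))) {
    test_rows <- folds[subjects] == f
    if (!any(test_rows) || all(test_rows)) next
    norm <- zscore_normalize(xmat[!test_rows, , drop = FALSE],
      xmat[test_rows, , drop = FALSE])
    model <- train_classifier(kind, norm$train, labels[!test_rows],
      seed = if (is.null(seed)) NULL else seed + f, ...)
    pred <- predict(model, norm$test)
    cc <- confusion_counts(labels[test_rows], pred)
    fold_metrics[[length(fold_metrics) + 1L]] <-
      do.call(compute_metrics, as.list(cc))
  }
  metric_names <- c("balanced_accuracy", "sensitivity", "specificity",
    "ppv", "npv", "mcc")
  vals <- sapply(metric_names, function(m)
    vapply(fold_metrics, function(r) r[[m]], 0))
  vals <- matrix(vals, nrow = length(fold_metrics),
    dimnames = list(NULL, metric_names))
  structure(
    list(
      kind = kind,
      fold_metrics = fold_metrics,
      mean = apply(vals, 2, mean, na.rm = TRUE),
      sd = apply(vals, 2, stats::sd, na.rm = TRUE),
      n_undefined = colSums(is.na(vals)),
      folds = folds
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds (subject-grouped)\n",
    x$kind, length(x$fold_metrics)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-18s %8.3f +- %.3f%s\n", m, x$mean[m],
      ifelse(is.na(x$sd[m]), 0, x$sd[m]),
      if (x$n_undefined[m] > 0)
        sprintf("  (%d undefined fold[s] excluded)", x$n_undefined[m])
      else ""))
  }
  invisible(x)
}
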