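## Downstream heads on embeddings (SVM, gradient-boosted trees),
## confusion-matrix evaluation, balanced accuracy (unweighted mean of
## per-class recalls), per-class report tables, and 2-D projections.

#' Train a classical head on an embedding table
#'
#' @param emb embedding matrix, rownames = compound ids.
#' @param labels integer labels (0/1/2), either aligned with `emb`'s rows
#'   or named by id.
#' @param kind `"svm"` (RBF kernel with probability estimates) or `"gbt"`
#'   (gradient-boosted trees, 200 rounds, depth 6 — the workflow fixes no
#'   head hyperparameters, so these defaults are recorded in the object).
#' @param seed integer seed; training is deterministic given it.
#' @return object of class `"origin_head"` with a [predict] method
#'   returning a 3-column probability matrix.
#' @export
train_head <- function(emb, labels, kind = c("svm", "gbt"), seed = 1) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(emb), nrow(emb) >= 2)
  if (!is.null(names(labels))) labels <- labels[rownames(emb)]
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(emb), !anyNA(labels))
  if (length(unique(labels)) < 2)
    stop("head training needs at least two classes present", call. = FALSE)
  model <- if (kind == "svm") {
    with_seed(derive_seed(seed, "svm-head"),
              e1071::svm(x = emb, y = factor(labels, levels = 0:2),
                         kernel = "radial", probability = TRUE,
                         scale = FALSE))
  } else {
    dtrain <- xgboost::xgb.DMatrix(emb, label = labels)
    params <- list(objective = "multi:softprob", num_class = 3,
                   max_depth = 6, eta = 0.3, nthread = 1,
                   seed = derive_seed(seed, "gbt-head"))
    xgboost::xgb.train(params = params, data = dtrain, nrounds = 200)
  }
  structure(list(kind = kind, model = model, seed = seed,
                 hyper = if (kind == "gbt")
                   list(nrounds = 200, max_depth = 6, eta = 0.3)
                 else list(kernel = "radial")),
            class = "origin_head")
}

#' @export
print.origin_head <- function(x, ...) {
  cat("<origin_head>", x$kind, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' @rdname train_head
#' @param object an `"origin_head"`.
#' @param newdata embedding matrix to score.
#' @param ... ignored.
#' @export
predict.origin_head <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  P <- if (object$kind == "svm") {
    pr <- predict(object$model, newdata, probability = TRUE)
    probs <- attr(pr, "probabilities")
    out <- matrix(0, nrow(newdata), 3, dimnames = list(rownames(newdata),
                                                       c("0", "1", "2")))
    out[, colnames(probs)] <- probs
    out
  } else {
    out <- predict(object$model, xgboost::xgb.DMatrix(newdata))
    dimnames(out) <- list(rownames(newdata), c("0", "1", "2"))
    out
  }
  P
}

#' Confusion matrix of true vs predicted kingdom labels
#'
#' @param truth,pred equal-length integer vectors with values in 0..2;
#'   rows of the matrix are true classes, columns predictions.
#' @return 3x3 integer matrix of class `"origin_confusion"`.
#' @export
confusion <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred))
    stop("truth and pred differ in length (", length(truth), " vs ",
         length(pred), ")", call. = FALSE)
  stopifnot(all(truth %in% 0:2), all(pred %in% 0:2))
  cm <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  m <- matrix(as.integer(cm), 3, 3,
              dimnames = list(true = c("0", "1", "2"),
                              pred = c("0", "1", "2")))
  structure(m, class = c("origin_confusion", "matrix"))
}

#' @export
print.origin_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  m <- unclass(x)
  dimnames(m) <- list(true = KINGDOM_LABELS, pred = KINGDOM_LABELS)
  print(m)
  invisible(x)
}

#' Balanced accuracy
#'
#' The unweighted mean of per-class recalls,
#' `1/N * sum_i TP_i / (TP_i + FN_i)` with `N = 3` classes, reported as a
#' percentage. Invariant to class-size rebalancing that preserves each
#' class's recall. Exactly this recall form — no chance-corrected variant.
#'
#' @param cm an `"origin_confusion"` matrix (or any 3x3 count matrix with
#'   true classes in rows).
#' @return balanced accuracy in percent.
#' @export
balanced_accuracy <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == 3, ncol(m) == 3, all(m >= 0))
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("class ", paste(KINGDOM_LABELS[totals == 0], collapse = ", "),
         " has no evaluated samples", call. = FALSE)
  100 * mean(diag(m) / totals)
}

#' Per-class report table
#'
#' Row-normalizes the confusion matrix into per-class accuracy and the two
#' misclassification rates, in percent, half-up rounded to two decimals —
#' so each class's three percentages sum to 100 within rounding (+/- 0.02).
#'
#' @param cm an `"origin_confusion"` matrix.
#' @return list with `per_class` (data frame: class, accuracy, and the two
#'   `to_*` misclassification percentages) and `balanced_accuracy`
#'   (half-up, two decimals).
#' @export
table_report <- function(cm) {
  m <- unclass(cm)
  stopifnot(is.matrix(m), nrow(m) == 3, ncol(m) == 3)
  pct <- round_half_up(100 * m / rowSums(m), 2)
  df <- data.frame(class = unname(KINGDOM_LABELS),
                   accuracy = diag(pct),
                   stringsAsFactors = FALSE)
  for (j in 1:3) df[[paste0("to_", KINGDOM_LABELS[j])]] <- pct[, j]
  for (i in 1:3) df[i, paste0("to_", KINGDOM_LABELS[i])] <- NA_real_
  rownames(df) <- NULL
  list(per_class = df,
       balanced_accuracy = round_half_up(balanced_accuracy(cm), 2))
}

#' Published per-class benchmark accuracies
#'
#' Per-class accuracies and misclassification rates (percent) of nine
#' origin-classification model configurations — a message-passing graph
#' classifier and SVM / gradient-boosted heads on its last-FFN embeddings,
#' each under raw, two-step-cleaned, and microbially pretrained + cleaned
#' training regimes — evaluated on a curated marine natural product test
#' set. Useful as a reference point for the evaluation arithmetic: each
#' row's balanced accuracy is the unweighted mean of its three per-class
#' accuracies, and each class's accuracy plus its two misclassification
#' rates sums to 100 within rounding.
#'
#' @return data frame with one row per model configuration.
#' @export
benchmark_models <- function() {
  read.csv(system.file("extdata", "benchmark_models.csv",
                       package = "mnporigin"),
           stringsAsFactors = FALSE)
}

## exact (dense) t-SNE, adequate for desk-scale n; deterministic given seed
.tsne_exact <- function(X, seed, perplexity = 30, iters = 300, eta = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, max(1, floor((n - 1) / 3)))
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), 1e-12)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- Y * 0
    for (it in seq_len(iters)) {
      ex <- if (it <= 50) 4 else 1      # early exaggeration
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * Y %*% t(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      inc <- 0.8 * inc - eta * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Project embeddings to two dimensions
#'
#' @param emb embedding matrix (>= 3 rows), rownames = ids.
#' @param method `"pca"` or `"tsne"` (exact t-SNE, suited to desk-scale n).
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity (default 30, clamped for small n).
#' @return n x 2 coordinate matrix with `emb`'s rownames.
#' @export
project_2d <- function(emb, method = c("pca", "tsne"), seed = 1,
                       perplexity = 30) {
  method <- match.arg(method)
  stopifnot(is.matrix(emb), nrow(emb) >= 3)
  Y <- if (method == "pca") {
    pc <- prcomp(emb, center = TRUE, rank. = 2)
    sc <- pc$x
    if (ncol(sc) < 2) sc <- cbind(sc, 0)
    sc[, 1:2, drop = FALSE]
  } else {
    .tsne_exact(emb, derive_seed(seed, "tsne"), perplexity)
  }
  dimnames(Y) <- list(rownames(emb), c("dim1", "dim2"))
  Y
}
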