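test_that("confusion counts are exact and validated", {
  cm <- confusion(c(0, 1, 2), c(1, 1, 2))
  expect_identical(cm["0", "1"], 1L)
  expect_identical(cm["1", "1"], 1L)
  expect_identical(cm["2", "2"], 1L)
  expect_identical(sum(cm), 3L)
  perfect <- confusion(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_identical(sum(unclass(perfect)) , sum(diag(unclass(perfect))))
  expect_error(confusion(c(0, 1), c(0, 1, 2)), "length")
  ## brute-force tally on random pairs
  set.seed(31)
  truth <- sample(0:2, 50, replace = TRUE)
  pred <- sample(0:2, 50, replace = TRUE)
  cm2 <- confusion(truth, pred)
  for (i in 0:2) for (j in 0:2)
    expect_identical(cm2[as.character(i), as.character(j)],
                     sum(truth == i & pred == j))
})

test_that("balanced accuracy is the unweighted mean of per-class recalls", {
  perfect <- confusion(rep(0:2, 10), rep(0:2, 10))
  expect_equal(balanced_accuracy(perfect), 100)
  ## invariance to class-size rebalancing preserving recalls
  m1 <- matrix(c(8, 1, 1, 2, 6, 2, 1, 1, 8), 3, byrow = TRUE)
  m2 <- m1 * c(10, 1, 3)   # scale rows
  expect_equal(balanced_accuracy(m1), balanced_accuracy(m2))
  ## closed form for one-class-perfect, rest fixed
  m3 <- matrix(c(10, 0, 0, 3, 5, 2, 2, 2, 6), 3, byrow = TRUE)
  expect_equal(balanced_accuracy(m3), 100 * mean(c(1, 0.5, 0.6)))
  empty <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(balanced_accuracy(empty), "Bacteria")
})

test_that("report rows reconstruct row-normalized percentages summing to 100", {
  diagm <- confusion(rep(0:2, 5), rep(0:2, 5))
  rep <- table_report(diagm)
  expect_equal(rep$per_class$accuracy, rep(100, 3))
  expect_equal(rep$balanced_accuracy, 100)
  cm <- confusion(rep(0, 100), rep(0, 100))
  cm["0", ] <- c(80L, 12L, 8L); cm["1", ] <- c(1L, 1L, 1L)
  cm["2", ] <- c(1L, 1L, 1L)
  r <- table_report(cm)
  expect_equal(r$per_class$accuracy[1], 80)
  expect_equal(r$per_class$to_Bacteria[1], 12)
  expect_equal(r$per_class$to_Fungi[1], 8)
  ## property: rows sum to 100 +/- 0.02 on random matrices
  set.seed(7)
  for (i in 1:100) {
    m <- matrix(sample(1:500, 9, replace = TRUE), 3)
    rr <- table_report(structure(m, class = c("origin_confusion", "matrix")))
    df <- rr$per_class
    sums <- df$accuracy +
      rowSums(cbind(df$to_Animalia, df$to_Bacteria, df$to_Fungi),
              na.rm = TRUE)
    expect_true(all(abs(sums - 100) <= 0.02))
  }
})

test_that("classical heads learn embeddings, deterministically", {
  ## linearly separable toy embedding
  emb <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2),
               matrix(rnorm(40, -6), 20, 2))
  rownames(emb) <- paste0("c", 1:60)
  y <- rep(0:2, each = 20)
  for (kind in c("svm", "gbt")) {
    h <- train_head(emb, y, kind = kind, seed = 3)
    p <- predict(h, emb)
    expect_identical(dim(p), c(60L, 3L))
    expect_equal(mean(max.col(p) - 1L == y), 1)
    h2 <- train_head(emb, y, kind = kind, seed = 3)
    expect_identical(predict(h2, emb), p)
  }
  expect_error(train_head(emb, rep(0, 60), kind = "svm"), "two classes")
})

test_that("heads on last_ffn embeddings beat the majority-class rate out of sample", {
  m <- small_model()
  ds <- small_dataset()
  emb <- extract_embeddings(m, ds, "last_ffn", feats = small_feats())
  test <- generate_dataset(synthetic_spec(20, 10, 10, seed = 77,
                                          id_prefix = "t_"))
  emb_te <- extract_embeddings(m, test, "last_ffn")
  majority <- max(class_counts(test)) / length(test)
  for (kind in c("svm", "gbt")) {
    h <- train_head(emb, ds$records$label, kind = kind, seed = 1)
    acc <- mean(max.col(predict(h, emb_te)) - 1L == test$records$label)
    expect_gt(acc, majority)
  }
})

test_that("2-D projections are sized, seeded, and PCA preserves collinearity", {
  emb <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(paste0("e", 1:40), NULL))
  for (method in c("pca", "tsne")) {
    y <- project_2d(emb, method = method, seed = 4)
    expect_identical(dim(y), c(40L, 2L))
    expect_identical(rownames(y), rownames(emb))
    expect_identical(project_2d(emb, method = method, seed = 4), y)
  }
  line <- outer(seq_len(10), c(1, 2, 3))   # collinear points
  rownames(line) <- paste0("l", 1:10)
  yl <- project_2d(line, method = "pca")
  expect_equal(unname(yl[, 2]), rep(0, 10), tolerance = 1e-8)
})

test_that("published benchmark rows obey the evaluation arithmetic", {
  bm <- benchmark_models()
  expect_identical(nrow(bm), 9L)
  recomputed <- floor(rowMeans(bm[c("ani_acc", "bac_acc", "fun_acc")]) * 100 +
                        0.5) / 100
  expect_equal(recomputed, bm$balanced_acc)
})
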