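test_that("oracle-driven screening recovers exactly the planted flips", {
  ds <- study_dataset()
  truth <- setNames(ds$records$true_label, ds$records$id)
  nz <- inject_label_noise(ds, 0.08, seed = 2)
  rep <- cross_prediction_screen(nz$dataset, oracle_trainer(truth),
                                 cycles = 10, subset_fraction = 0.5,
                                 seed = 4)
  expect_identical(rep$step1_flagged, nz$flipped)
  ## microbial compounds never appear in the flag set
  micro <- ds$records$id[nz$dataset$records$label != 0L]
  expect_length(intersect(rep$step1_flagged, micro), 0)
  ## noise-free data yields zero flags
  rep0 <- cross_prediction_screen(ds, oracle_trainer(truth),
                                  cycles = 10, subset_fraction = 0.5,
                                  seed = 4)
  expect_length(rep0$step1_flagged, 0)
})

test_that("screening guarantees OOF coverage, logs simplex probabilities, and is seeded", {
  ds <- small_dataset()
  truth <- setNames(ds$records$true_label, ds$records$id)
  rep <- cross_prediction_screen(ds, oracle_trainer(truth), cycles = 5,
                                 subset_fraction = 0.5, seed = 6)
  ani <- ds$records$id[ds$records$label == 0L]
  expect_setequal(unique(rep$oof_log$id), ani)      # every Animalia >= 1 OOF
  expect_true(all(rep$mean_confidence$n_oof >= 1))
  expect_equal(rowSums(rep$oof_log[c("p0", "p1", "p2")]),
               rep(1, nrow(rep$oof_log)), tolerance = 1e-9)
  rep2 <- cross_prediction_screen(ds, oracle_trainer(truth), cycles = 5,
                                  subset_fraction = 0.5, seed = 6)
  expect_identical(rep$oof_log, rep2$oof_log)
  ## infeasible coverage names the minimal cycle count
  expect_error(
    cross_prediction_screen(ds, oracle_trainer(truth), cycles = 2,
                            subset_fraction = 0.9, seed = 1),
    "at least")
  expect_error(
    cross_prediction_screen(ds, oracle_trainer(truth), cycles = 0), ">= 1")
  expect_error(
    cross_prediction_screen(ds, oracle_trainer(truth), subset_fraction = 1),
    "strictly between")
})

test_that("neighborhood filter equals the brute-force predicate on random instances", {
  set.seed(17)
  for (trial in 1:30) {
    n <- sample(10:500, 1)
    d <- sample(c(2, 3, 8, 16), 1)
    emb <- matrix(rnorm(n * d, sd = 2), n, d,
                  dimnames = list(paste0("p", seq_len(n)), NULL))
    labels <- setNames(sample(0:2, n, replace = TRUE), rownames(emb))
    radius <- runif(1, 0, 3)
    expect_identical(neighborhood_filter(emb, labels, radius),
                     brute_force_removed(emb, labels, radius))
  }
})

test_that("neighborhood filter edge cases: strict inequality, no microbial, empty", {
  emb <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  labels <- c(a = 0L, b = 1L)
  expect_length(neighborhood_filter(emb, labels, 0), 0)
  expect_identical(neighborhood_filter(emb, labels, 1), character(0)) # d == r
  expect_identical(neighborhood_filter(emb, labels, 1.01), "a")
  all_ani <- c(a = 0L, b = 0L)
  expect_length(neighborhood_filter(emb, all_ani, 10), 0)
  expect_length(neighborhood_filter(emb[0, , drop = FALSE], labels, 5), 0)
})

test_that("removed set is non-decreasing in radius", {
  set.seed(23)
  emb <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(paste0("p", 1:200), NULL))
  labels <- setNames(sample(0:2, 200, replace = TRUE), rownames(emb))
  radii <- sort(runif(8, 0, 3))
  prev <- character(0)
  for (r in radii) {
    cur <- neighborhood_filter(emb, labels, r)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("auto radius uses the distance-distribution quantile", {
  set.seed(5)
  emb <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(paste0("p", 1:60), NULL))
  labels <- setNames(rep(0:2, 20), rownames(emb))
  r <- as.numeric(quantile(dist(emb), 0.01))
  expect_identical(neighborhood_filter(emb, labels, "auto"),
                   neighborhood_filter(emb, labels, r))
})

test_that("applying a cleaning report removes the union and validates ids", {
  ds <- study_dataset()
  ids <- ds$records$id[ds$records$label == 0L]
  rep <- cleaning_report(step1_flagged = ids[1:5], step2_removed = ids[6:8])
  out <- apply_cleaning(ds, rep)
  expect_length(out, length(ds) - 8L)
  ## empty report leaves the dataset identical
  none <- cleaning_report(character(0))
  expect_identical(apply_cleaning(ds, none)$records, ds$records)
  ## microbial records untouched
  micro_before <- ds$records[ds$records$label != 0L, ]
  micro_after <- out$records[out$records$label != 0L, ]
  rownames(micro_before) <- rownames(micro_after) <- NULL
  expect_identical(micro_after, micro_before)
  bad <- cleaning_report(step1_flagged = "nope")
  expect_error(apply_cleaning(ds, bad), "unknown id")
  expect_error(cleaning_report(ids[1:3], step2_removed = ids[2:4]),
               "disjoint")
})
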