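test_that("featurization encodes atoms, directed edges and aromaticity", {
  f <- featurize("CC")
  expect_identical(f$n_atoms, 2L)
  expect_length(f$src, 2)                    # one bond, two directions
  benz <- featurize("c1ccccc1")
  expect_identical(benz$n_atoms, 6L)
  expect_length(benz$src, 12)
  expect_identical(sum(benz$x[, 18]), 6)     # aromatic flag on every atom
  expect_true(all(benz$e[, 4] == 1))
  meth <- featurize("C")
  expect_identical(meth$n_atoms, 1L)
  expect_length(meth$src, 0)                 # degenerate but encodable
  expect_identical(f$rev, c(2L, 1L))
})

test_that("encoder output is deterministic and invariant to atom reordering", {
  m <- small_model()
  e1 <- predict(m, c(x = "OCCc1ccccc1"), type = "mpn")
  e2 <- predict(m, c(x = "c1ccccc1CCO"), type = "mpn")
  expect_equal(unname(e1), unname(e2))
  expect_identical(predict(m, c(x = "CCO"), type = "mpn"),
                   predict(m, c(x = "CCO"), type = "mpn"))
  ## seeded init: two from-scratch fits agree bitwise
  cfg <- tiny_config(seed = 21, epochs = 2)
  ds <- small_dataset()[1:20]
  m1 <- mnp_mpnn(ds, cfg)
  m2 <- mnp_mpnn(ds, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("forward pass yields a probability simplex and sized embeddings", {
  m <- small_model()
  ds <- small_dataset()[1:10]
  p <- predict(m, ds, type = "prob", feats = small_feats())
  expect_identical(dim(p), c(10L, 3L))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-6)
  lf <- predict(m, ds, type = "last_ffn", feats = small_feats())
  expect_identical(ncol(lf), m$config$ffn_hidden)
  mp <- extract_embeddings(m, ds, "mpn", feats = small_feats())
  expect_identical(ncol(mp), m$config$hidden_dim)
  expect_identical(attr(mp, "kind"), "mpn")
  expect_true(all(is.finite(lf)))
})

test_that("training reduces the loss on separable data", {
  m <- small_model()
  expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
})

test_that("pretraining combines Animalia with an equal-sized seeded microbial sample", {
  ds <- small_dataset()
  ani <- ds[ds$records$id[ds$records$label == 0L]]
  pool <- generate_dataset(synthetic_spec(0, 40, 40, seed = 8,
                                          id_prefix = "p_"))
  cfg <- tiny_config(seed = 2, epochs = 2)
  m1 <- pretrain(ani, pool, cfg)
  expect_identical(m1$n_train, 2L * length(ani))
  m2 <- pretrain(ani, pool, cfg)
  expect_identical(m1$pretrain_microbial_ids, m2$pretrain_microbial_ids)
  ## pool smaller than the Animalia set: use it all, with a warning
  tiny_pool <- pool[1:10]
  expect_warning(m3 <- pretrain(ani, tiny_pool, cfg), "smaller")
  expect_identical(m3$n_train, length(ani) + 10L)
  expect_error(pretrain(ani[integer(0)], pool, cfg), "non-empty")
})

test_that("fine-tuning freezes the encoder bitwise across epochs and updates the head", {
  base <- small_model()
  other <- generate_dataset(synthetic_spec(20, 10, 10, seed = 31,
                                           id_prefix = "o_"))
  ft <- finetune(base, other, config = tiny_config(seed = 9, epochs = 12))
  expect_identical(ft$params$W_i, base$params$W_i)
  expect_identical(ft$params$W_h, base$params$W_h)
  expect_identical(ft$params$W_o, base$params$W_o)
  expect_false(identical(ft$params$W_out, base$params$W_out))
  ## frozen fine-tune still learns the separable classes head-only
  acc <- mean(predict(ft, other, type = "class") == other$records$label)
  expect_gte(acc, 0.8)
})

test_that("map4like fingerprint honours dims, equivalence and degenerate input", {
  expect_identical(map4like_fp("OCC"), map4like_fp("CCO"))
  expect_length(map4like_fp("CCO", dims = 512), 512)
  single <- map4like_fp("C")
  expect_length(single, 1024)
  expect_true(all(is.finite(single)))
  expect_false(identical(map4like_fp("CCO"), map4like_fp("CCN")))
})

test_that("model methods print, summarize, and expose coefficients", {
  m <- small_model()
  expect_output(print(m), "mnp_mpnn")
  expect_output(summary(m), "message steps")
  expect_named(coef(m), c("W_i", "W_h", "W_o", "W_f", "b_f", "W_out",
                          "b_out"))
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(m); grDevices::dev.off()
  expect_true(file.exists(tf))
})
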