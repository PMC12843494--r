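test_that("canonicalization maps alternative writings to one form and is idempotent", {
  alt <- c("OCC", "C(C)O", "C(O)C")
  can <- canonicalize_smiles(alt)
  expect_length(unique(can), 1)
  expect_identical(canonicalize_smiles("CCO"), "CCO")
  expect_identical(canonicalize_smiles(can), can)
  ## round-trip invariance on a generated set of rewritings
  forms <- list(c("c1ccccc1C", "Cc1ccccc1"),
                c("N#Cc1ccccc1", "c1ccccc1C#N"),
                c("CC(=O)OC", "COC(C)=O"))
  for (f in forms) expect_length(unique(canonicalize_smiles(f)), 1)
})

test_that("malformed SMILES raise structured parse errors naming the input", {
  expect_error(canonicalize_smiles("C("), "C\\(")
  expect_error(canonicalize_smiles("C1CC"), "unparseable")
  expect_false(any(smiles_is_valid(c("", "C(", "C1CC", "[Xx]", "C=(C)"))))
  expect_true(all(smiles_is_valid(c("CCO", "c1ccccc1", "C/C=C/C",
                                    "CC(=O)[O-]", "[nH]1cccc1"))))
  ## lenient mode yields NA instead
  expect_identical(canonicalize_smiles(c("CCO", "C("), strict = FALSE)[2],
                   NA_character_)
})

test_that("salts reduce to the largest covalent fragment", {
  expect_identical(canonicalize_smiles("[Na+].CC(=O)[O-]"),
                   canonicalize_smiles("CC(=O)[O-]"))
})

test_that("dataset construction enforces unique ids and the 3-class scheme", {
  expect_error(mnp_dataset(c("a", "a"), c("C", "CC"), c(0, 1)), "duplicate")
  expect_error(mnp_dataset(c("a", "b"), c("C", "CC"), c(0, 3)),
               "\\{0, 1, 2\\}")
  ds <- mnp_dataset(c("a", "b", "c", "d"), c("C", "CC", "CCC", "CCCC"),
                    c(0, 0, 1, 2))
  expect_identical(class_counts(ds), c(`0` = 2L, `1` = 1L, `2` = 1L))
  expect_identical(sum(class_counts(ds)), length(ds))
  empty <- ds[integer(0)]
  expect_identical(class_counts(empty), c(`0` = 0L, `1` = 0L, `2` = 0L))
})

test_that("lenient loading drops invalid structures; strict mode raises", {
  expect_message(
    ds <- mnp_dataset(c("a", "b"), c("CCO", "C("), c(0, 1), strict = FALSE),
    "1 record")
  expect_identical(ds$records$id, "a")
  expect_error(mnp_dataset(c("a", "b"), c("CCO", "C("), c(0, 1),
                           strict = TRUE), "unparseable")
})

test_that("CSV round-trip reproduces ids, labels and canonical SMILES", {
  ds <- small_dataset()
  tf <- tempfile(fileext = ".csv")
  write_dataset(ds, tf)
  back <- load_dataset(tf)
  expect_identical(back$records$id, ds$records$id)
  expect_identical(back$records$label, ds$records$label)
  expect_identical(back$records$smiles, ds$records$smiles)
})

test_that("CSV loader validates schema and labels", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("x", "x"), smiles = c("C", "CC"),
                       label = c(0, 1)), tf, row.names = FALSE)
  expect_error(load_dataset(tf), "duplicate")
  write.csv(data.frame(id = c("x", "y"), smiles = c("C", "CC"),
                       label = c(0, 3)), tf, row.names = FALSE)
  expect_error(load_dataset(tf), "\\{0, 1, 2\\}")
  write.csv(data.frame(id = "x", structure = "C"), tf, row.names = FALSE)
  expect_error(load_dataset(tf), "missing")
})

test_that(".smi input with sidecar labels loads", {
  smi <- tempfile(fileext = ".smi")
  lab <- tempfile(fileext = ".csv")
  writeLines(c("CCO\tm1", "c1ccccc1\tm2"), smi)
  write.csv(data.frame(id = c("m1", "m2"), label = c(0, 2)), lab,
            row.names = FALSE)
  ds <- load_dataset(smi, labels = lab)
  expect_identical(ds$records$label, c(0L, 2L))
  expect_error(load_dataset(smi), "sidecar")
})
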