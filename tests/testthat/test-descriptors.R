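test_that("physchem profile matches hand-derived values for small molecules", {
  ds <- mnp_dataset(c("eth", "benz"), c("CCO", "c1ccccc1"), c(0, 1))
  p <- physchem_profile(ds)
  ## ethanol: C2H6O from standard atomic masses; one O-H donor, one O acceptor
  expect_equal(p$MW[1], 46.07, tolerance = 1e-3)
  expect_identical(p$HBD[1], 1L)
  expect_identical(p$HBA[1], 1L)
  ## benzene: no acyclic single bonds
  expect_identical(p$RotB[2], 0L)
  expect_true(all(p$MW > 0))
  expect_true(all(p[c("HBD", "HBA", "RotB")] >= 0))
})

test_that("Murcko scaffolds keep rings and linkers, drop side chains", {
  expect_identical(murcko_scaffold("CCc1ccccc1"),
                   canonicalize_smiles("c1ccccc1"))
  expect_identical(murcko_scaffold("CCO"), "")
  biphenyl <- canonicalize_smiles("c1ccc(-c2ccccc2)cc1")
  expect_identical(murcko_scaffold(biphenyl), biphenyl)
  ## idempotence on a mixed batch
  smi <- c("CCc1ccccc1", "CC1CCCCC1=O", "c1ccc(CCc2ccncc2)cc1",
           "CC(C)C1CCC2CCCCC2C1")
  s1 <- murcko_scaffold(smi)
  expect_identical(murcko_scaffold(s1[nzchar(s1)]), s1[nzchar(s1)])
})

test_that("Morgan fingerprints are SMILES-form invariant with bounded popcount", {
  expect_identical(morgan_fp("OCC"), morgan_fp("CCO"))
  expect_identical(morgan_fp("c1ccccc1C"), morgan_fp("Cc1ccccc1"))
  fp <- morgan_fp("C")
  expect_length(fp, 1024)
  expect_gte(sum(fp), 1)
  expect_lte(sum(morgan_fp("CC1CCC2CCCCC2C1")), 1024)
  expect_length(morgan_fp("CCO", nbits = 256), 256)
})

test_that("fingerprint clustering is seeded, clamps k, and errors when k > n", {
  smi <- c("CCO", "CCCO", "c1ccccc1", "c1ccncc1", "CC(=O)OC", "CCC(=O)OC",
           "CC1CCCCC1", "C1CCNCC1", "CCCCC", "CC(C)CC")
  fps <- morgan_fp(setNames(smi, paste0("m", 1:10)))
  a1 <- cluster_fingerprints(fps, pca_dims = 5, k = 3, seed = 9)
  a2 <- cluster_fingerprints(fps, pca_dims = 5, k = 3, seed = 9)
  expect_identical(a1$cluster, a2$cluster)
  expect_length(unique(a1$cluster), 3)
  expect_true(all(a1$cluster %in% 0:2))
  ## duplicated points land in one cluster
  dup <- fps[c(1, 1, 1, 3, 3, 5), ]
  rownames(dup) <- paste0("d", 1:6)
  ad <- suppressWarnings(cluster_fingerprints(dup, pca_dims = 2, k = 3,
                                              seed = 1))
  expect_length(unique(ad$cluster[1:3]), 1)
  expect_error(cluster_fingerprints(fps, k = 11), "k = 5")
  expect_warning(cluster_fingerprints(fps, pca_dims = 5, k = 8, seed = 1),
                 "clamped")
})

test_that("Venn regions are exact on brute-force enumeration and conserve the union", {
  counts <- overlap_counts(list(`0` = c("a", "b"), `1` = c("b", "c"),
                                `2` = c("c")))
  expect_identical(counts[["0"]], 1L)     # {a}
  expect_identical(counts[["01"]], 1L)    # {b}
  expect_identical(counts[["12"]], 1L)    # {c}
  expect_identical(sum(counts), 3L)
  disjoint <- overlap_counts(list(`0` = "a", `1` = "b", `2` = "c"))
  expect_true(all(disjoint[c("01", "02", "12", "012")] == 0))
  same <- overlap_counts(list(`0` = c("x", "y"), `1` = c("x", "y"),
                              `2` = c("x", "y")))
  expect_identical(same[["012"]], 2L)
  expect_identical(sum(same), 2L)
  ## random property: counts sum to |union|
  set.seed(4)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(0:15, 1)))
    names(sets) <- c("0", "1", "2")
    expect_identical(sum(overlap_counts(sets)),
                     length(unique(unlist(sets))))
  }
})

test_that("top scaffolds rank by count with lexicographic ties, excluding ring-free", {
  smi <- c("CCc1ccccc1", "CCCc1ccccc1", "Cc1ccccc1",   # benzene scaffold x3
           "CCc1ccncc1", "Cc1ccncc1",                  # pyridine x2
           "CCO")                                      # no ring
  ds <- mnp_dataset(paste0("m", 1:6), smi, rep(0, 6))
  top <- top_scaffolds(ds, n = 20)
  expect_identical(nrow(top[["0"]]), 2L)
  expect_identical(top[["0"]]$count, c(3L, 2L))
  expect_identical(top[["0"]]$scaffold[1], canonicalize_smiles("c1ccccc1"))
  ## single shared scaffold
  one <- mnp_dataset(paste0("x", 1:3),
                     c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"),
                     rep(1, 3))
  t1 <- top_scaffolds(one)
  expect_identical(nrow(t1[["1"]]), 1L)
  expect_identical(t1[["1"]]$count, 3L)
})
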