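## toy scorer: class-1 probability is 1 when the substructure contains
## nitrogen, else 0
nitrogen_scorer <- function(smi) c(0, as.numeric(grepl("n|N", smi)), 0)

test_that("rationales match the exhaustive subgraph oracle under the nitrogen scorer", {
  parent <- "CCCCc1ccncc1"
  cfg <- mcts_config(rollouts = 30, min_atoms = 6, max_atoms = 20,
                     prop_delta = 0.5, seed = 1)
  r <- mcts_rationales(nitrogen_scorer, parent, target_class = 1, cfg)
  expect_gt(nrow(r), 0)
  g <- mol_graph(parent)
  qualifying <- enumerate_connected(g, 6)
  qualifying <- Filter(function(s) "N" %in% g$elem[s], qualifying)
  keys <- vapply(qualifying, function(s) paste(sort(s), collapse = ","),
                 character(1))
  got <- vapply(r$atoms, paste, character(1), collapse = ",")
  ## every returned rationale is in the enumerated qualifying set,
  ## hence contains the pyridine nitrogen
  expect_true(all(got %in% keys))
  expect_true(all(grepl("n|N", r$smiles)))
  expect_true(all(r$score >= cfg$prop_delta))
  expect_true(all(r$n_atoms >= 6 & r$n_atoms <= 20))
})

test_that("rationale atom sets induce connected subgraphs that re-parse", {
  cfg <- mcts_config(rollouts = 25, min_atoms = 5, max_atoms = 20)
  parent <- "CC(C)Cc1ccc2[nH]ccc2c1"
  r <- mcts_rationales(function(s) c(0.2, 0.7, 0.1), parent, 1, cfg)
  g <- mol_graph(parent)
  for (i in seq_len(nrow(r))) {
    atoms <- r$atoms[[i]]
    sub <- g$bonds[g$bonds$a1 %in% atoms & g$bonds$a2 %in% atoms, ]
    comp <- atoms[1]
    repeat {
      grow <- unique(c(sub$a2[sub$a1 %in% comp], sub$a1[sub$a2 %in% comp]))
      new <- setdiff(grow, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    expect_setequal(comp, atoms)
    expect_true(smiles_is_valid(r$smiles[i]))
  }
})

test_that("constant scorers give the two threshold extremes, deterministically", {
  cfg <- mcts_config(rollouts = 15, min_atoms = 6)
  parent <- "CCCCc1ccncc1"
  always <- mcts_rationales(function(s) c(1, 1, 1), parent, 0, cfg)
  expect_gt(nrow(always), 0)
  never <- mcts_rationales(function(s) c(0, 0, 0), parent, 0, cfg)
  expect_identical(nrow(never), 0L)
  r1 <- mcts_rationales(nitrogen_scorer, parent, 1, cfg)
  r2 <- mcts_rationales(nitrogen_scorer, parent, 1, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("raising prop_delta never enlarges the rationale set", {
  parent <- "CCCCc1ccncc1"
  scorer <- function(s) c(0, 0.3 + 0.6 * grepl("n|N", s), 0)  # scores 0.3/0.9
  sizes <- vapply(c(0.2, 0.5, 0.95), function(pd) {
    nrow(mcts_rationales(scorer, parent, 1,
                         mcts_config(rollouts = 20, min_atoms = 6,
                                     prop_delta = pd)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("a failing scorer prunes the branch with a warning", {
  bomb <- function(s) if (nchar(s) < 10) stop("boom") else c(1, 1, 1)
  w <- testthat::capture_warnings(
    r <- mcts_rationales(bomb, "CCCCc1ccncc1", 0,
                         mcts_config(rollouts = 10, min_atoms = 6)))
  expect_true(any(grepl("pruned", w)))
  expect_true(all(nchar(r$smiles) >= 10))
})

test_that("aggregation groups by canonical substructure and ranks by count then score", {
  rats <- data.frame(
    parent = c("a", "b", "c", "d", "e"),
    smiles = c("c1ccncc1", "c1ccncc1", "c1ccccc1", "CCO", "CCO"),
    n_atoms = c(6L, 6L, 6L, 3L, 3L),
    score = c(0.9, 0.7, 0.95, 0.6, 0.8))
  rats$atoms <- replicate(5, 1:3, simplify = FALSE)
  tab <- aggregate_rationales(rats)
  expect_identical(tab$count, c(2L, 2L, 1L))
  expect_identical(tab$substructure[1:2], c("c1ccncc1", "CCO"))
  expect_equal(tab$mean_score[tab$substructure == "c1ccncc1"], 0.8)
  expect_identical(nrow(aggregate_rationales(rats[0, ])), 0L)
  ## class column splits per kingdom
  rats$class <- c(0L, 0L, 1L, 2L, 2L)
  by_class <- aggregate_rationales(rats)
  expect_named(by_class, c("0", "1", "2"))
  expect_identical(by_class[["2"]]$count, 2L)
})
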