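## Rationale extraction: Monte Carlo tree search over connected subgraphs of
## a parent molecule. Search states are induced subgraphs; the only move is
## deleting one side of a bridge (non-ring) bond, so ring systems are never
## fragmented and every state stays connected. A state's value is the
## classifier probability of the target class for its substructure SMILES;
## minimal substructures that keep that probability above a threshold are
## reported as rationales.

#' MCTS search configuration
#'
#' @param rollouts search iterations (default 20).
#' @param c_puct exploration constant of the upper-confidence selection
#'   rule (default 10).
#' @param max_atoms,min_atoms rationale size window in heavy atoms
#'   (defaults 20 and 8).
#' @param prop_delta minimum classifier probability a rationale must keep,
#'   in (0, 1) (default 0.5).
#' @param seed integer seed (kept for the determinism contract; the search
#'   itself is deterministic).
#' @return list of class `"mcts_config"`.
#' @export
mcts_config <- function(rollouts = 20, c_puct = 10, max_atoms = 20,
                        min_atoms = 8, prop_delta = 0.5, seed = 1) {
  stopifnot(rollouts >= 1, min_atoms >= 1, min_atoms <= max_atoms,
            prop_delta > 0, prop_delta < 1)
  structure(list(rollouts = as.integer(rollouts), c_puct = c_puct,
                 max_atoms = as.integer(max_atoms),
                 min_atoms = as.integer(min_atoms),
                 prop_delta = prop_delta, seed = as.integer(seed)),
            class = "mcts_config")
}

## children of a state: for every bridge bond of the induced subgraph, the
## two sides it separates; keeping either side (>= min_atoms) is one move
.mcts_children <- function(g, atoms, min_atoms) {
  sub <- g$bonds[g$bonds$a1 %in% atoms & g$bonds$a2 %in% atoms, , drop = FALSE]
  if (!nrow(sub)) return(list())
  local <- match(c(sub$a1, sub$a2), atoms)
  a1 <- local[seq_len(nrow(sub))]
  a2 <- local[nrow(sub) + seq_len(nrow(sub))]
  ring <- .ring_bonds(length(atoms), a1, a2)
  bridges <- which(!ring)
  out <- list()
  for (k in bridges) {
    ## component of a1[k] after removing bond k, by BFS
    adj <- vector("list", length(atoms))
    for (j in seq_along(a1)) {
      if (j == k) next
      adj[[a1[j]]] <- c(adj[[a1[j]]], a2[j])
      adj[[a2[j]]] <- c(adj[[a2[j]]], a1[j])
    }
    comp <- rep(FALSE, length(atoms))
    q <- a1[k]; comp[q] <- TRUE
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- TRUE; q <- c(q, w) }
    }
    for (side in list(atoms[comp], atoms[!comp])) {
      if (length(side) >= min_atoms && length(side) < length(atoms))
        out[[paste(sort(side), collapse = ",")]] <- sort(side)
    }
  }
  out
}

#' Extract predictive substructures by Monte Carlo tree search
#'
#' Searches the space of connected subgraphs of `smiles`, pruning one
#' peripheral fragment (one side of a bridge bond) per move, guided by an
#' upper-confidence selection rule with prior equal to the scorer
#' probability of `target_class`. Returns the visited substructures inside
#' the configured size window whose score stays at or above
#' `cfg$prop_delta`. Deterministic given the configuration; returns an
#' empty set when no qualifying subgraph exists. Substructures on which the
#' scorer fails are pruned with a warning.
#'
#' @param scorer `function(smiles) -> numeric vector of 3 class
#'   probabilities` (see [model_scorer]).
#' @param smiles parent molecule SMILES.
#' @param target_class class whose probability is tracked (0, 1 or 2).
#' @param cfg an [mcts_config].
#' @return data frame of class `"mnp_rationales"`: columns `parent`,
#'   `smiles`, `n_atoms`, `score`, and `atoms` (list column of parent atom
#'   indices, each inducing a connected subgraph).
#' @export
mcts_rationales <- function(scorer, smiles, target_class,
                            cfg = mcts_config()) {
  stopifnot(is.function(scorer), inherits(cfg, "mcts_config"),
            target_class %in% 0:2)
  g <- mol_graph(smiles)
  nodes <- new.env(parent = emptyenv())
  score_state <- function(atoms) {
    sub <- subgraph_smiles(g, atoms)
    if (is.na(sub)) return(NULL)
    p <- tryCatch(scorer(sub), error = function(e) NULL)
    if (is.null(p) || length(p) < 3 || anyNA(p[1:3])) return(NULL)
    list(smiles = sub, value = as.numeric(p[[target_class + 1]]))
  }
  get_node <- function(atoms) {
    key <- paste(atoms, collapse = ",")
    nd <- nodes[[key]]
    if (!is.null(nd)) return(nd)
    sc <- score_state(atoms)
    if (is.null(sc)) {
      warning("scorer failed on a substructure of ", smiles,
              "; branch pruned", call. = FALSE)
      nd <- list(atoms = atoms, bad = TRUE)
    } else {
      nd <- list(atoms = atoms, bad = FALSE, smiles = sc$smiles,
                 score = sc$value, W = 0, N = 0L, children = NULL)
    }
    nodes[[key]] <- nd
    nd
  }
  root_atoms <- seq_len(g$n_atoms)
  root <- get_node(root_atoms)
  if (!root$bad) {
    for (r in seq_len(cfg$rollouts)) {
      path <- list()
      cur <- root_atoms
      repeat {
        key <- paste(cur, collapse = ",")
        nd <- nodes[[key]]
        path[[length(path) + 1L]] <- key
        if (length(cur) <= cfg$min_atoms) break
        if (is.null(nd$children)) {
          kids <- .mcts_children(g, cur, cfg$min_atoms)
          kids <- Filter(function(a) !get_node(a)$bad, kids)
          nd$children <- unname(vapply(kids, paste, character(1),
                                       collapse = ","))
          nodes[[key]] <- nd
        }
        if (!length(nd$children)) break
        ## PUCT: exploit mean value, explore by prior score
        ucb <- vapply(nd$children, function(ck) {
          ch <- nodes[[ck]]
          q <- if (ch$N > 0) ch$W / ch$N else 0
          q + cfg$c_puct * ch$score * sqrt(nd$N + 1) / (1 + ch$N)
        }, numeric(1))
        cur <- nodes[[nd$children[which.max(ucb)]]]$atoms
      }
      leaf <- nodes[[path[[length(path)]]]]
      v <- leaf$score
      for (key in path) {
        nd <- nodes[[key]]
        nd$W <- nd$W + v; nd$N <- nd$N + 1L
        nodes[[key]] <- nd
      }
    }
  }
  rows <- list()
  for (key in ls(nodes)) {
    nd <- nodes[[key]]
    if (isTRUE(nd$bad)) next
    n <- length(nd$atoms)
    if (n >= cfg$min_atoms && n <= cfg$max_atoms &&
        nd$score >= cfg$prop_delta)
      rows[[key]] <- data.frame(parent = smiles, smiles = nd$smiles,
                                n_atoms = n, score = nd$score,
                                stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(parent = character(0), smiles = character(0),
                      n_atoms = integer(0), score = numeric(0))
    out$atoms <- list()
  } else {
    keys <- names(rows)
    out <- do.call(rbind, rows)
    out$atoms <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1]]))
    out <- out[order(-out$score, out$n_atoms, out$smiles), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mnp_rationales", "data.frame")
  out
}

#' Probability scorer backed by a fitted model
#'
#' @param model an `"mnp_mpnn"` model.
#' @return `function(smiles)` returning the model's 3-class probabilities,
#'   suitable for [mcts_rationales].
#' @export
model_scorer <- function(model) {
  stopifnot(inherits(model, "mnp_mpnn"))
  function(smiles) as.numeric(predict(model, smiles, type = "prob")[1, ])
}

#' Extract rationales for every compound of a dataset
#'
#' Runs [mcts_rationales] per compound with the compound's own label as the
#' target class.
#'
#' @param model an `"mnp_mpnn"`.
#' @param ds an [mnp_dataset].
#' @param cfg an [mcts_config].
#' @return combined `"mnp_rationales"` data frame with an extra `class`
#'   column.
#' @export
extract_rationales <- function(model, ds, cfg = mcts_config()) {
  stopifnot(inherits(ds, "mnp_dataset"))
  scorer <- model_scorer(model)
  out <- list()
  for (i in seq_len(length(ds))) {
    r <- mcts_rationales(scorer, ds$records$smiles[i],
                         ds$records$label[i], cfg)
    if (nrow(r)) {
      r$class <- ds$records$label[i]
      r$parent <- ds$records$id[i]
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) {
    res <- data.frame(parent = character(0), smiles = character(0),
                      n_atoms = integer(0), score = numeric(0))
    res$atoms <- list(); res$class <- integer(0)
  } else res <- do.call(rbind, out)
  class(res) <- c("mnp_rationales", "data.frame")
  res
}

#' Aggregate rationales into per-class motif tables
#'
#' Groups rationales by exact canonical substructure SMILES and ranks by
#' count, then mean score, descending. Exact grouping keeps the
#' aggregation reproducible; fuzzy fingerprint-similarity merging is
#' deliberately not applied.
#'
#' @param rationales a (possibly combined) `"mnp_rationales"` data frame;
#'   a `class` column splits the table per kingdom, otherwise one table is
#'   returned.
#' @return data frame(s) with columns `substructure`, `count`,
#'   `mean_score`; a named list when a `class` column is present.
#' @export
aggregate_rationales <- function(rationales) {
  df <- as.data.frame(rationales)
  agg_one <- function(d) {
    if (!nrow(d))
      return(data.frame(substructure = character(0), count = integer(0),
                        mean_score = numeric(0)))
    a <- aggregate(d$score, by = list(substructure = d$smiles),
                   FUN = function(v) c(length(v), mean(v)))
    out <- data.frame(substructure = a$substructure,
                      count = as.integer(a$x[, 1]),
                      mean_score = a$x[, 2], stringsAsFactors = FALSE)
    out <- out[order(-out$count, -out$mean_score, out$substructure), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  }
  if ("class" %in% names(df)) {
    split_df <- split(df, factor(df$class, levels = 0:2))
    lapply(split_df, agg_one)
  } else agg_one(df)
}
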