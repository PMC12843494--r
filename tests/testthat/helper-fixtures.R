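## Shared fixtures: tiny configs and memoized synthetic datasets so the
## expensive generation/featurization work happens once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

tiny_config <- function(seed = 1, epochs = 8, hidden = 16) {
  mpnn_config(hidden_dim = hidden, ffn_hidden = hidden, epochs = epochs,
              batch_size = 32, seed = seed)
}

## reference study-condition dataset (200/100/100), shared across tests
study_dataset <- function(seed = 7) {
  memo(paste0("ds", seed), generate_dataset(synthetic_spec(seed = seed)))
}

small_dataset <- function() {
  memo("small", generate_dataset(
    synthetic_spec(n_animalia = 30, n_bacteria = 15, n_fungi = 15, seed = 3)))
}

small_feats <- function() {
  memo("small_feats", featurize_dataset(small_dataset()))
}

small_model <- function() {
  memo("small_model",
       mnp_mpnn(small_dataset(), tiny_config(seed = 5, epochs = 15,
                                             hidden = 24),
                feats = small_feats()))
}

## brute-force neighborhood predicate: the oracle the kd-tree must match
brute_force_removed <- function(emb, labels, radius) {
  labels <- labels[rownames(emb)]
  if (radius == 0 || nrow(emb) == 0) return(character(0))
  ani <- which(labels == 0L)
  micro <- which(labels != 0L)
  if (!length(ani) || !length(micro)) return(character(0))
  D <- as.matrix(dist(emb))
  hit <- vapply(ani, function(i) any(D[i, micro] < radius), logical(1))
  sort(rownames(emb)[ani[hit]])
}

## exhaustive enumeration of connected atom subsets of a small molecule;
## independent oracle for the MCTS rationale search
enumerate_connected <- function(g, min_atoms) {
  n <- g$n_atoms
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    adj[[g$bonds$a1[k]]] <- c(adj[[g$bonds$a1[k]]], g$bonds$a2[k])
    adj[[g$bonds$a2[k]]] <- c(adj[[g$bonds$a2[k]]], g$bonds$a1[k])
  }
  is_conn <- function(s) {
    seen <- s[1]; q <- s[1]
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in intersect(adj[[v]], s))
        if (!w %in% seen) { seen <- c(seen, w); q <- c(q, w) }
    }
    length(seen) == length(s)
  }
  subsets <- unlist(lapply(min_atoms:n, function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  Filter(is_conn, subsets)
}

f1_score <- function(flagged, planted) {
  tp <- length(intersect(flagged, planted))
  prec <- if (length(flagged)) tp / length(flagged) else 0
  rec <- if (length(planted)) tp / length(planted) else 1
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
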