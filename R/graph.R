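## Molecular graphs: built from canonical SMILES through the OpenBabel SDF
## route, with ring-bond perception (bridge decomposition), aromatic flags
## read off the canonical SMILES, implicit-H bookkeeping, and the numeric
## atom/bond features consumed by the message-passing encoder.

.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4, Se = 2, As = 3)

.FEAT_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

## per-atom annotations recoverable from the SMILES token stream, in atom
## order: aromatic (lowercase) flag and explicit bracket H counts
.token_atom_info <- function(smiles) {
  toks <- smiles_tokens(smiles)
  if (is.null(toks)) return(NULL)
  atoms <- toks[vapply(toks, .is_atom_token, logical(1))]
  arom <- logical(length(atoms))
  h_expl <- rep(NA_integer_, length(atoms))
  for (k in seq_along(atoms)) {
    t <- atoms[k]
    if (grepl("^\\[", t)) {
      body <- sub("^\\[", "", sub("\\]$", "", t))
      sym <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      arom[k] <- length(sym) == 1 && sym == tolower(sym) && !sym %in% c("se", "as", "te", "si")
      hm <- regmatches(body, regexec("(?<![A-Za-z])H([0-9]*)", body, perl = TRUE))[[1]]
      ## bracket atom: H count is explicit (absent H token means zero)
      h_expl[k] <- if (length(hm)) {
        if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      } else 0L
      if (grepl("^\\[[0-9]*[a-z]", t) && !grepl("^\\[(se|as|te|si)", body))
        arom[k] <- TRUE
    } else {
      arom[k] <- t %in% c("b", "c", "n", "o", "p", "s")
    }
  }
  list(aromatic = arom, h_explicit = h_expl)
}

## bridge bonds by DFS lowpoint; a bond is in a ring iff it is not a bridge
.ring_bonds <- function(n, a1, a2) {
  m <- length(a1)
  if (m == 0) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[a1[k]]] <- c(adj[[a1[k]]], k)
    adj[[a2[k]]] <- c(adj[[a2[k]]], k)
  }
  disc <- integer(n); low <- integer(n); timer <- 0L
  is_bridge <- logical(m)
  for (root in seq_len(n)) {
    if (disc[root] > 0) next
    ## iterative DFS: stack of (vertex, incoming bond, next adj position)
    stack <- list(list(v = root, pe = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      if (top$i <= length(adj[[v]])) {
        k <- adj[[v]][top$i]
        stack[[length(stack)]]$i <- top$i + 1L
        if (k == top$pe) next
        w <- if (a1[k] == v) a2[k] else a1[k]
        if (disc[w] > 0) {
          low[v] <- min(low[v], disc[w])
          stack[[length(stack)]]$low_v <- low[v]
        } else {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, i = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[top$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

#' Build a molecular graph from SMILES
#'
#' The input is canonicalized first, so any writing of the same molecule
#' (including atom-order shuffles) yields an identical graph — all downstream
#' representations inherit this invariance. Atom annotations: element,
#' formal charge, aromaticity, implicit hydrogen count, degree, ring
#' membership. Bond annotations: order, ring membership, aromaticity.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `"mol_graph"`.
#' @export
mol_graph <- function(smiles) {
  mol_graph_batch(smiles)[[1]]
}

#' Build molecular graphs for a vector of SMILES
#'
#' Vectorized variant of [mol_graph]; one OpenBabel conversion for the whole
#' batch.
#'
#' @param smiles character vector.
#' @return list of `"mol_graph"` objects, named after `smiles` names if set.
#' @export
mol_graph_batch <- function(smiles) {
  can <- canonicalize_smiles(smiles, strict = TRUE)
  tags <- paste0("m", seq_along(can))
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(setNames(can, tags)))
  out <- vector("list", length(can))
  for (i in seq_along(can)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    n <- nrow(ab)
    elem <- sub("_.*$", "", rownames(ab))
    chg_code <- if ("C5" %in% colnames(ab)) ab[, "C5"] else rep(0, n)
    charge <- ifelse(chg_code >= 1 & chg_code <= 7 & chg_code != 4,
                     4 - chg_code, 0L)
    if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
      a1 <- integer(0); a2 <- integer(0); order <- integer(0)
    } else {
      a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
      order <- as.integer(bb[, 3])
    }
    info <- .token_atom_info(can[i])
    aromatic <- if (!is.null(info) && length(info$aromatic) == n)
      info$aromatic else rep(FALSE, n)
    h_expl <- if (!is.null(info) && length(info$h_explicit) == n)
      info$h_explicit else rep(NA_integer_, n)
    ring_bond <- .ring_bonds(n, a1, a2)
    ring_atom <- rep(FALSE, n)
    if (any(ring_bond)) ring_atom[unique(c(a1[ring_bond], a2[ring_bond]))] <- TRUE
    degree <- tabulate(c(a1, a2), nbins = n)
    ## implicit H from default valence (aromatic Kekule orders as written);
    ## bracket atoms carry their explicit H count
    bo_sum <- rep(0, n)
    for (k in seq_along(a1)) {
      o <- min(order[k], 3)
      bo_sum[a1[k]] <- bo_sum[a1[k]] + o
      bo_sum[a2[k]] <- bo_sum[a2[k]] + o
    }
    val <- unname(.DEFAULT_VALENCE[elem])
    val[is.na(val)] <- 0
    val <- val + ifelse(elem %in% c("N", "P", "O", "S"), charge,
                        -abs(charge))
    h_count <- pmax(0L, as.integer(val - bo_sum))
    h_count[!is.na(h_expl)] <- h_expl[!is.na(h_expl)]
    out[[i]] <- structure(list(
      smiles = can[i], n_atoms = n, elem = elem, charge = as.integer(charge),
      aromatic = aromatic, h_count = h_count, degree = degree,
      ring_atom = ring_atom,
      bonds = data.frame(a1 = a1, a2 = a2, order = order,
                         ring = ring_bond,
                         aromatic = ring_bond & aromatic[a1] & aromatic[a2])
    ), class = "mol_graph")
  }
  if (!is.null(names(smiles))) names(out) <- names(smiles)
  out
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Featurize a molecule for the message-passing encoder
#'
#' Atom features: one-hot element (C, N, O, S, P, F, Cl, Br, I, other),
#' one-hot degree (0–5), formal charge, aromatic flag, one-hot implicit H
#' count (0–4), ring membership. Bond features: one-hot order
#' (single/double/triple), aromatic flag, ring membership. Each undirected
#' bond contributes two directed edges. Deterministic, and invariant to
#' SMILES rewriting (inherited from [mol_graph]).
#'
#' @param x a SMILES string or a `"mol_graph"`.
#' @return a list with atom feature matrix `x` (n × 24), directed edge
#'   endpoints `src`/`dst`, `rev` (index of each edge's reverse), and edge
#'   feature matrix `e` (2·bonds × 5).
#' @export
featurize <- function(x) {
  g <- if (inherits(x, "mol_graph")) x else mol_graph(x)
  n <- g$n_atoms
  el <- match(g$elem, .FEAT_ELEMENTS)
  X <- matrix(0, n, 24)
  X[cbind(seq_len(n), ifelse(is.na(el), 10L, el))] <- 1
  X[cbind(seq_len(n), 10L + pmin(g$degree, 5L) + 1L)] <- 1       # cols 11..16
  X[, 17] <- g$charge
  X[, 18] <- as.numeric(g$aromatic)
  X[cbind(seq_len(n), 18L + pmin(g$h_count, 4L) + 1L)] <- 1      # cols 19..23
  X[, 24] <- as.numeric(g$ring_atom)
  nb <- nrow(g$bonds)
  if (nb) {
    src <- c(g$bonds$a1, g$bonds$a2)
    dst <- c(g$bonds$a2, g$bonds$a1)
    rev <- c(nb + seq_len(nb), seq_len(nb))
    E <- matrix(0, 2 * nb, 5)
    oo <- pmin(g$bonds$order, 3)
    E[cbind(seq_len(nb), oo)] <- 1
    E[cbind(nb + seq_len(nb), oo)] <- 1
    E[, 4] <- rep(as.numeric(g$bonds$aromatic), 2)
    E[, 5] <- rep(as.numeric(g$bonds$ring), 2)
  } else {
    src <- integer(0); dst <- integer(0); rev <- integer(0)
    E <- matrix(0, 0, 5)
  }
  list(x = X, src = src, dst = dst, rev = rev, e = E, n_atoms = n,
       smiles = g$smiles)
}

## all-pairs topological distances by BFS; -1 where disconnected
.topo_dist <- function(g) {
  n <- g$n_atoms
  D <- matrix(-1L, n, n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    adj[[g$bonds$a1[k]]] <- c(adj[[g$bonds$a1[k]]], g$bonds$a2[k])
    adj[[g$bonds$a2[k]]] <- c(adj[[g$bonds$a2[k]]], g$bonds$a1[k])
  }
  for (s in seq_len(n)) {
    d <- rep(-1L, n); d[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (d[w] < 0) { d[w] <- d[v] + 1L; q <- c(q, w) }
    }
    D[s, ] <- d
  }
  D
}

## V2000 molfile for an induced subgraph of `g` (1-based atom indices);
## used to turn scaffolds and MCTS rationales back into SMILES
.subgraph_molfile <- function(g, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  idx <- match(seq_len(g$n_atoms), atoms)
  keep <- which(!is.na(match(g$bonds$a1, atoms)) & !is.na(match(g$bonds$a2, atoms)))
  na <- length(atoms); nb <- length(keep)
  hdr <- c("", " mnporigin", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                0, 0, 0, g$elem[atoms])
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        idx[g$bonds$a1[keep]], idx[g$bonds$a2[keep]],
                        pmin(g$bonds$order[keep], 3)) else character(0)
  chg <- which(g$charge[atoms] != 0)
  cl <- if (length(chg))
    vapply(chg, function(j) sprintf("M  CHG  1%4d%4d", j, g$charge[atoms[j]]),
           character(1)) else character(0)
  paste(c(hdr, al, bl, cl, "M  END", "$$$$"), collapse = "\n")
}

## batched subgraph -> canonical SMILES: one OpenBabel call for a list of
## (graph, atom-set) pairs; returns NA where conversion fails
.subgraph_smiles_batch <- function(graphs, atom_sets) {
  stopifnot(length(graphs) == length(atom_sets))
  n <- length(graphs)
  out <- rep(NA_character_, n)
  todo <- which(lengths(atom_sets) > 0)
  if (!length(todo)) return(out)
  blocks <- vapply(todo, function(i) {
    mf <- .subgraph_molfile(graphs[[i]], atom_sets[[i]])
    sub("^\n", paste0("t", i, "\n"), mf)   # title line carries the index tag
  }, character(1))
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "SMI",
                                               paste(blocks, collapse = "\n"))),
    error = function(e) "")
  for (ln in strsplit(raw, "\n", fixed = TRUE)[[1]]) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(parts) >= 2) {
      idx <- suppressWarnings(as.integer(sub("^t", "", parts[length(parts)])))
      if (!is.na(idx)) out[idx] <- parts[1]
    }
  }
  ## canonicalize the written forms in one more pass
  ok <- !is.na(out)
  if (any(ok)) out[ok] <- .ob_canonical(out[ok])
  out
}

#' Canonical SMILES of an induced subgraph
#'
#' Open valences created by cutting bonds are filled with implicit
#' hydrogens, the usual convention for substructure fragments.
#'
#' @param g a `"mol_graph"`.
#' @param atoms integer vector of (1-based) atom indices.
#' @return canonical SMILES string, or `NA` if conversion fails.
#' @export
subgraph_smiles <- function(g, atoms) {
  stopifnot(inherits(g, "mol_graph"), length(atoms) >= 1)
  mf <- .subgraph_molfile(g, atoms)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", mf)),
    error = function(e) "")
  s <- strsplit(trimws(out), "[\t\n ]+")[[1]]
  if (length(s) < 1 || !nzchar(s[1])) return(NA_character_)
  s[1]
}
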