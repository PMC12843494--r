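## Physicochemical profiling, Murcko scaffolds, Morgan (ECFP) fingerprints,
## PCA + k-means fingerprint clustering, cross-kingdom overlap counting and
## top-scaffold reporting.

#' Physicochemical descriptor table
#'
#' Six drug-likeness descriptors per compound: molecular weight (Da), AlogP
#' (octanol-water partition estimate), hydrogen-bond donors and acceptors
#' (Lipinski-style counts), rotatable bonds, and topological polar surface
#' area (A^2). MW, AlogP, HBD, HBA and PSA come from the OpenBabel property
#' engine; rotatable bonds are counted on the molecular graph as acyclic
#' single bonds between two non-terminal heavy atoms.
#'
#' @param ds an [mnp_dataset].
#' @return data frame with columns `id, MW, AlogP, HBD, HBA, RotB, PSA`.
#' @export
physchem_profile <- function(ds) {
  stopifnot(inherits(ds, "mnp_dataset"))
  if (length(ds) == 0)
    return(data.frame(id = character(0), MW = numeric(0), AlogP = numeric(0),
                      HBD = integer(0), HBA = integer(0), RotB = integer(0),
                      PSA = numeric(0)))
  smi <- ds$records$smiles
  sdfs <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(smi, paste0("m", seq_along(smi)))))
  p <- ChemmineR::propOB(sdfs)
  graphs <- mol_graph_batch(smi)
  rotb <- vapply(graphs, function(g) {
    b <- g$bonds
    if (nrow(b) == 0) return(0L)
    sum(b$order == 1 & !b$ring & g$degree[b$a1] > 1 & g$degree[b$a2] > 1)
  }, integer(1))
  data.frame(id = ds$records$id, MW = p$MW, AlogP = p$logP,
             HBD = as.integer(p$HBD), HBA = as.integer(p$HBA1),
             RotB = as.integer(rotb), PSA = p$TPSA,
             stringsAsFactors = FALSE)
}

#' Murcko scaffold extraction
#'
#' Removes side chains, retaining only ring systems and the linkers between
#' them: terminal atoms attached by single bonds are pruned iteratively, so
#' exocyclic multiple bonds (e.g. carbonyl oxygens on a ring) stay part of
#' the scaffold. Acyclic molecules yield the empty scaffold `""`. The map is
#' idempotent.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for
#'   ring-free molecules).
#' @export
murcko_scaffold <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  graphs <- mol_graph_batch(smiles)
  sets <- lapply(graphs, function(g) {
    if (!any(g$ring_atom)) return(integer(0))
    keep <- rep(TRUE, g$n_atoms)
    b <- g$bonds
    repeat {
      deg <- tabulate(c(b$a1[keep[b$a1] & keep[b$a2]],
                        b$a2[keep[b$a1] & keep[b$a2]]), nbins = g$n_atoms)
      ## terminal (or orphaned) non-ring atoms whose remaining attachment is
      ## a single bond get pruned; multiply-bonded terminals stay
      prune <- which(keep & !g$ring_atom & deg <= 1)
      prune <- prune[vapply(prune, function(a) {
        j <- which((b$a1 == a & keep[b$a2]) | (b$a2 == a & keep[b$a1]))
        length(j) == 0 || all(b$order[j] == 1)
      }, logical(1))]
      if (!length(prune)) break
      keep[prune] <- FALSE
    }
    which(keep)
  })
  out <- .subgraph_smiles_batch(graphs, sets)
  out[lengths(sets) == 0] <- ""
  out
}

.MORGAN_BOND_CODE <- function(order, aromatic) ifelse(aromatic, 4L, pmin(order, 3L))

## Morgan atom identifiers for radii 0..radius; returns list of per-radius
## numeric identifier vectors. Invariant to atom order by sorted-neighbor
## hashing; inputs are canonical graphs anyway.
.morgan_identifiers <- function(g, radius) {
  n <- g$n_atoms
  inv <- vapply(seq_len(n), function(a) hash_codes(c(
    hash_string(g$elem[a]), g$degree[a], g$charge[a] + 8,
    g$h_count[a], as.integer(g$ring_atom[a]), as.integer(g$aromatic[a]))),
    numeric(1))
  ids <- vector("list", radius + 1)
  ids[[1]] <- inv
  if (radius == 0 || nrow(g$bonds) == 0) {
    for (r in seq_len(radius)) ids[[r + 1]] <- numeric(0)
    return(ids)
  }
  b <- g$bonds
  bcode <- .MORGAN_BOND_CODE(b$order, b$aromatic)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbr[[b$a1[k]]] <- rbind(nbr[[b$a1[k]]], c(bcode[k], b$a2[k]))
    nbr[[b$a2[k]]] <- rbind(nbr[[b$a2[k]]], c(bcode[k], b$a1[k]))
  }
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(a) {
      nb <- nbr[[a]]
      if (is.null(nb)) return(hash_codes(c(r, ids[[r]][a])))
      pairs <- cbind(nb[, 1], ids[[r]][nb[, 2]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_codes(c(r, ids[[r]][a], t(pairs)))
    }, numeric(1))
    ids[[r + 1]] <- inv
  }
  ids
}

#' Morgan (extended-connectivity) fingerprint
#'
#' Iterative neighborhood hashing up to the given environment radius, folded
#' into an `nbits`-long binary vector. The default radius of 6 is unusually
#' deep for ECFP-style fingerprints (typical radii are 2-3) but is the
#' setting this workflow standardizes on; it is a knob, not a constant.
#' Invariant to SMILES rewriting of the same molecule.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint length (default 1024).
#' @param radius environment radius (default 6).
#' @return for a single SMILES, an integer 0/1 vector of length `nbits`;
#'   for several, a matrix with one row per compound.
#' @export
morgan_fp <- function(smiles, nbits = 1024, radius = 6) {
  stopifnot(nbits >= 1, radius >= 0)
  graphs <- mol_graph_batch(smiles)
  M <- matrix(0L, length(graphs), nbits)
  for (i in seq_along(graphs)) {
    ids <- unlist(.morgan_identifiers(graphs[[i]], radius))
    M[i, unique(ids %% nbits) + 1] <- 1L
  }
  rownames(M) <- names(smiles)
  if (length(smiles) == 1) M[1, ] else M
}

#' Cluster fingerprints into structural groups
#'
#' PCA compression of the fingerprint matrix followed by k-means. Both steps
#' are seeded and deterministic. `k` is clamped to `floor(n/2)` (and to the
#' number of distinct fingerprints) with a warning when the data cannot
#' support the requested cluster count; requesting more clusters than points
#' is an error proposing `floor(n/2)`.
#'
#' @param fps fingerprint matrix (compounds x bits), rownames = ids.
#' @param pca_dims number of principal components to keep (default 85,
#'   clamped to what the data admit).
#' @param k number of clusters.
#' @param seed integer seed.
#' @return object of class `"cluster_assignment"`: list with `cluster`
#'   (named integer vector, values in `[0, k)`), `k`, and `seed`.
#' @export
cluster_fingerprints <- function(fps, pca_dims = 85, k, seed = 1) {
  stopifnot(is.matrix(fps), k >= 1)
  n <- nrow(fps)
  if (k > n)
    stop("k = ", k, " exceeds the number of compounds (", n,
         "); try k = ", max(1L, floor(n / 2)), call. = FALSE)
  n_distinct <- nrow(unique(fps))
  k_max <- max(1L, min(floor(n / 2), n_distinct))
  if (k > k_max) {
    warning("k clamped from ", k, " to ", k_max, " for n = ", n,
            " compounds (", n_distinct, " distinct fingerprints)")
    k <- k_max
  }
  pca_dims <- min(pca_dims, ncol(fps), n - 1)
  z <- if (pca_dims >= 1 && n > 1) {
    pc <- prcomp(fps, center = TRUE, scale. = FALSE, rank. = pca_dims)
    pc$x
  } else fps
  cl <- with_seed(derive_seed(seed, "kmeans"),
                  kmeans(z, centers = k, nstart = 5, iter.max = 100))
  structure(list(cluster = setNames(as.integer(cl$cluster) - 1L,
                                    rownames(fps)),
                 k = k, seed = seed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", length(x$cluster), "compounds in", x$k,
      "clusters (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Three-set Venn region counts
#'
#' Counts the seven regions of the Venn diagram of three key sets (e.g.
#' scaffolds or cluster ids per kingdom). Region names concatenate the
#' class names of the sets that contain the element, e.g. `"0"`, `"01"`,
#' `"012"`. Counts sum to the cardinality of the union.
#'
#' @param sets_by_class named list of three character vectors.
#' @return named integer vector of length 7.
#' @export
overlap_counts <- function(sets_by_class) {
  stopifnot(is.list(sets_by_class), length(sets_by_class) == 3)
  nm <- names(sets_by_class) %||% c("0", "1", "2")
  sets <- lapply(sets_by_class, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0) member <- matrix(FALSE, 0, 3)
  regions <- c(nm[1], nm[2], nm[3],
               paste0(nm[1], nm[2]), paste0(nm[1], nm[3]),
               paste0(nm[2], nm[3]), paste0(nm[1], nm[2], nm[3]))
  pattern <- list(c(T, F, F), c(F, T, F), c(F, F, T),
                  c(T, T, F), c(T, F, T), c(F, T, T), c(T, T, T))
  counts <- vapply(pattern, function(p) {
    sum(member[, 1] == p[1] & member[, 2] == p[2] & member[, 3] == p[3])
  }, numeric(1))
  setNames(as.integer(counts), regions)
}

#' Most frequent Murcko scaffolds per kingdom
#'
#' Ranks scaffolds by count (descending), breaking ties lexicographically by
#' canonical scaffold SMILES. Ring-free compounds (empty scaffold) are
#' excluded: a "no ring" pseudo-scaffold carries no information about
#' origin-typical core chemistry.
#'
#' @param ds an [mnp_dataset].
#' @param n scaffolds to report per class (default 20).
#' @return named list (`"0"`, `"1"`, `"2"`) of data frames with columns
#'   `scaffold`, `count`.
#' @export
top_scaffolds <- function(ds, n = 20) {
  stopifnot(inherits(ds, "mnp_dataset"), n >= 1)
  scaf <- if (length(ds)) murcko_scaffold(ds$records$smiles) else character(0)
  out <- list()
  for (k in 0:2) {
    s <- scaf[ds$records$label == k]
    s <- s[!is.na(s) & nzchar(s)]
    if (!length(s)) {
      out[[as.character(k)]] <- data.frame(scaffold = character(0),
                                           count = integer(0))
      next
    }
    tab <- table(s)
    df <- data.frame(scaffold = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$scaffold), , drop = FALSE]
    rownames(df) <- NULL
    out[[as.character(k)]] <- head(df, n)
  }
  out
}
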