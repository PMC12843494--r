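## Directed message-passing molecular encoder with a feed-forward
## classification head, implemented in base R + sparse Matrix ops with
## hand-derived backpropagation and Adam. Messages live on directed bond
## edges: the hidden state of edge v->w aggregates incoming edge states at v
## excluding the reverse edge w->v, the construction that distinguishes a
## directed MPNN from an ordinary bond-graph GNN and avoids immediate
## message echo. Molecule vectors are sum-readouts over atom states.

#' Encoder / training configuration
#'
#' @param hidden_dim encoder hidden width (default 1100, the production
#'   setting; reduced widths such as 64 train in minutes on a CPU at
#'   desk scale).
#' @param message_steps number of message-passing iterations T (default 3).
#' @param ffn_hidden width of the feed-forward head's hidden layers
#'   (default: equal to `hidden_dim`). The last hidden activation is the
#'   `last_ffn` representation.
#' @param ffn_layers number of hidden layers in the head (default 1).
#' @param dropout dropout probability on the head activations during
#'   training (default 0).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 30).
#' @param batch_size molecules per minibatch (default 50).
#' @param grad_clip global gradient-norm clip (default 5).
#' @param seed integer seed controlling initialization and shuffling.
#' @return list of class `"mpnn_config"`.
#' @export
mpnn_config <- function(hidden_dim = 1100, message_steps = 3,
                        ffn_hidden = NULL, ffn_layers = 1, dropout = 0,
                        lr = 1e-3, epochs = 30, batch_size = 50,
                        grad_clip = 5, seed = 1) {
  stopifnot(hidden_dim >= 1, message_steps >= 1, ffn_layers >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 message_steps = as.integer(message_steps),
                 ffn_hidden = as.integer(ffn_hidden %||% hidden_dim),
                 ffn_layers = as.integer(ffn_layers), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "mpnn_config")
}

.ATOM_FDIM <- 24L
.BOND_FDIM <- 5L

#' Featurize a whole dataset
#'
#' One OpenBabel pass for the batch; returns the per-molecule feature lists
#' consumed by the encoder. Reuse this across repeated trainings (e.g.
#' cross-prediction cycles) to avoid re-parsing.
#'
#' @param ds an [mnp_dataset] or character vector of SMILES.
#' @return named list of [featurize] outputs, keyed by compound id.
#' @export
featurize_dataset <- function(ds) {
  smi <- if (inherits(ds, "mnp_dataset"))
    setNames(ds$records$smiles, ds$records$id) else ds
  graphs <- mol_graph_batch(smi)
  out <- lapply(graphs, featurize)
  names(out) <- names(graphs)
  out
}

## combine featurized molecules into one sparse-batch structure
.batch_graphs <- function(feats) {
  nb <- length(feats)
  na <- vapply(feats, `[[`, integer(1), "n_atoms")
  ne <- vapply(feats, function(f) length(f$src), integer(1))
  aoff <- cumsum(c(0L, na[-nb]))
  eoff <- cumsum(c(0L, ne[-nb]))
  X <- do.call(rbind, lapply(feats, `[[`, "x"))
  E <- do.call(rbind, lapply(feats, `[[`, "e"))
  src <- unlist(lapply(seq_len(nb), function(i) feats[[i]]$src + aoff[i]),
                use.names = FALSE)
  dst <- unlist(lapply(seq_len(nb), function(i) feats[[i]]$dst + aoff[i]),
                use.names = FALSE)
  rev <- unlist(lapply(seq_len(nb), function(i) feats[[i]]$rev + eoff[i]),
                use.names = FALSE)
  nE <- length(src); nA <- nrow(X)
  ## edge k feeds edge e when dst(k) == src(e), k != rev(e)
  if (nE > 0) {
    by_dst <- split(seq_len(nE), dst)
    ii <- integer(0); jj <- integer(0)
    feeders <- by_dst[as.character(src)]
    cnt <- lengths(feeders)
    ii <- rep(seq_len(nE), cnt)
    jj <- unlist(feeders, use.names = FALSE)
    keep <- jj != rev[ii]
    A_e2e <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = 1,
                                  dims = c(nE, nE))
    A_e2a <- Matrix::sparseMatrix(i = dst, j = seq_len(nE), x = 1,
                                  dims = c(nA, nE))
  } else {
    A_e2e <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0, 0))
    A_e2a <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nA, 0))
  }
  A_mol <- Matrix::sparseMatrix(i = rep(seq_len(nb), na), j = seq_len(nA),
                                x = 1, dims = c(nb, nA))
  list(X = X, E = E, src = src, A_e2e = A_e2e, A_e2a = A_e2a, A_mol = A_mol,
       n_mol = nb, n_edges = nE)
}

.xavier <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

.init_params <- function(cfg) {
  h <- cfg$hidden_dim; f <- cfg$ffn_hidden
  p <- list(W_i = .xavier(.ATOM_FDIM + .BOND_FDIM, h),
            W_h = .xavier(h, h),
            W_o = .xavier(.ATOM_FDIM + h, h))
  p$W_f <- vector("list", cfg$ffn_layers)
  p$b_f <- vector("list", cfg$ffn_layers)
  din <- h
  for (l in seq_len(cfg$ffn_layers)) {
    p$W_f[[l]] <- .xavier(din, f); p$b_f[[l]] <- numeric(f); din <- f
  }
  p$W_out <- .xavier(f, 3L)
  p$b_out <- numeric(3L)
  p
}

.relu <- function(x) pmax(x, 0)

## forward pass; returns activations needed for backprop / embeddings
.forward <- function(p, b, cfg, train_masks = NULL) {
  T_ <- cfg$message_steps
  if (b$n_edges > 0) {
    Z <- cbind(b$X[b$src, , drop = FALSE], b$E)
    P0 <- Z %*% p$W_i
    H0 <- .relu(P0)
    H <- H0
    Ms <- vector("list", T_); Ps <- vector("list", T_)
    for (t in seq_len(T_)) {
      M <- as.matrix(b$A_e2e %*% H)
      P <- H0 + M %*% p$W_h
      H <- .relu(P)
      Ms[[t]] <- M; Ps[[t]] <- P
    }
    M_a <- as.matrix(b$A_e2a %*% H)
  } else {
    Z <- NULL; P0 <- NULL; H0 <- NULL; H <- NULL
    Ms <- list(); Ps <- list()
    M_a <- matrix(0, nrow(b$X), cfg$hidden_dim)
  }
  Za <- cbind(b$X, M_a)
  Pa <- Za %*% p$W_o
  Ha <- .relu(Pa)
  G <- as.matrix(b$A_mol %*% Ha)
  A <- G
  Fp <- vector("list", cfg$ffn_layers)
  Fa <- vector("list", cfg$ffn_layers)
  for (l in seq_len(cfg$ffn_layers)) {
    pre <- sweep(A %*% p$W_f[[l]], 2, p$b_f[[l]], `+`)
    act <- .relu(pre)
    if (!is.null(train_masks)) act <- act * train_masks[[l]]
    Fp[[l]] <- pre; Fa[[l]] <- act
    A <- act
  }
  logits <- sweep(A %*% p$W_out, 2, p$b_out, `+`)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(Z = Z, P0 = P0, H0 = H0, H = H, Ms = Ms, Ps = Ps, M_a = M_a,
       Za = Za, Pa = Pa, Ha = Ha, G = G, Fp = Fp, Fa = Fa,
       logits = logits, probs = probs)
}

## gradients of mean cross-entropy; frozen=TRUE stops at the head
.backward <- function(p, b, cfg, fw, Y, frozen = FALSE, train_masks = NULL) {
  n <- b$n_mol
  g <- list()
  dlog <- (fw$probs - Y) / n
  A_last <- if (cfg$ffn_layers > 0) fw$Fa[[cfg$ffn_layers]] else fw$G
  g$W_out <- t(A_last) %*% dlog
  g$b_out <- colSums(dlog)
  dA <- dlog %*% t(p$W_out)
  g$W_f <- vector("list", cfg$ffn_layers)
  g$b_f <- vector("list", cfg$ffn_layers)
  for (l in rev(seq_len(cfg$ffn_layers))) {
    if (!is.null(train_masks)) dA <- dA * train_masks[[l]]
    dpre <- dA * (fw$Fp[[l]] > 0)
    Ain <- if (l == 1) fw$G else fw$Fa[[l - 1]]
    g$W_f[[l]] <- t(Ain) %*% dpre
    g$b_f[[l]] <- colSums(dpre)
    dA <- dpre %*% t(p$W_f[[l]])
  }
  if (frozen) return(g)
  dG <- dA
  dHa <- as.matrix(Matrix::t(b$A_mol) %*% dG)
  dPa <- dHa * (fw$Pa > 0)
  g$W_o <- t(fw$Za) %*% dPa
  if (b$n_edges > 0) {
    h <- cfg$hidden_dim
    dZa <- dPa %*% t(p$W_o)
    dM_a <- dZa[, .ATOM_FDIM + seq_len(h), drop = FALSE]
    dH <- as.matrix(Matrix::t(b$A_e2a) %*% dM_a)
    dH0 <- matrix(0, nrow(dH), h)
    g$W_h <- matrix(0, h, h)
    for (t in rev(seq_len(cfg$message_steps))) {
      dP <- dH * (fw$Ps[[t]] > 0)
      dH0 <- dH0 + dP
      g$W_h <- g$W_h + t(fw$Ms[[t]]) %*% dP
      dM <- dP %*% t(p$W_h)
      dH <- as.matrix(Matrix::t(b$A_e2e) %*% dM)
    }
    dH0 <- dH0 + dH           # initial state also seeds the first message
    dP0 <- dH0 * (fw$P0 > 0)
    g$W_i <- t(fw$Z) %*% dP0
  } else {
    g$W_h <- matrix(0, cfg$hidden_dim, cfg$hidden_dim)
    g$W_i <- matrix(0, .ATOM_FDIM + .BOND_FDIM, cfg$hidden_dim)
  }
  g
}

.flatten_grads <- function(g) {
  unlist(lapply(g, function(x) if (is.list(x)) unlist(lapply(x, as.numeric))
                else as.numeric(x)))
}

.adam_state <- function(p) {
  rapply(p, function(x) list(m = x * 0, v = x * 0), how = "list")
}

.adam_step <- function(p, g, st, lr, t, names_upd) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(par, grad, s) {
    s$m <- b1 * s$m + (1 - b1) * grad
    s$v <- b2 * s$v + (1 - b2) * grad^2
    mh <- s$m / (1 - b1^t); vh <- s$v / (1 - b2^t)
    list(par = par - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (nm in names_upd) {
    if (is.list(p[[nm]]) && !is.matrix(p[[nm]])) {
      for (l in seq_along(p[[nm]])) {
        r <- upd(p[[nm]][[l]], as.matrix(g[[nm]][[l]]) * 0 + g[[nm]][[l]],
                 st[[nm]][[l]])
        p[[nm]][[l]] <- r$par; st[[nm]][[l]] <- r$s
      }
    } else {
      r <- upd(p[[nm]], as.matrix(g[[nm]]), st[[nm]])
      p[[nm]] <- r$par; st[[nm]] <- r$s
    }
  }
  list(p = p, st = st)
}

.train_loop <- function(params, feats, labels, cfg, frozen = FALSE,
                        adam = NULL, loss_trace = numeric(0)) {
  n <- length(feats)
  Yall <- matrix(0, n, 3); Yall[cbind(seq_len(n), labels + 1L)] <- 1
  st <- adam %||% .adam_state(params)
  step <- 0L
  upd_names <- if (frozen) c("W_f", "b_f", "W_out", "b_out")
               else names(params)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      b <- .batch_graphs(feats[idx])
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(seq_len(cfg$ffn_layers), function(l) {
          (matrix(runif(length(idx) * cfg$ffn_hidden), length(idx)) >
             cfg$dropout) / (1 - cfg$dropout)
        })
      }
      fw <- .forward(params, b, cfg, masks)
      Y <- Yall[idx, , drop = FALSE]
      ep_loss <- ep_loss - sum(log(pmax(fw$probs[Y == 1], 1e-12))) / length(idx)
      nb <- nb + 1L
      gr <- .backward(params, b, cfg, fw, Y, frozen, masks)
      gn <- sqrt(sum(.flatten_grads(gr)^2))
      if (is.finite(gn) && gn > cfg$grad_clip) {
        sc <- cfg$grad_clip / gn
        gr <- rapply(gr, function(x) x * sc, how = "replace")
      }
      step <- step + 1L
      r <- .adam_step(params, gr, st, cfg$lr, step, upd_names)
      params <- r$p; st <- r$st
    }
    loss_trace <- c(loss_trace, ep_loss / nb)
  }
  list(params = params, adam = st, loss_trace = loss_trace)
}

#' Fit the origin classifier
#'
#' Trains the directed message-passing encoder and feed-forward head
#' jointly with a three-class cross-entropy objective. Deterministic given
#' `config$seed`: the same data and config reproduce the weights exactly.
#'
#' @param ds an [mnp_dataset] with at least two classes present (use
#'   [pretrain] / [finetune] for the two-stage scheme).
#' @param config an [mpnn_config].
#' @param feats optional pre-computed [featurize_dataset] output for `ds`
#'   (keyed by id); avoids re-parsing in repeated-training workflows.
#' @param init optional `"mnp_mpnn"` model whose weights seed the fit.
#' @param frozen if `TRUE`, encoder weights are not updated (head-only
#'   training).
#' @return an object of class `"mnp_mpnn"` with elements `params`,
#'   `config`, `loss_trace`, `stage`, `n_train`.
#' @export
mnp_mpnn <- function(ds, config = mpnn_config(), feats = NULL,
                     init = NULL, frozen = FALSE) {
  stopifnot(inherits(ds, "mnp_dataset"), inherits(config, "mpnn_config"))
  if (length(ds) == 0) stop("empty training dataset", call. = FALSE)
  feats <- feats %||% featurize_dataset(ds)
  feats <- feats[ds$records$id]
  labels <- ds$records$label
  res <- with_seed(derive_seed(config$seed, "mpnn-fit"), {
    params <- if (is.null(init)) .init_params(config) else init$params
    .train_loop(params, feats, labels, config, frozen = frozen)
  })
  structure(list(params = res$params, config = config,
                 loss_trace = res$loss_trace,
                 stage = if (frozen) "finetune" else "fit",
                 frozen = frozen, n_train = length(ds),
                 class_counts = class_counts(ds)),
            class = "mnp_mpnn")
}

#' Pretrain on Animalia plus an equal-sized microbial subset
#'
#' Builds the pretraining set from all Animalia records plus a seeded
#' uniform sample of the microbial pool of equal size (so the combined set
#' is twice the Animalia count), then trains encoder and head jointly. If
#' the pool is smaller than the Animalia set, the whole pool is used with a
#' warning.
#'
#' @param animalia [mnp_dataset] of Animalia-labeled compounds.
#' @param microbial_pool [mnp_dataset] of microbial (label 1/2) reference
#'   compounds.
#' @param config an [mpnn_config].
#' @param feats optional featurization cache covering both datasets.
#' @return an `"mnp_mpnn"` model (`stage = "pretrain"`), with the sampled
#'   microbial ids in `$pretrain_microbial_ids`.
#' @export
pretrain <- function(animalia, microbial_pool, config = mpnn_config(),
                     feats = NULL) {
  stopifnot(inherits(animalia, "mnp_dataset"),
            inherits(microbial_pool, "mnp_dataset"))
  if (length(animalia) == 0 || length(microbial_pool) == 0)
    stop("pretrain needs non-empty Animalia and microbial datasets",
         call. = FALSE)
  n <- length(animalia)
  pool_ids <- microbial_pool$records$id
  take <- if (length(pool_ids) >= n) {
    with_seed(derive_seed(config$seed, "pretrain-sample"),
              sample(pool_ids, n))
  } else {
    warning("microbial pool (", length(pool_ids),
            ") smaller than Animalia set (", n, "); using the whole pool")
    pool_ids
  }
  comb <- mnp_dataset(
    c(animalia$records$id, take),
    c(animalia$records$smiles,
      microbial_pool$records$smiles[match(take, pool_ids)]),
    c(animalia$records$label,
      microbial_pool$records$label[match(take, pool_ids)]),
    canonicalize = FALSE)
  model <- mnp_mpnn(comb, config, feats = feats)
  model$stage <- "pretrain"
  model$pretrain_microbial_ids <- sort(take)
  model
}

#' Fine-tune with a frozen encoder
#'
#' Continues training on `train` with the encoder weights frozen
#' (bit-identical before and after); only the feed-forward head is updated.
#' Freezing prevents the encoder from overfitting to noisy labels in the
#' smaller fine-tuning set.
#'
#' @param model a fitted `"mnp_mpnn"` (typically from [pretrain]).
#' @param train an [mnp_dataset].
#' @param config optional [mpnn_config] for the fine-tuning stage
#'   (defaults to the model's config).
#' @param feats optional featurization cache for `train`.
#' @return an `"mnp_mpnn"` with updated head weights only.
#' @export
finetune <- function(model, train, config = NULL, feats = NULL) {
  stopifnot(inherits(model, "mnp_mpnn"))
  cfg <- config %||% model$config
  out <- mnp_mpnn(train, cfg, feats = feats, init = model, frozen = TRUE)
  stopifnot(identical(out$params$W_i, model$params$W_i),
            identical(out$params$W_h, model$params$W_h),
            identical(out$params$W_o, model$params$W_o))
  out$stage <- "finetune"
  out
}

#' Predict from a fitted origin model
#'
#' @param object an `"mnp_mpnn"`.
#' @param newdata an [mnp_dataset] or character vector of SMILES.
#' @param type `"prob"` (class-probability matrix), `"class"` (hard labels
#'   0/1/2), `"mpn"` (molecule embeddings read out from the message-passing
#'   encoder) or `"last_ffn"` (activation of the head's last hidden layer).
#' @param feats optional featurization cache.
#' @param ... ignored.
#' @return matrix (rows = compounds) or integer vector for `"class"`.
#' @export
predict.mnp_mpnn <- function(object, newdata, type = c("prob", "class",
                                                       "mpn", "last_ffn"),
                             feats = NULL, ...) {
  type <- match.arg(type)
  ids <- if (inherits(newdata, "mnp_dataset")) newdata$records$id
         else names(newdata) %||% paste0("q", seq_along(newdata))
  feats <- feats %||% featurize_dataset(newdata)
  if (inherits(newdata, "mnp_dataset")) feats <- feats[newdata$records$id]
  out <- NULL
  for (start in seq(1, length(feats), by = 512)) {
    idx <- start:min(start + 511, length(feats))
    b <- .batch_graphs(feats[idx])
    fw <- .forward(object$params, b, object$config)
    piece <- switch(type,
      prob = fw$probs,
      class = fw$probs,
      mpn = fw$G,
      last_ffn = fw$Fa[[object$config$ffn_layers]])
    out <- rbind(out, piece)
  }
  rownames(out) <- ids
  if (type == "class") {
    cls <- max.col(out, ties.method = "first") - 1L
    return(setNames(as.integer(cls), ids))
  }
  if (type == "prob") colnames(out) <- c("0", "1", "2")
  out
}

#' Extract an embedding table
#'
#' @param model a fitted `"mnp_mpnn"`.
#' @param ds an [mnp_dataset].
#' @param kind `"mpn"` or `"last_ffn"`.
#' @param feats optional featurization cache.
#' @return numeric matrix (compounds x dim) with the representation kind in
#'   `attr(, "kind")`.
#' @export
extract_embeddings <- function(model, ds, kind = c("last_ffn", "mpn"),
                               feats = NULL) {
  kind <- match.arg(kind)
  emb <- predict(model, ds, type = kind, feats = feats)
  attr(emb, "kind") <- kind
  emb
}

#' @export
print.mnp_mpnn <- function(x, ...) {
  cat("<mnp_mpnn> stage:", x$stage,
      " hidden:", x$config$hidden_dim,
      " T:", x$config$message_steps,
      " trained on", x$n_train, "compounds\n")
  if (length(x$loss_trace))
    cat("  final training loss:", round(tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.mnp_mpnn <- function(object, ...) {
  cat("Origin classifier (directed message-passing encoder + FFN head)\n")
  cat("  stage:        ", object$stage, "\n")
  cat("  hidden_dim:   ", object$config$hidden_dim, "\n")
  cat("  message steps:", object$config$message_steps, "\n")
  cat("  parameters:   ", length(.flatten_grads(object$params)), "\n")
  cat("  training set: ", object$n_train, " (",
      paste(object$class_counts, collapse = "/"), ")\n", sep = "")
  cat("  epochs:       ", length(object$loss_trace), "\n")
  if (length(object$loss_trace))
    cat("  loss: first ", round(object$loss_trace[1], 4), " -> final ",
        round(tail(object$loss_trace, 1), 4), "\n", sep = "")
  invisible(object)
}

#' @export
coef.mnp_mpnn <- function(object, ...) object$params

#' @export
plot.mnp_mpnn <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "mean cross-entropy",
       main = "Training loss", ...)
  invisible(x)
}

.map4_env <- new.env(parent = emptyenv())

#' MinHashed atom-pair fingerprint
#'
#' A MAP4-style descriptor: circular atom environments (Morgan identifiers
#' at radii 1 and 2) are paired across all atom pairs, keyed by their
#' topological distance, and the resulting shingle set is MinHashed into
#' `dims` slots. Single-atom molecules hash their singleton environment
#' (distance 0 to itself). Deterministic and invariant to SMILES rewriting.
#'
#' @param smiles character vector of SMILES.
#' @param dims fingerprint length (default 1024).
#' @return numeric vector (one SMILES) or matrix of MinHash values.
#' @export
map4like_fp <- function(smiles, dims = 1024) {
  p <- 2097143
  key <- as.character(dims)
  if (is.null(.map4_env[[key]])) {
    .map4_env[[key]] <- with_seed(990331, list(
      a = sample(p - 1, dims, replace = TRUE),
      b = sample(p, dims, replace = TRUE) - 1))
  }
  ab <- .map4_env[[key]]
  graphs <- mol_graph_batch(smiles)
  M <- matrix(0, length(graphs), dims)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    ids <- .morgan_identifiers(g, 2)
    env1 <- ids[[2]]; env2 <- ids[[3]]
    if (length(env1) == 0) { env1 <- ids[[1]]; env2 <- ids[[1]] }
    D <- .topo_dist(g)
    sh <- character(0)
    n <- g$n_atoms
    if (n >= 2) {
      pr <- which(upper.tri(D) & D > 0, arr.ind = TRUE)
      for (r in 1:2) {
        e <- if (r == 1) env1 else env2
        a_ <- pmin(e[pr[, 1]], e[pr[, 2]]); b_ <- pmax(e[pr[, 1]], e[pr[, 2]])
        sh <- c(sh, paste0(a_, "|", D[pr], "|", b_))
      }
    }
    if (length(sh) == 0)
      sh <- paste0(env2, "|0|", env2)   # singleton sentinel shingles
    s <- vapply(unique(sh), hash_string, numeric(1), USE.NAMES = FALSE)
    hm <- outer(s %% p, ab$a) + rep(ab$b, each = length(s))
    M[i, ] <- apply(hm %% p, 2, min)
  }
  rownames(M) <- names(smiles)
  if (length(smiles) == 1) M[1, ] else M
}
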