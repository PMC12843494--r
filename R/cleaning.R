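## Two-step misannotation cleaning:
##   step 1 — repeated cross-prediction: train on a random Animalia subset +
##   all microbial compounds, predict the held-out Animalia out-of-fold,
##   average each compound's OOF class probabilities across cycles and flag
##   it when the averaged prediction is not Animalia;
##   step 2 — embedding-space neighborhood filter: remove Animalia points
##   lying within a radius of any microbial point.
## Only Animalia labels are screened: the asymmetry encodes the trust
## structure of the annotation problem (microbial origins usually rest on
## direct isolation; animal-host attributions are inference-prone).

#' Build a cleaning report
#'
#' @param step1_flagged ids flagged by [cross_prediction_screen].
#' @param step2_removed ids removed by [neighborhood_filter] (must be
#'   Animalia ids that survived step 1).
#' @param n_animalia number of Animalia-labeled compounds screened.
#' @param cycles,subset_fraction,radius,seed settings used.
#' @param oof_log per-cycle OOF probability log (data frame `id, cycle,
#'   p0, p1, p2`).
#' @param mean_confidence per-id averaged OOF probabilities.
#' @return object of class `"mnp_cleaning"`.
#' @export
cleaning_report <- function(step1_flagged, step2_removed = character(0),
                            n_animalia = NA_integer_, cycles = NA_integer_,
                            subset_fraction = NA_real_, radius = NA_real_,
                            seed = NA_integer_, oof_log = NULL,
                            mean_confidence = NULL) {
  step1_flagged <- sort(unique(as.character(step1_flagged)))
  step2_removed <- sort(unique(as.character(step2_removed)))
  if (length(intersect(step2_removed, step1_flagged)))
    stop("step2_removed must be disjoint from step-1 flags: step 2 runs on ",
         "the data surviving step 1", call. = FALSE)
  structure(list(step1_flagged = step1_flagged,
                 step2_removed = step2_removed,
                 n_animalia = as.integer(n_animalia),
                 cycles = as.integer(cycles),
                 subset_fraction = subset_fraction, radius = radius,
                 seed = seed, oof_log = oof_log,
                 mean_confidence = mean_confidence),
            class = "mnp_cleaning")
}

#' @export
print.mnp_cleaning <- function(x, ...) {
  cat("<mnp_cleaning> step 1 flagged:", length(x$step1_flagged),
      " step 2 removed:", length(x$step2_removed), "\n")
  invisible(x)
}

#' Summarize a cleaning report
#'
#' @param object an `"mnp_cleaning"` report.
#' @param ... ignored.
#' @return invisibly, a list with `n_flagged`, `n_removed`, `n_animalia`,
#'   and `flag_rate` — the step-1 flag rate as a percentage of screened
#'   Animalia compounds, half-up rounded to one decimal.
#' @export
summary.mnp_cleaning <- function(object, ...) {
  rate <- if (is.na(object$n_animalia) || object$n_animalia == 0) NA_real_
          else round_half_up(100 * length(object$step1_flagged) /
                               object$n_animalia, 1)
  cat("Two-step cleaning report\n")
  cat("  Animalia screened:   ", object$n_animalia, "\n")
  cat("  step 1 flagged:      ", length(object$step1_flagged),
      if (!is.na(rate)) paste0(" (", rate, "%)"), "\n", sep = "")
  cat("  step 2 removed:      ", length(object$step2_removed), "\n")
  cat("  cycles: ", object$cycles, "  subset_fraction: ",
      object$subset_fraction, "  radius: ", object$radius, "\n", sep = "")
  invisible(list(n_flagged = length(object$step1_flagged),
                 n_removed = length(object$step2_removed),
                 n_animalia = object$n_animalia, flag_rate = rate))
}

#' Model-factory trainer backed by the message-passing classifier
#'
#' Returns a trainer satisfying the [cross_prediction_screen] contract: a
#' function `(train_ds, seed)` producing a fresh fitted model's prediction
#' closure. A shared featurization cache avoids re-parsing molecules across
#' cycles.
#'
#' @param config an [mpnn_config]; its seed is replaced by the per-cycle
#'   seed.
#' @param feats optional featurization cache covering every compound the
#'   screen will see.
#' @return function `(train_ds, seed) -> function(eval_ds) -> probability
#'   matrix`.
#' @export
mpnn_trainer <- function(config = mpnn_config(hidden_dim = 64), feats = NULL) {
  force(config); force(feats)
  function(train_ds, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    model <- mnp_mpnn(train_ds, cfg, feats = feats)
    function(eval_ds) predict(model, eval_ds, type = "prob", feats = feats)
  }
}

#' Truth-table oracle trainer
#'
#' A diagnostic trainer that ignores the training data and predicts each
#' compound's known true label with probability one. Plugged into
#' [cross_prediction_screen], it must recover exactly the planted label
#' flips (and flag nothing on noise-free data).
#'
#' @param truth named integer vector: compound id -> true label.
#' @return a trainer with the same contract as [mpnn_trainer].
#' @export
oracle_trainer <- function(truth) {
  force(truth)
  function(train_ds, seed) {
    function(eval_ds) {
      ids <- eval_ds$records$id
      if (anyNA(truth[ids])) stop("oracle has no truth for some ids")
      P <- matrix(0, length(ids), 3, dimnames = list(ids, c("0", "1", "2")))
      P[cbind(seq_along(ids), truth[ids] + 1L)] <- 1
      P
    }
  }
}

#' Cross-prediction misannotation screen (cleaning step 1)
#'
#' Runs `cycles` train/predict rounds. In each round a random fraction
#' `subset_fraction` of the Animalia compounds joins all microbial
#' compounds as the training set; the remaining Animalia are predicted
#' out-of-fold. Each Animalia compound's OOF probability vectors are
#' averaged across the cycles in which it was held out, and the compound is
#' flagged when the averaged prediction is not Animalia (argmax of the mean
#' vector, ties resolved conservatively toward Animalia). Microbial
#' compounds are never flagged.
#'
#' With `coverage = "strict"` (default) the holdouts are scheduled so every
#' Animalia compound is out-of-fold at least once; if that is impossible
#' for the requested cycle count the error states the minimal feasible
#' count. `"independent"` draws each cycle's subset independently.
#'
#' @param ds an [mnp_dataset] containing all three labels.
#' @param trainer model factory: `function(train_ds, seed)` returning a
#'   prediction closure (see [mpnn_trainer], [oracle_trainer]).
#' @param cycles number of rounds (default 10).
#' @param subset_fraction Animalia fraction entering each round's training
#'   set, strictly between 0 and 1 (default 0.5).
#' @param seed integer seed; the whole screen is deterministic given it.
#' @param coverage `"strict"` or `"independent"`.
#' @return an `"mnp_cleaning"` report with `step1_flagged`, the per-cycle
#'   `oof_log` and per-id `mean_confidence`.
#' @export
cross_prediction_screen <- function(ds, trainer, cycles = 10,
                                    subset_fraction = 0.5, seed = 1,
                                    coverage = c("strict", "independent")) {
  coverage <- match.arg(coverage)
  stopifnot(inherits(ds, "mnp_dataset"), is.function(trainer))
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  if (!(subset_fraction > 0 && subset_fraction < 1))
    stop("subset_fraction must be strictly between 0 and 1", call. = FALSE)
  labs <- ds$records$label
  if (!all(0:2 %in% labs))
    stop("screening needs all three classes present", call. = FALSE)
  ani <- ds$records$id[labs == 0L]
  micro <- ds$records$id[labs != 0L]
  nA <- length(ani)
  h <- max(1L, as.integer(floor((1 - subset_fraction) * nA + 0.5)))
  if (coverage == "strict" && cycles * h < nA)
    stop("full out-of-fold coverage impossible: ", cycles, " cycles x ", h,
         " held out < ", nA, " Animalia compounds; need at least ",
         ceiling(nA / h), " cycles", call. = FALSE)
  holdouts <- with_seed(derive_seed(seed, "screen-schedule"), {
    if (coverage == "independent") {
      lapply(seq_len(cycles), function(i) sample(ani, h))
    } else {
      uncovered <- ani
      lapply(seq_len(cycles), function(i) {
        take <- if (length(uncovered) >= h) sample(uncovered, h)
                else c(uncovered, sample(setdiff(ani, uncovered),
                                         h - length(uncovered)))
        uncovered <<- setdiff(uncovered, take)
        take
      })
    }
  })
  logs <- vector("list", cycles)
  for (cyc in seq_len(cycles)) {
    hold <- holdouts[[cyc]]
    train_ids <- c(setdiff(ani, hold), micro)
    cyc_seed <- derive_seed(seed, paste0("screen-cycle", cyc))
    model <- trainer(ds[train_ids], cyc_seed)
    P <- model(ds[hold])
    logs[[cyc]] <- data.frame(id = hold, cycle = cyc,
                              p0 = P[, 1], p1 = P[, 2], p2 = P[, 3],
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  oof <- do.call(rbind, logs)
  mean_conf <- aggregate(oof[c("p0", "p1", "p2")], by = list(id = oof$id),
                         FUN = mean)
  n_oof <- as.integer(table(oof$id)[mean_conf$id])
  pm <- as.matrix(mean_conf[c("p0", "p1", "p2")])
  ## conservative tie-break: a compound is flagged only when a microbial
  ## class strictly dominates the Animalia probability
  flag <- pm[, 2] > pm[, 1] | pm[, 3] > pm[, 1]
  mean_conf$n_oof <- n_oof
  mean_conf$flagged <- flag
  cleaning_report(step1_flagged = mean_conf$id[flag],
                  n_animalia = nA, cycles = cycles,
                  subset_fraction = subset_fraction, seed = seed,
                  oof_log = oof, mean_confidence = mean_conf)
}

## ---- kd-tree spatial index -------------------------------------------------

.kd_build <- function(P, idx, depth, leaf_size = 16L) {
  if (length(idx) <= leaf_size) return(list(leaf = TRUE, idx = idx))
  ax <- (depth %% ncol(P)) + 1L
  v <- P[idx, ax]
  med <- stats::median(v)
  left <- idx[v <= med]; right <- idx[v > med]
  if (length(left) == 0 || length(right) == 0)
    return(list(leaf = TRUE, idx = idx))   # degenerate split: stop here
  list(leaf = FALSE, axis = ax, thresh = med,
       left = .kd_build(P, left, depth + 1L, leaf_size),
       right = .kd_build(P, right, depth + 1L, leaf_size))
}

## TRUE iff any indexed point lies strictly within radius r of x
.kd_within <- function(node, P, x, r) {
  if (node$leaf) {
    if (!length(node$idx)) return(FALSE)
    d2 <- colSums((t(P[node$idx, , drop = FALSE]) - x)^2)
    return(any(d2 < r^2))
  }
  delta <- x[node$axis] - node$thresh
  first <- if (delta <= 0) node$left else node$right
  second <- if (delta <= 0) node$right else node$left
  if (.kd_within(first, P, x, r)) return(TRUE)
  if (abs(delta) < r) return(.kd_within(second, P, x, r))
  FALSE
}

#' Embedding-neighborhood filter (cleaning step 2)
#'
#' Removes Animalia-labeled compounds lying strictly within `radius`
#' (Euclidean) of any microbial compound in embedding space. The removed
#' set is defined by the brute-force predicate
#' `{ id : label(id) = 0 and exists microbial j with d(id, j) < radius }`
#' and computed with a kd-tree index over the microbial points.
#'
#' The default radius 5.0 matches the production workflow's threshold on
#' raw last-FFN embeddings, but any fixed radius is scale-dependent;
#' `radius = "auto"` instead sets it to a quantile (default 1%) of the
#' pairwise embedding-distance distribution.
#'
#' @param emb embedding matrix with compound ids as rownames.
#' @param labels named integer vector id -> label, covering `emb`'s rows.
#' @param radius non-negative numeric, or `"auto"`.
#' @param auto_quantile distance-distribution quantile for `"auto"`.
#' @return sorted character vector of removed Animalia ids (empty for an
#'   empty table, radius 0, or no microbial points).
#' @export
neighborhood_filter <- function(emb, labels, radius = 5.0,
                                auto_quantile = 0.01) {
  if (is.null(emb) || nrow(emb) == 0) return(character(0))
  stopifnot(!is.null(rownames(emb)))
  labels <- labels[rownames(emb)]
  if (anyNA(labels)) stop("labels missing for some embedded ids", call. = FALSE)
  if (identical(radius, "auto")) {
    radius <- as.numeric(quantile(dist(emb), auto_quantile))
  }
  stopifnot(is.numeric(radius), radius >= 0)
  if (radius == 0) return(character(0))
  ani <- which(labels == 0L)
  micro <- which(labels != 0L)
  if (!length(ani) || !length(micro)) return(character(0))
  P <- emb[micro, , drop = FALSE]
  tree <- .kd_build(P, seq_len(nrow(P)), 0L)
  hit <- vapply(ani, function(i) .kd_within(tree, P, emb[i, ], radius),
                logical(1))
  sort(rownames(emb)[ani[hit]])
}

#' Apply a cleaning report to a dataset
#'
#' Drops the union of step-1 flags and step-2 removals; microbial records
#' are untouched by construction (only Animalia ids are ever flagged).
#'
#' @param ds an [mnp_dataset].
#' @param report an `"mnp_cleaning"` report whose ids all occur in `ds`.
#' @return the cleaned [mnp_dataset].
#' @export
apply_cleaning <- function(ds, report) {
  stopifnot(inherits(ds, "mnp_dataset"), inherits(report, "mnp_cleaning"))
  drop <- union(report$step1_flagged, report$step2_removed)
  unknown <- setdiff(drop, ds$records$id)
  if (length(unknown))
    stop("cleaning report references unknown id(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  ds[setdiff(ds$records$id, drop)]
}
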