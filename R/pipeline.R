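## End-to-end orchestration: simulate -> profile -> pretrain -> fine-tune ->
## two-step clean -> retrain -> evaluate -> interpret, with one global seed,
## a content-addressed run directory and a JSON metrics report.

#' Pipeline configuration
#'
#' Every random stage derives its seed deterministically from the single
#' global `seed`; data specs not supplied explicitly are built from it.
#' Default study conditions: 200/100/100 training compounds with 8%
#' microbial-to-Animalia label noise, a 150+150 microbial pretraining pool,
#' a noise-free 60/30/30 test set, a 64-unit encoder, 10 screening cycles
#' at subset fraction 0.5, and the auto (distance-quantile) neighborhood
#' radius.
#'
#' @param out_dir parent directory for run artifacts.
#' @param seed global integer seed.
#' @param train_spec,test_spec,pool_spec optional [synthetic_spec]s.
#' @param encoder an [mpnn_config].
#' @param cycles,subset_fraction step-1 screening settings.
#' @param radius step-2 radius (numeric or `"auto"`).
#' @param stages named logical list toggling `profile`, `clean`,
#'   `interpret`.
#' @param n_interpret compounds to run rationale extraction on.
#' @param mcts an [mcts_config].
#' @param overwrite allow writing into an existing run directory.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "runs", seed = 1,
                            train_spec = NULL, test_spec = NULL,
                            pool_spec = NULL,
                            encoder = mpnn_config(hidden_dim = 64,
                                                  epochs = 20, seed = 1),
                            cycles = 10, subset_fraction = 0.5,
                            radius = "auto",
                            stages = list(profile = TRUE, clean = TRUE,
                                          interpret = TRUE),
                            n_interpret = 6, mcts = mcts_config(),
                            overwrite = FALSE) {
  seed <- as.integer(seed)
  cfg <- list(
    out_dir = out_dir, seed = seed,
    train_spec = train_spec %||%
      synthetic_spec(200, 100, 100, noise_rate = 0.08,
                     seed = derive_seed(seed, "train-data"),
                     id_prefix = "tr_"),
    test_spec = test_spec %||%
      synthetic_spec(60, 30, 30, noise_rate = 0,
                     seed = derive_seed(seed, "test-data"),
                     id_prefix = "te_"),
    pool_spec = pool_spec %||%
      synthetic_spec(0, 150, 150, noise_rate = 0,
                     seed = derive_seed(seed, "pool-data"),
                     id_prefix = "po_"),
    encoder = encoder, cycles = cycles,
    subset_fraction = subset_fraction, radius = radius,
    stages = utils::modifyList(list(profile = TRUE, clean = TRUE,
                                    interpret = TRUE), stages),
    n_interpret = n_interpret, mcts = mcts, overwrite = overwrite)
  class(cfg) <- "pipeline_config"
  cfg
}

.config_hash <- function(cfg) {
  x <- cfg[setdiff(names(cfg), c("out_dir", "overwrite"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(x), collapse = ""), tf)
  substr(unname(tools::md5sum(tf)), 1, 8)
}

.eval_models <- function(model, train_emb, test_emb, y_train, y_test,
                         test_probs, seed) {
  out <- list()
  cm <- confusion(y_test, max.col(test_probs) - 1L)
  out$gcn <- table_report(cm)
  for (kind in c("svm", "gbt")) {
    head <- train_head(train_emb, y_train, kind = kind, seed = seed)
    p <- predict(head, test_emb)
    out[[kind]] <- table_report(confusion(y_test, max.col(p) - 1L))
  }
  out
}

#' Run the full workflow
#'
#' Executes the pipeline stages in the enforced order; in particular, the
#' step-2 neighborhood filter always uses embeddings from a model retrained
#' on the step-1-cleaned data. Artifacts (datasets, truth table, cleaning
#' report, per-model metric tables, rationale tables, run log) are written
#' to a run directory addressed by a hash of the configuration; an existing
#' run directory is never silently overwritten.
#'
#' @param cfg a [pipeline_config].
#' @return the run directory path, invisibly; its `metrics.json` holds the
#'   evaluation and cleaning summaries.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  run_dir <- file.path(cfg$out_dir, paste0("run-", .config_hash(cfg)))
  if (dir.exists(run_dir) && !cfg$overwrite)
    stop("run directory ", run_dir,
         " already exists (content-addressed by config); ",
         "set overwrite = TRUE to redo it", call. = FALSE)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste("mnporigin", as.character(utils::packageVersion("mnporigin"))),
                 paste("R", getRversion()), paste("seed", cfg$seed),
                 paste("started", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name),
                   conditionMessage(e)), file.path(run_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  metrics <- list(seed = cfg$seed)

  ## -- simulate ---------------------------------------------------------
  truth_ds <- noisy <- NULL
  stage("simulate", {
    truth_ds <- generate_dataset(cfg$train_spec)
    nz <- inject_label_noise(truth_ds, cfg$train_spec$noise_rate,
                             seed = derive_seed(cfg$seed, "noise"))
    noisy <- nz$dataset
    planted <- nz$flipped
    test_ds <- generate_dataset(cfg$test_spec)
    pool_ds <- generate_dataset(cfg$pool_spec)
    write_dataset(noisy, file.path(run_dir, "train.csv"))
    write_dataset(test_ds, file.path(run_dir, "test.csv"))
    truth <- data.frame(id = truth_ds$records$id,
                        true_label = truth_ds$records$true_label,
                        planted_flag = truth_ds$records$id %in% planted)
    write.csv(truth, file.path(run_dir, "truth.csv"), row.names = FALSE)
  })

  ## -- profile ----------------------------------------------------------
  if (isTRUE(cfg$stages$profile)) stage("profile", {
    write.csv(physchem_profile(noisy),
              file.path(run_dir, "physchem.csv"), row.names = FALSE)
    tops <- top_scaffolds(noisy)
    scafs <- do.call(rbind, lapply(names(tops), function(k)
      cbind(class = k, tops[[k]])))
    write.csv(scafs, file.path(run_dir, "top_scaffolds.csv"),
              row.names = FALSE)
    scaff_all <- murcko_scaffold(noisy$records$smiles)
    sets <- split(scaff_all[nzchar(scaff_all)],
                  noisy$records$label[nzchar(scaff_all)])
    names(sets) <- as.character(names(sets))
    full <- setNames(vector("list", 3), c("0", "1", "2"))
    for (k in names(full)) full[[k]] <- unique(sets[[k]] %||% character(0))
    jsonlite::write_json(as.list(overlap_counts(full)),
                         file.path(run_dir, "scaffold_venn.json"),
                         auto_unbox = TRUE)
  })

  ## -- featurize + pretrain + fine-tune ---------------------------------
  feats <- model_raw <- NULL
  stage("pretrain", {
    all_smi <- c(setNames(noisy$records$smiles, noisy$records$id),
                 setNames(test_ds$records$smiles, test_ds$records$id),
                 setNames(pool_ds$records$smiles, pool_ds$records$id))
    feats <- featurize_dataset(all_smi[!duplicated(names(all_smi))])
    enc <- cfg$encoder
    enc$seed <- derive_seed(cfg$seed, "encoder")
    ani <- noisy[noisy$records$id[noisy$records$label == 0L]]
    pre <- pretrain(ani, pool_ds, enc, feats = feats)
    model_raw <- finetune(pre, noisy, feats = feats)
  })

  ## -- evaluate on the raw (noisy) training regime ----------------------
  y_test <- test_ds$records$true_label
  stage("evaluate-raw", {
    emb_tr <- extract_embeddings(model_raw, noisy, "last_ffn", feats = feats)
    emb_te <- extract_embeddings(model_raw, test_ds, "last_ffn", feats = feats)
    probs <- predict(model_raw, test_ds, type = "prob", feats = feats)
    metrics$raw <- .eval_models(model_raw, emb_tr, emb_te,
                                 noisy$records$label, y_test, probs,
                                 derive_seed(cfg$seed, "heads-raw"))
  })

  ## -- two-step cleaning ------------------------------------------------
  cleaned <- noisy
  if (isTRUE(cfg$stages$clean)) stage("clean", {
    enc <- cfg$encoder
    trainer <- mpnn_trainer(enc, feats = feats)
    rep1 <- cross_prediction_screen(noisy, trainer, cycles = cfg$cycles,
                                    subset_fraction = cfg$subset_fraction,
                                    seed = derive_seed(cfg$seed, "screen"))
    step1_ds <- apply_cleaning(noisy, rep1)
    ## step 2 on embeddings from a model retrained on step-1 output
    enc2 <- enc; enc2$seed <- derive_seed(cfg$seed, "retrain-step1")
    model_s1 <- finetune(pre, step1_ds, config = enc2, feats = feats)
    emb <- extract_embeddings(model_s1, step1_ds, "last_ffn", feats = feats)
    removed <- neighborhood_filter(
      emb, setNames(step1_ds$records$label, step1_ds$records$id),
      radius = cfg$radius)
    report <- cleaning_report(
      step1_flagged = rep1$step1_flagged, step2_removed = removed,
      n_animalia = rep1$n_animalia, cycles = cfg$cycles,
      subset_fraction = cfg$subset_fraction,
      radius = if (identical(cfg$radius, "auto")) NA_real_ else cfg$radius,
      seed = cfg$seed, oof_log = rep1$oof_log,
      mean_confidence = rep1$mean_confidence)
    cleaned <- apply_cleaning(noisy, report)
    write_dataset(cleaned, file.path(run_dir, "train_cleaned.csv"))
    write.csv(report$oof_log, file.path(run_dir, "oof_log.csv"),
              row.names = FALSE)
    tp <- length(intersect(report$step1_flagged, planted))
    prec <- if (length(report$step1_flagged))
      tp / length(report$step1_flagged) else 0
    rec <- if (length(planted)) tp / length(planted) else 1
    metrics$cleaning <- list(
      step1_flagged = length(report$step1_flagged),
      step2_removed = length(report$step2_removed),
      n_animalia_screened = report$n_animalia,
      planted_flips = length(planted),
      step1_precision = prec, step1_recall = rec,
      step1_f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    jsonlite::write_json(
      c(metrics$cleaning,
        list(step1_ids = report$step1_flagged,
             step2_ids = report$step2_removed)),
      file.path(run_dir, "cleaning_report.json"), auto_unbox = TRUE)
  }) else metrics$cleaning <- list(skipped = TRUE)

  ## -- retrain on cleaned data and evaluate -----------------------------
  model_final <- NULL
  stage("evaluate-cleaned", {
    enc3 <- cfg$encoder; enc3$seed <- derive_seed(cfg$seed, "retrain-final")
    model_final <- finetune(pre, cleaned, config = enc3, feats = feats)
    emb_tr <- extract_embeddings(model_final, cleaned, "last_ffn",
                                 feats = feats)
    emb_te <- extract_embeddings(model_final, test_ds, "last_ffn",
                                 feats = feats)
    probs <- predict(model_final, test_ds, type = "prob", feats = feats)
    metrics$cleaned_pretrained <- .eval_models(
      model_final, emb_tr, emb_te, cleaned$records$label, y_test, probs,
      derive_seed(cfg$seed, "heads-final"))
  })

  ## -- interpret --------------------------------------------------------
  if (isTRUE(cfg$stages$interpret)) stage("interpret", {
    pick <- unlist(lapply(0:2, function(k) {
      ids <- cleaned$records$id[cleaned$records$label == k]
      head(ids, ceiling(cfg$n_interpret / 3))
    }))
    rats <- extract_rationales(model_final, cleaned[pick], cfg$mcts)
    tabs <- aggregate_rationales(rats)
    flat <- do.call(rbind, lapply(names(tabs), function(k)
      if (nrow(tabs[[k]])) cbind(class = k, tabs[[k]]) else NULL))
    write.csv(flat %||% data.frame(), file.path(run_dir, "rationales.csv"),
              row.names = FALSE)
  })

  jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines,
               paste("finished", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(run_dir, "run_log.txt"))
  invisible(run_dir)
}
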