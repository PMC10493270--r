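#' Experiment specification
#'
#' Describes one cross-validated classification experiment: the 3-class task
#' or one of the three pairwise tasks, on a set of labeled recordings (or a
#' prebuilt dataset), with full configuration of every pipeline stage.
#'
#' @param classes Character vector of 2 or 3 distinct labels from
#'   [class_labels()].
#' @param recordings List of labeled [eeg_recording()] objects; ignored when
#'   `dataset` is given.
#' @param dataset Optional prebuilt `cpd_dataset` (skips preprocessing).
#' @param pre_cfg,ttm_cfg,sgcm_cfg,train_cfg Stage configurations; `NULL`
#'   selects defaults sized to the data.
#' @param graph Electrode graph; default [build_graph()].
#' @param k Fold count for subject-wise cross-validation.
#' @param folds Fold indices to actually train/evaluate (defaults to all
#'   `1:k`; a subset gives a scaled-down run).
#' @param seed Master seed (folds, initialization, shuffling).
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(classes, recordings = NULL, dataset = NULL,
                            pre_cfg = preprocess_config(), ttm_cfg = NULL,
                            sgcm_cfg = NULL, train_cfg = train_config(),
                            graph = build_graph(), k = 10, folds = NULL,
                            seed = 1) {
  classes <- as.character(classes)
  if (anyDuplicated(classes) || !length(classes) %in% c(2, 3)) {
    stop("classes must be 2 or 3 distinct labels")
  }
  if (is.null(dataset) && is.null(recordings)) {
    stop("provide recordings or a prebuilt dataset")
  }
  structure(list(classes = classes, recordings = recordings,
                 dataset = dataset, pre_cfg = pre_cfg, ttm_cfg = ttm_cfg,
                 sgcm_cfg = sgcm_cfg, train_cfg = train_cfg, graph = graph,
                 k = k, folds = folds %||% seq_len(k), seed = seed),
            class = "experiment_spec")
}

#' Run a cross-validated two-stage experiment
#'
#' For each requested fold: trains the TTM on the training subjects' CPD
#' maps (stage 1), freezes it, extracts per-segment node features, trains
#' the SGCM (stage 2) and evaluates on the held-out subjects. Fold metrics
#' are averaged across folds ("averaged over the ten test sets");
#' confusion matrices are summed. Subject exclusivity of every split is
#' asserted at run time.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Print fold progress.
#' @param keep_models Also store each fold's trained `ttm`/`sgcm` models in
#'   its fold result (off by default to keep results light).
#' @return An `experiment_result`: list with `fold_results`, `mean_metrics`
#'   (metrics averaged over folds), `confusion` (summed), `auc` (per-class,
#'   averaged), `stage1_best_macro_f1` and `stage2_macro_f1` (fold means),
#'   `fold_plan`, `classes`.
#' @export
run_experiment <- function(spec, verbose = FALSE, keep_models = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  dataset <- spec$dataset %||% build_cpd_dataset(spec$recordings,
                                                 spec$pre_cfg)
  keep <- dataset$meta$label %in% spec$classes
  dataset <- subset_dataset(dataset, which(keep))
  classes <- spec$classes
  ttm_cfg <- spec$ttm_cfg %||% ttm_config(input_dim = dataset$input_dim,
                                          n_classes = length(classes))
  sgcm_cfg <- spec$sgcm_cfg %||% sgcm_config(n_classes = length(classes))
  plan <- make_subject_folds(dataset$meta$subject_id, dataset$meta$label,
                             k = spec$k, seed = derive_seed(spec$seed, 1))
  fold_results <- list()
  for (fold in spec$folds) {
    test_subjects <- names(plan$assignments)[plan$assignments == fold]
    train_subjects <- setdiff(names(plan$assignments), test_subjects)
    stopifnot(length(intersect(train_subjects, test_subjects)) == 0)
    if (verbose) message("fold ", fold, ": ", length(test_subjects),
                         " test subjects")
    cfg1 <- spec$train_cfg
    cfg1$seed <- derive_seed(spec$seed, 2, fold)
    ttm <- ttm_init(ttm_cfg, seed = derive_seed(spec$seed, 3, fold))
    s1 <- train_stage1(ttm, dataset, cfg1, test_subjects = test_subjects,
                       classes = classes)
    nf <- extract_node_features(s1$model, dataset)
    sgcm <- sgcm_init(sgcm_cfg, d_in = ttm_cfg$embed_dim,
                      seed = derive_seed(spec$seed, 4, fold))
    s2 <- train_stage2(sgcm, nf, spec$graph, cfg1,
                       test_subjects = test_subjects, classes = classes)
    test_idx <- which(nf$meta$subject_id %in% test_subjects)
    logits <- predict_sgcm(s2$model, nf, spec$graph, test_idx)
    scores <- softmax_rows(logits)
    colnames(scores) <- classes
    y_true <- nf$meta$label[test_idx]
    y_pred <- classes[max.col(logits)]
    metrics <- compute_metrics(y_true, y_pred, labels = classes)
    auc <- if (length(unique(y_true)) >= 2) {
      roc_auc(y_true, scores, labels = classes)
    } else rep(NA_real_, length(classes))
    fold_results[[as.character(fold)]] <- c(
      list(fold = fold, test_subjects = test_subjects, metrics = metrics,
           auc = auc, channel_accuracy = s1$channel_accuracy,
           stage1_loss = s1$loss, stage2_loss = s2$loss),
      if (keep_models) list(ttm = s1$model, sgcm = s2$model))
  }
  summarize_experiment(fold_results, plan, classes)
}

summarize_experiment <- function(fold_results, plan, classes) {
  get <- function(f) vapply(fold_results, function(r) r$metrics[[f]],
                            numeric(1))
  mean_metrics <- list(accuracy = mean(get("accuracy")),
                       recall = mean(get("recall")),
                       precision = mean(get("precision")),
                       f1 = mean(get("f1")))
  confusion <- Reduce(`+`, lapply(fold_results,
                                  function(r) r$metrics$confusion))
  auc <- colMeans(do.call(rbind, lapply(fold_results, function(r) r$auc)),
                  na.rm = TRUE)
  best_ch <- mean(vapply(fold_results, function(r) {
    max(r$channel_accuracy$macro_f1)
  }, numeric(1)))
  structure(list(fold_results = fold_results, mean_metrics = mean_metrics,
                 confusion = confusion, auc = auc,
                 stage1_best_macro_f1 = best_ch,
                 stage2_macro_f1 = mean_metrics$f1,
                 fold_plan = plan, classes = classes),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> classes:", paste(x$classes, collapse = ", "),
      "| folds run:", length(x$fold_results), "\n")
  cat(sprintf(
    "mean accuracy %.4f | recall %.4f | precision %.4f | F1 %.4f\n",
    x$mean_metrics$accuracy, x$mean_metrics$recall,
    x$mean_metrics$precision, x$mean_metrics$f1))
  cat("per-class AUC:", paste(sprintf("%s %.3f", names(x$auc), x$auc),
                              collapse = ", "), "\n")
  cat("summed confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
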