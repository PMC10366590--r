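# End-to-end orchestration: manifest -> preprocess -> extract -> fit/predict
# per task, evaluation metrics with ROC, hyperparameter sweep, and model /
# report serialization.

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `path` and `label` (labels drawn from
#' AD/MCI/NC) and an optional `subject` column for grouped splitting; when
#' absent, each image is treated as its own subject. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame with columns `path`, `label`, `subject`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have columns 'path' and 'label'")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (is.null(m$subject))
    m$subject <- sub("\\.nii(\\.gz)?$", "", basename(m$path))
  m
}

#' Define a classification task
#'
#' @param name One of `"AD_vs_NC"`, `"AD_vs_MCI"`, `"MCI_vs_NC"`,
#'   `"three_class"`.
#' @param split_ratio Train fraction (default 0.7, i.e. a 0.7:0.3 split).
#' @param split_seed Seed of the stratified random split.
#' @param split_level `"subject"` (default; all scans of a subject stay on
#'   one side, avoiding subject leakage) or `"image"`.
#' @param positive Positive class for sensitivity/precision; defaults to AD
#'   for the AD tasks and MCI for MCI_vs_NC.
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(name = c("AD_vs_NC", "AD_vs_MCI", "MCI_vs_NC", "three_class"),
                      split_ratio = 0.7, split_seed = 0L,
                      split_level = c("subject", "image"), positive = NULL) {
  name <- match.arg(name)
  stopifnot(split_ratio > 0, split_ratio < 1)
  classes <- switch(name,
                    AD_vs_NC = c("AD", "NC"),
                    AD_vs_MCI = c("AD", "MCI"),
                    MCI_vs_NC = c("MCI", "NC"),
                    three_class = c("AD", "MCI", "NC"))
  positive <- positive %||% classes[1]
  if (!positive %in% classes) stop("positive class not part of the task")
  structure(list(name = name, classes = classes, positive = positive,
                 split_ratio = split_ratio, split_seed = as.integer(split_seed),
                 split_level = match.arg(split_level)),
            class = "task_spec")
}

#' Stratified train/test split
#'
#' Rows are restricted to the task's classes and split at `split_ratio`
#' within each class stratum using `split_seed`. At the default subject
#' level, whole subjects are assigned to one side, so no subject's scans
#' leak across the split; the partition is disjoint and exhaustive by
#' construction and asserted at run time.
#'
#' @param manifest Manifest data frame ([read_manifest()]).
#' @param task A [task_spec()].
#' @return List with data frames `train` and `test`.
#' @export
split_dataset <- function(manifest, task) {
  stopifnot(inherits(task, "task_spec"))
  m <- manifest[manifest$label %in% task$classes, , drop = FALSE]
  if (nrow(m) == 0L) stop("no manifest rows match the task classes")
  unit <- if (task$split_level == "subject") m$subject else as.character(seq_len(nrow(m)))
  train_units <- with_local_seed(task$split_seed, {
    unlist(lapply(task$classes, function(cl) {
      u <- unique(unit[m$label == cl])
      if (length(u) < 2L)
        stop("class ", cl, " has fewer than 2 ",
             task$split_level, " units; cannot split")
      sample(u, round(task$split_ratio * length(u)))
    }))
  })
  in_train <- unit %in% train_units
  train <- m[in_train, , drop = FALSE]
  test <- m[!in_train, , drop = FALSE]
  if (task$split_level == "subject" &&
      length(intersect(train$subject, test$subject)) > 0L)
    stop("internal error: subject leakage across the split")
  if (nrow(train) + nrow(test) != nrow(m))
    stop("internal error: split is not a partition")
  if (nrow(test) == 0L) stop("empty test set")
  list(train = train, test = test)
}

#' ROC curve and AUC from real-valued scores
#'
#' Sweeps the decision threshold over the positive-class scores; points run
#' from (0, 0) to (1, 1) and the AUC is the trapezoidal area.
#'
#' @param scores Numeric score of the positive class per sample.
#' @param truth Logical (or 0/1) vector, `TRUE` for positives.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L) stop("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

metric_or_zero <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator, reporting 0")
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' The confusion matrix has truth in rows and predictions in columns, with
#' the positive class first. For binary tasks: ACC = (TP+TN)/n, SEN =
#' TP/(TP+FN), SPEC = TN/(TN+FP), PREC = TP/(TP+FP), F1 = 2*PREC*SEN /
#' (PREC+SEN); zero denominators yield 0 with a warning. For multi-class
#' confusions only the accuracy is defined. If real-valued scores and truth
#' are supplied, the ROC curve and AUC are included.
#'
#' @param confusion Square integer matrix, truth x predicted.
#' @param scores Optional positive-class scores (binary only).
#' @param truth Optional logical truth vector matching `scores`.
#' @return A list of class `evaluation_metrics`.
#' @export
compute_metrics <- function(confusion, scores = NULL, truth = NULL) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  acc <- metric_or_zero(sum(diag(confusion)), n, "accuracy")
  out <- list(confusion = confusion, n = n, accuracy = acc,
              sensitivity = NA_real_, specificity = NA_real_,
              precision = NA_real_, f1 = NA_real_, roc = NULL, auc = NA_real_)
  if (nrow(confusion) == 2L) {
    tp <- confusion[1, 1]; fn <- confusion[1, 2]
    fp <- confusion[2, 1]; tn <- confusion[2, 2]
    sen <- metric_or_zero(tp, tp + fn, "sensitivity")
    spec <- metric_or_zero(tn, tn + fp, "specificity")
    prec <- metric_or_zero(tp, tp + fp, "precision")
    f1 <- if (prec + sen == 0) {
      warning("f1: zero denominator, reporting 0"); 0
    } else 2 * prec * sen / (prec + sen)
    out[c("sensitivity", "specificity", "precision", "f1")] <-
      list(sen, spec, prec, f1)
  }
  if (!is.null(scores) && !is.null(truth)) {
    r <- roc_curve(scores, truth)
    out$roc <- r$points
    out$auc <- r$auc
  }
  structure(out, class = "evaluation_metrics")
}

confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes))
}

feature_cache_key <- function(path, extractor, cfg) {
  paste(path, extractor$seed, extractor$init_scheme, extractor$stride_scheme,
        paste(extractor$channels, collapse = ","),
        cfg$target_spacing_mm, paste(cfg$crop_shape, collapse = ","),
        paste(cfg$intensity_range, collapse = ","), sep = "|")
}

#' Preprocess and extract deep features for every manifest row
#'
#' The extractor is frozen, so features are a pure function of (file,
#' extractor, preprocessing config); an optional environment caches them
#' across calls, which makes sweeps and repeated splits cheap.
#'
#' @param manifest Manifest data frame.
#' @param extractor An [init_extractor()] parameter set.
#' @param pre_cfg A [preprocess_config()].
#' @param cache Optional environment used as a key-value cache.
#' @param verbose Print per-volume progress to stderr.
#' @return List with matrices `X_d` (`n x len(x_d)`) and `X_e`.
#' @export
compute_features <- function(manifest, extractor, pre_cfg = preprocess_config(),
                             cache = NULL, verbose = FALSE) {
  n <- nrow(manifest)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    key <- feature_cache_key(manifest$path[i], extractor, pre_cfg)
    hit <- !is.null(cache) && !is.null(cache[[key]])
    if (hit) {
      feats[[i]] <- cache[[key]]
    } else {
      v <- preprocess_volume(manifest$path[i], pre_cfg)
      feats[[i]] <- extract_features(v, extractor)
      if (!is.null(cache)) cache[[key]] <- feats[[i]]
    }
    if (verbose) message(sprintf("[broadvol] features %d/%d %s%s", i, n,
                                 basename(manifest$path[i]),
                                 if (hit) " (cached)" else ""))
  }
  list(X_d = do.call(rbind, lapply(feats, `[[`, "x_d")),
       X_e = do.call(rbind, lapply(feats, `[[`, "x_e")))
}

run_task_features <- function(features, manifest, task, bls_cfg) {
  split <- split_dataset(manifest, task)
  idx <- match(rownames_key(split$train), rownames_key(manifest))
  jdx <- match(rownames_key(split$test), rownames_key(manifest))
  t_fit <- system.time(
    model <- bls_fit(features$X_d[idx, , drop = FALSE],
                     split$train$label,
                     features$X_e[idx, , drop = FALSE], bls_cfg)
  )[["elapsed"]]
  pred <- predict(model, features$X_d[jdx, , drop = FALSE],
                  features$X_e[jdx, , drop = FALSE])
  cm <- confusion_matrix(split$test$label, pred$labels, task$classes)
  metrics <- if (length(task$classes) == 2L)
    compute_metrics(cm, scores = pred$scores[, task$positive],
                    truth = split$test$label == task$positive)
  else compute_metrics(cm)
  structure(list(task = task$name, positive = task$positive,
                 classes = task$classes, split_level = task$split_level,
                 split_seed = task$split_seed, bls_config = unclass(bls_cfg),
                 n_train = nrow(split$train), n_test = nrow(split$test),
                 metrics = metrics, model = model,
                 wall_time_s = list(fit = unname(t_fit))),
            class = "evaluation_report")
}

rownames_key <- function(df) paste(df$path, df$subject)

#' Run one classification task end to end
#'
#' Preprocesses all volumes, extracts the deep feature pairs once, fits the
#' broad learner on the training split and evaluates on the held-out test
#' split.
#'
#' @param manifest Manifest data frame or CSV path.
#' @param task A [task_spec()].
#' @param extractor An [init_extractor()] parameter set.
#' @param bls_cfg A [bls_config()].
#' @param pre_cfg A [preprocess_config()].
#' @param cache Optional feature cache environment.
#' @param verbose Progress logging to stderr.
#' @return An `evaluation_report`: confusion matrix, ACC/SEN/SPEC/PREC/F1,
#'   ROC points and AUC, split sizes, configs, and fit wall time
#'   (informational only).
#' @export
run_task <- function(manifest, task, extractor, bls_cfg = bls_config(),
                     pre_cfg = preprocess_config(), cache = NULL,
                     verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(task, "task_spec"))
  t_feat <- system.time(
    features <- compute_features(manifest, extractor, pre_cfg, cache, verbose)
  )[["elapsed"]]
  report <- run_task_features(features, manifest, task, bls_cfg)
  report$wall_time_s$features <- unname(t_feat)
  report$wall_time_s$total <- unname(t_feat + report$wall_time_s$fit)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat("<evaluation_report>", x$task, " (positive:", x$positive, ")\n",
      " n_train:", x$n_train, " n_test:", x$n_test, "\n")
  print(m$confusion)
  cat(sprintf("  ACC %.3f  SEN %.3f  SPEC %.3f  PREC %.3f  F1 %.3f  AUC %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1,
              m$auc))
  invisible(x)
}

#' Hyperparameter stability sweep
#'
#' Runs the task over the cartesian grid of feature-node counts,
#' enhancement-node counts and sparsity values, repeated over a list of
#' seeds (each seed re-draws the split and the random BLS weights). Features
#' are extracted once and shared across all grid points.
#'
#' @param manifest Manifest data frame or CSV path.
#' @param task A [task_spec()].
#' @param extractor An [init_extractor()] parameter set.
#' @param feature_node_values,enh_node_values,sparsity_values Grid values;
#'   validated against the sweep ranges 500-4000, 100-1000 and 0.4-0.7
#'   (sparsity 0 = auto-coding off is always allowed).
#' @param seeds Integer vector of repeat seeds (default 5 repeats).
#' @param bls_base A [bls_config()] supplying the non-swept fields.
#' @param pre_cfg A [preprocess_config()].
#' @param cache Optional feature cache environment.
#' @param verbose Progress logging.
#' @return List with `results` (one row per grid point x seed) and `summary`
#'   (mean and sd of accuracy per grid point).
#' @export
sweep_hyperparams <- function(manifest, task, extractor,
                              feature_node_values = c(500L, 2000L, 4000L),
                              enh_node_values = 500L,
                              sparsity_values = 0,
                              seeds = 0:4,
                              bls_base = bls_config(),
                              pre_cfg = preprocess_config(),
                              cache = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  grid <- expand.grid(n_feature_nodes = feature_node_values,
                      n_enh_nodes = enh_node_values,
                      sparsity = sparsity_values)
  features <- compute_features(manifest, extractor, pre_cfg, cache, verbose)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (s in seeds) {
      cfg <- bls_config(n_feature_nodes = grid$n_feature_nodes[i],
                        n_enh_nodes = grid$n_enh_nodes[i],
                        sparsity = grid$sparsity[i],
                        n_feature_groups = bls_base$n_feature_groups,
                        n_enh_groups = bls_base$n_enh_groups,
                        phi = bls_base$phi, delta = bls_base$delta,
                        lam = bls_base$lam, seed = s, mode = bls_base$mode,
                        sweep_mode = TRUE)
      tk <- task
      tk$split_seed <- as.integer(s)
      rep_ <- run_task_features(features, manifest, tk, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(n_feature_nodes = grid$n_feature_nodes[i],
                   n_enh_nodes = grid$n_enh_nodes[i],
                   sparsity = grid$sparsity[i], seed = s,
                   accuracy = rep_$metrics$accuracy,
                   sensitivity = rep_$metrics$sensitivity,
                   f1 = rep_$metrics$f1, auc = rep_$metrics$auc)
      if (verbose)
        message(sprintf("[broadvol] sweep nf=%d ne=%d sp=%.2f seed=%d acc=%.3f",
                        grid$n_feature_nodes[i], grid$n_enh_nodes[i],
                        grid$sparsity[i], s, rep_$metrics$accuracy))
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate(accuracy ~ n_feature_nodes + n_enh_nodes + sparsity,
                       data = results,
                       FUN = function(a) c(mean = mean(a), sd = sd(a)))
  summary <- cbind(summary[, 1:3],
                   mean_accuracy = summary$accuracy[, "mean"],
                   sd_accuracy = summary$accuracy[, "sd"])
  list(results = results, summary = summary)
}

#' Export extracted features to a CSV table
#'
#' One row per manifest entry: the concatenated shallow and deep feature
#' vectors (`d1..`, `e1..`) plus `label`, `subject` and `path` — e.g. for
#' external embedding/visualisation tools.
#'
#' @param manifest Manifest data frame or CSV path.
#' @param extractor An [init_extractor()] parameter set.
#' @param out_path Output CSV path.
#' @param pre_cfg A [preprocess_config()].
#' @param cache Optional feature cache environment.
#' @param verbose Progress logging.
#' @return `out_path`, invisibly; the table as attribute `"features"`.
#' @export
export_features <- function(manifest, extractor, out_path,
                            pre_cfg = preprocess_config(), cache = NULL,
                            verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  f <- compute_features(manifest, extractor, pre_cfg, cache, verbose)
  colnames(f$X_d) <- paste0("d", seq_len(ncol(f$X_d)))
  colnames(f$X_e) <- paste0("e", seq_len(ncol(f$X_e)))
  tab <- data.frame(f$X_d, f$X_e, label = manifest$label,
                    subject = manifest$subject, path = manifest$path)
  write.csv(tab, out_path, row.names = FALSE)
  attr(out_path, "features") <- tab
  invisible(out_path)
}

#' Save / load a fitted ensemble model
#'
#' A model archive bundles the frozen extractor parameters, the fitted broad
#' learner and the preprocessing configuration in a single uncompressed RDS
#' file, so identical runs produce byte-identical archives.
#'
#' @param extractor An [init_extractor()] parameter set.
#' @param bls A fitted `bls_model`.
#' @param pre_cfg A [preprocess_config()].
#' @param path Archive path.
#' @return `path` invisibly ([save_model()]); the model list
#'   ([load_model()]).
#' @export
save_model <- function(extractor, bls, pre_cfg, path) {
  obj <- list(package = "broadvol", extractor = extractor, bls = bls,
              preprocess = pre_cfg)
  saveRDS(obj, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$package, "broadvol")) stop("not a broadvol model archive")
  obj
}

#' Write an evaluation report as JSON
#'
#' Serializes the report (confusion matrix, metrics, ROC points, split and
#' configuration echo). Wall-clock timings are informational and excluded by
#' default so identical runs give byte-identical files.
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @param include_timings Include the hardware-dependent timings.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_timings = FALSE) {
  m <- report$metrics
  out <- list(task = report$task, positive = report$positive,
              classes = report$classes, split_level = report$split_level,
              split_seed = report$split_seed,
              n_train = report$n_train, n_test = report$n_test,
              confusion = unclass(unname(as.matrix(m$confusion))),
              accuracy = m$accuracy, sensitivity = m$sensitivity,
              specificity = m$specificity, precision = m$precision,
              f1 = m$f1, auc = m$auc,
              roc = m$roc,
              bls_config = report$bls_config[c("n_feature_nodes", "n_enh_nodes",
                                               "sparsity", "lam", "phi",
                                               "delta", "seed", "mode")])
  if (include_timings) out$wall_time_s <- report$wall_time_s
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
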