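#' Train the EPI classifier
#'
#' A random forest (binned CART ensemble, Gini impurity, bootstrap sampling)
#' trained on the feature columns of an encoded dataset. Defaults: 500 trees,
#' `floor(sqrt(p))` features per split, unlimited depth, no class weighting.
#' Deterministic given `seed`.
#'
#' @param fm an `epi_fm` with positive/negative labels.
#' @param seed integer seed.
#' @param num_trees number of trees.
#' @param mtry features considered per split (default `floor(sqrt(p))`).
#' @param min_node_size minimum samples per leaf.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param max_bins histogram bins per feature for split search.
#' @param provenance character tags describing the training data (cell line,
#'   platform); recorded in the model.
#' @return an `epi_model`.
#' @export
train <- function(fm, seed = 1, num_trees = 500, mtry = NULL,
                  min_node_size = 1, max_depth = 0, max_bins = 64,
                  provenance = "unspecified") {
  stopifnot(inherits(fm, "epi_fm"))
  y <- fm_labels(fm)
  if (length(unique(y)) < 2) stopf("training data has a single class")
  p <- ncol(fm$x)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  fit <- rf_train_cpp(fm$x, y, as.integer(num_trees), as.integer(mtry),
                      as.integer(min_node_size), as.integer(max_depth),
                      as.integer(max_bins), as.numeric(seed))
  imp <- as.numeric(fit$importance)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(fm$x)
  structure(list(forest = fit, feature_names = colnames(fm$x),
                 fingerprint = matrix_fingerprint(colnames(fm$x)),
                 importance = imp,
                 hyperparams = list(num_trees = num_trees, mtry = mtry,
                                    min_node_size = min_node_size,
                                    max_depth = max_depth, max_bins = max_bins),
                 provenance = provenance, seed = as.integer(seed)),
            class = "epi_model")
}

matrix_fingerprint <- function(feature_names) {
  sprintf("d%d;h=%d", length(feature_names),
          str_hash(paste(feature_names, collapse = ",")))
}

#' @export
print.epi_model <- function(x, ...) {
  cat(sprintf("epi_model: %d trees on %d features [%s] (data: %s, seed %d)\n",
              x$hyperparams$num_trees, length(x$feature_names), x$fingerprint,
              paste(x$provenance, collapse = "+"), x$seed))
  invisible(x)
}

#' Predict EPI probabilities
#'
#' Refuses matrices whose feature columns do not match the model's scheme
#' fingerprint.
#'
#' @param object an `epi_model`.
#' @param fm an `epi_fm` or numeric matrix with named columns.
#' @param ... unused.
#' @return probability vector in `[0, 1]`.
#' @export
predict.epi_model <- function(object, fm, ...) {
  x <- if (inherits(fm, "epi_fm")) fm$x else as.matrix(fm)
  fp <- matrix_fingerprint(colnames(x))
  if (!identical(colnames(x), object$feature_names))
    stopf("feature fingerprint mismatch: model=%s, data=%s",
          object$fingerprint, fp)
  rf_predict_cpp(object$forest, x)
}

new_eval_result <- function(scores, labels, per_split = NULL, extra = list()) {
  y <- as_binary_labels(labels)
  res <- c(list(auprc = auprc(scores, y), auroc = auroc(scores, y),
                baseline = mean(y), per_split = per_split), extra)
  if (!is.null(per_split)) {
    res$auprc_mean <- mean(per_split$auprc)
    res$auprc_sd <- sd(per_split$auprc)
    res$auroc_mean <- mean(per_split$auroc)
    res$auroc_sd <- sd(per_split$auroc)
  }
  structure(res, class = "epi_eval")
}

#' @export
print.epi_eval <- function(x, ...) {
  cat(sprintf("epi_eval: AUPRC %.4f | AUROC %.4f | baseline %.4f\n",
              x$auprc, x$auroc, x$baseline))
  if (!is.null(x$per_split))
    cat(sprintf("  over %d split(s): AUPRC %.4f +/- %.4f, AUROC %.4f +/- %.4f\n",
                nrow(x$per_split), x$auprc_mean, x$auprc_sd,
                x$auroc_mean, x$auroc_sd))
  invisible(x)
}

# stratified fold assignment: within each class, shuffled samples dealt
# round-robin into k folds
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      if (length(idx) < k)
        stopf("class %s has fewer samples (%d) than folds (%d); use more data",
              cls, length(idx), k)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Out-of-fold scores are pooled for a single AUPRC/AUROC; per-fold values
#' are reported alongside.
#'
#' @param fm an `epi_fm` with labels.
#' @param k number of folds (default 5).
#' @param seed integer seed (drives both fold assignment and tree growing).
#' @param ... passed to [train()].
#' @return an `epi_eval`; `$scores` holds the pooled out-of-fold scores in
#'   row order.
#' @export
cross_validate <- function(fm, k = 5, seed = 1, ...) {
  y <- fm_labels(fm)
  fold <- stratified_folds(y, k, child_seed(seed, "folds"))
  scores <- numeric(length(y))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fm_subset(fm, rows = which(fold != f))
    te <- fm_subset(fm, rows = which(fold == f))
    model <- train(tr, seed = child_seed(seed, "fold", f), ...)
    s <- predict(model, te)
    scores[fold == f] <- s
    per_fold[[f]] <- data.table::data.table(
      split = f, auprc = auprc(s, y[fold == f]), auroc = auroc(s, y[fold == f]))
  }
  new_eval_result(scores, y, per_split = data.table::rbindlist(per_fold),
                  extra = list(scores = scores, k = k, seed = seed))
}

#' Repeated random-resampling evaluation
#'
#' `n_reps` independent stratified train/test splits; reports the mean and
#' standard deviation of AUPRC/AUROC across replicates (the protocol's
#' "100-time random resampling").
#'
#' @param fm an `epi_fm` with labels.
#' @param n_reps number of replicates (default 100).
#' @param test_fraction held-out fraction per replicate (default 0.2).
#' @param seed integer seed.
#' @param ... passed to [train()].
#' @return an `epi_eval` with one row per replicate in `$per_split`.
#' @export
resample_evaluate <- function(fm, n_reps = 100, test_fraction = 0.2,
                              seed = 1, ...) {
  y <- fm_labels(fm)
  reps <- vector("list", n_reps)
  all_scores <- NULL
  all_labels <- NULL
  for (r in seq_len(n_reps)) {
    test_idx <- local_seed(child_seed(seed, "resample", r), {
      unlist(lapply(unique(y), function(cls) {
        idx <- which(y == cls)
        sample(idx, max(1L, round(test_fraction * length(idx))))
      }))
    })
    tr <- fm_subset(fm, rows = setdiff(seq_along(y), test_idx))
    te <- fm_subset(fm, rows = test_idx)
    model <- train(tr, seed = child_seed(seed, "resample_fit", r), ...)
    s <- predict(model, te)
    reps[[r]] <- data.table::data.table(
      split = r, auprc = auprc(s, y[test_idx]), auroc = auroc(s, y[test_idx]))
    all_scores <- c(all_scores, s)
    all_labels <- c(all_labels, y[test_idx])
  }
  new_eval_result(all_scores, all_labels,
                  per_split = data.table::rbindlist(reps),
                  extra = list(n_reps = n_reps, test_fraction = test_fraction,
                               seed = seed))
}

#' Cross-sample AUPRC matrix
#'
#' Train on the row dataset, test on the column dataset; diagonal entries use
#' cross-validation within the dataset.
#'
#' @param datasets named list of `epi_fm` objects with matching schemes.
#' @param seed integer seed.
#' @param k folds for the diagonal entries.
#' @param ... passed to [train()].
#' @return numeric matrix of AUPRC values (rows = training set).
#' @export
cross_sample_matrix <- function(datasets, seed = 1, k = 5, ...) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  check_matching_schemes(datasets)
  n <- length(datasets)
  out <- matrix(NA_real_, n, n, dimnames = list(names(datasets), names(datasets)))
  for (i in seq_len(n)) {
    model <- train(datasets[[i]], seed = child_seed(seed, "xs", i), ...)
    for (j in seq_len(n)) {
      if (i == j) {
        out[i, j] <- cross_validate(datasets[[i]], k = k,
                                    seed = child_seed(seed, "xs_cv", i), ...)$auprc
      } else {
        s <- predict(model, datasets[[j]])
        out[i, j] <- auprc(s, fm_labels(datasets[[j]]))
      }
    }
  }
  out
}

check_matching_schemes <- function(datasets) {
  fps <- vapply(datasets, function(d) matrix_fingerprint(colnames(d$x)), "")
  if (length(unique(fps)) > 1)
    stopf("datasets have mismatched feature schemes: %s",
          paste(unique(fps), collapse = " vs "))
  invisible(fps[1])
}

#' Train a general model on pooled datasets
#'
#' Concatenates rows across datasets (schemes must match) and trains one
#' classifier whose provenance lists every source.
#'
#' @param datasets named list of `epi_fm` objects.
#' @param seed integer seed.
#' @param ... passed to [train()].
#' @return an `epi_model`.
#' @export
train_general <- function(datasets, seed = 1, ...) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  check_matching_schemes(datasets)
  x <- do.call(rbind, lapply(datasets, function(d) d$x))
  meta <- data.table::rbindlist(lapply(datasets, function(d) d$meta),
                                fill = TRUE)
  pooled <- structure(list(x = x, meta = meta, scheme = datasets[[1]]$scheme),
                      class = "epi_fm")
  train(pooled, seed = seed, provenance = names(datasets), ...)
}

#' Save / load a trained model
#'
#' Versioned plain-text-free serialization via R's native format is
#' deliberately avoided for interchange; models are session objects. This
#' helper writes the run log that accompanies a model instead.
#'
#' @param model an `epi_model`.
#' @param path output path for the run log.
#' @param extra named list of extra fields to record.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(model, path, extra = list()) {
  lines <- c(
    sprintf("package = rtepi %s", as.character(packageVersion("rtepi"))),
    sprintf("fingerprint = %s", model$fingerprint),
    sprintf("provenance = %s", paste(model$provenance, collapse = ",")),
    sprintf("seed = %d", model$seed),
    vapply(names(model$hyperparams),
           function(k) sprintf("%s = %s", k, model$hyperparams[[k]]), ""),
    vapply(names(extra), function(k) sprintf("%s = %s", k, extra[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}
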