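#' Feature importance ranking
#'
#' Default is the forest's mean-impurity-decrease importance (normalized to
#' sum to 1), annotated with the anchor and scale group of each feature. A
#' permutation mode is available because impurity importance is biased toward
#' high-cardinality features: it measures the drop in AUPRC when one column
#' is shuffled, on supplied (ideally held-out) data.
#'
#' @param model an `epi_model`.
#' @param type `"impurity"` (default) or `"permutation"`.
#' @param fm data for permutation importance (required for that type).
#' @param seed seed for the permutation draw.
#' @param scheme optional [feature_scheme()] for group annotation; defaults to
#'   the package default scheme when the model's columns match it.
#' @return `data.table` with `feature`, `importance`, `anchor_group`,
#'   `scale_group`, sorted descending by importance.
#' @export
importance <- function(model, type = c("impurity", "permutation"),
                       fm = NULL, seed = 1, scheme = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(model, "epi_model"))
  if (type == "impurity") {
    imp <- model$importance
  } else {
    if (is.null(fm)) stopf("permutation importance needs data (fm)")
    y <- fm_labels(fm)
    base <- auprc(predict(model, fm), y)
    imp <- local_seed(seed, {
      vapply(seq_along(model$feature_names), function(j) {
        xp <- fm$x
        xp[, j] <- sample(xp[, j])
        base - auprc(rf_predict_cpp(model$forest, xp), y)
      }, numeric(1))
    })
    names(imp) <- model$feature_names
  }
  out <- data.table::data.table(feature = names(imp), importance = as.numeric(imp))
  out <- annotate_feature_groups(out, model$feature_names, scheme)
  data.table::setorder(out, -importance, feature)
  out[]
}

annotate_feature_groups <- function(tab, feature_names_model, scheme) {
  anchor <- ifelse(startsWith(tab$feature, "prom_"), "promoter",
                   ifelse(startsWith(tab$feature, "enh_"), "enhancer", "other"))
  scale <- ifelse(endsWith(tab$feature, "_anchor"), "anchor",
                  sub("^.*_w([0-9]+)_b[0-9]+$", "\\1", tab$feature))
  scale[!grepl("^[0-9]+$", scale) & scale != "anchor"] <- "other"
  tab$anchor_group <- anchor
  tab$scale_group <- scale
  tab
}

#' Incremental feature selection curve
#'
#' Cross-validated performance using the top-k features of a ranking, for
#' each k in an ascending grid; reports the best k by AUPRC.
#'
#' @param fm an `epi_fm` with labels.
#' @param ranking character vector of feature names, best first (e.g. from
#'   [importance()]), or an importance table.
#' @param k_grid ascending integer grid; default brackets the protocol's
#'   reported optimum of 30 features.
#' @param seed integer seed.
#' @param k folds.
#' @param ... passed to [train()].
#' @return list with `curve` (`k`, `auprc`, `auroc`) and `best_k`.
#' @export
incremental_selection <- function(fm, ranking,
                                  k_grid = c(5, 10, 20, 30, 50, 100, 200, 482),
                                  seed = 1, k = 5, ...) {
  if (is.data.frame(ranking)) ranking <- ranking$feature
  if (is.unsorted(k_grid, strictly = TRUE))
    stopf("k_grid must be sorted ascending")
  k_grid <- k_grid[k_grid <= length(ranking)]
  rows <- lapply(k_grid, function(kk) {
    sub <- fm_subset(fm, cols = ranking[seq_len(kk)])
    ev <- cross_validate(sub, k = k, seed = seed, ...)
    data.table::data.table(k = kk, auprc = ev$auprc, auroc = ev$auroc)
  })
  curve <- data.table::rbindlist(rows)
  list(curve = curve[], best_k = curve$k[which.max(curve$auprc)])
}

#' Evaluate a feature-group subset
#'
#' Cross-validation restricted to one named group from [feature_groups()]
#' (e.g. `"promoter"`, `"enhancer"`, `"scale_500"`), or `"all"`.
#'
#' @param fm an `epi_fm` with labels.
#' @param group group name.
#' @param seed integer seed.
#' @param k folds.
#' @param ... passed to [train()].
#' @return an `epi_eval`.
#' @export
subset_eval <- function(fm, group, seed = 1, k = 5, ...) {
  if (identical(group, "all"))
    return(cross_validate(fm, k = k, seed = seed, ...))
  groups <- feature_groups(fm$scheme)
  if (!group %in% names(groups))
    stopf("unknown feature group '%s' (known: %s)", group,
          paste(names(groups), collapse = ", "))
  cross_validate(fm_subset(fm, cols = groups[[group]]), k = k, seed = seed, ...)
}

#' Distance-only control model
#'
#' Trains and cross-validates the same classifier on the single genomic
#' distance column. On a properly distance-matched dataset this control sits
#' at the no-skill baseline (positive prevalence) — the sanity check that
#' distance cannot explain the model's performance.
#'
#' @param fm an `epi_fm` whose `meta` carries a `distance` column.
#' @param seed integer seed.
#' @param k folds.
#' @param ... passed to [train()].
#' @return an `epi_eval`.
#' @export
distance_only_control <- function(fm, seed = 1, k = 5, ...) {
  if (!"distance" %in% names(fm$meta))
    stopf("feature matrix metadata lacks a distance column")
  dfm <- structure(list(
    x = matrix(fm$meta$distance, ncol = 1, dimnames = list(NULL, "distance")),
    meta = fm$meta, scheme = fm$scheme), class = "epi_fm")
  cross_validate(dfm, k = k, seed = seed, ...)
}
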