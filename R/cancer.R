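#' Select the top-scoring candidate EPIs
#'
#' Deterministic tie-break: score descending, then chromosome, enhancer
#' start, promoter start.
#'
#' @param scored candidate pair table with a `score` column.
#' @param n number to keep (default 1000); fewer when the input is smaller.
#' @return the selected pair rows, best first.
#' @export
select_top_epis <- function(scored, n = 1000) {
  stopifnot("score" %in% names(scored))
  out <- data.table::as.data.table(scored)
  data.table::setorder(out, -score, chrom, enh_start, prom_start)
  head(out, n)[]
}

#' Build the sample x EPI probability matrix
#'
#' Re-encodes a fixed EPI list with each sample's RT profile and scores every
#' (sample, EPI) cell with one trained model — the sample-level prediction
#' matrix used for group-specific calling and clustering.
#'
#' @param epis pair table of EPIs (columns as in [build_epi_dataset()]).
#' @param model an `epi_model`.
#' @param profiles list of [rt_profile()]s, one per sample; group labels are
#'   taken from each profile's `group` field.
#' @param scheme the model's [feature_scheme()].
#' @return a `sample_prob_matrix`: numeric samples x EPIs matrix with sample
#'   ids as row names, EPI keys as column names, and a `groups` attribute.
#' @export
build_sample_matrix <- function(epis, model, profiles,
                                scheme = feature_scheme()) {
  stopifnot(length(profiles) >= 1)
  epi_ids <- pair_key(epis)
  mat <- matrix(NA_real_, length(profiles), nrow(epis),
                dimnames = list(vapply(profiles, `[[`, "", "sample_id"),
                                epi_ids))
  for (s in seq_along(profiles)) {
    fm <- encode_dataset(epis, profiles[[s]], scheme)
    mat[s, ] <- predict(model, fm)
  }
  structure(mat,
            groups = vapply(profiles, function(p) p$group %||% NA_character_, ""),
            class = c("sample_prob_matrix", "matrix", "array"))
}

#' Call group-specific, common, and unobserved EPIs
#'
#' An EPI is positive in a group when the group's summary probability is at
#' least `tau_hi` (summary: mean by default, or per-sample majority vote at
#' 0.5); it is specific to group A when positive in A while the other
#' group's summary stays below `tau_lo`. The four output sets partition the
#' input EPI list.
#'
#' @param mat a `sample_prob_matrix` (or samples x EPIs matrix).
#' @param groups two-group label vector, one per sample (defaults to the
#'   matrix's `groups` attribute).
#' @param tau_hi,tau_lo positivity / exclusion thresholds (default 0.5).
#' @param mode `"mean"` (default) or `"vote"` (fraction of samples above 0.5).
#' @return list with `a_specific`, `common`, `b_specific`, `neither`
#'   (character vectors of EPI ids), the group names, and the per-group
#'   summary table.
#' @export
call_group_specific <- function(mat, groups = attr(mat, "groups"),
                                tau_hi = 0.5, tau_lo = 0.5,
                                mode = c("mean", "vote")) {
  mode <- match.arg(mode)
  glev <- unique(groups)
  if (length(glev) != 2) stopf("exactly two groups required (got %d)", length(glev))
  summarize <- function(rows) {
    if (mode == "mean") colMeans(mat[rows, , drop = FALSE])
    else colMeans(mat[rows, , drop = FALSE] >= 0.5)
  }
  sa <- summarize(groups == glev[1])
  sb <- summarize(groups == glev[2])
  pos_a <- sa >= tau_hi
  pos_b <- sb >= tau_hi
  ids <- colnames(mat)
  list(a_specific = ids[pos_a & sb < tau_lo],
       common = ids[pos_a & pos_b],
       b_specific = ids[pos_b & sa < tau_lo],
       neither = ids[!(pos_a & sb < tau_lo) & !(pos_a & pos_b) &
                       !(pos_b & sa < tau_lo)],
       group_a = glev[1], group_b = glev[2],
       summary = data.table::data.table(epi = ids, mean_a = sa, mean_b = sb))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of matrix rows (average linkage, Euclidean
#' distance by default) cut at `k` clusters. Deterministic.
#'
#' @param mat samples x EPIs matrix.
#' @param k number of clusters (default 2).
#' @param linkage linkage method for [stats::hclust()].
#' @param distance distance method for [stats::dist()].
#' @return integer cluster labels named by sample.
#' @export
hierarchical_cluster <- function(mat, k = 2, linkage = "average",
                                 distance = "euclidean") {
  if (k > nrow(mat)) stopf("k (%d) exceeds the number of samples (%d)", k, nrow(mat))
  hc <- hclust(dist(mat, method = distance), method = linkage)
  cutree(hc, k = k)
}
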