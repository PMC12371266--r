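#' Score an independent loop catalogue with a trained model
#'
#' Each loop is mapped to candidate enhancer-promoter readings with the same
#' overlap rule used for positive calling; a mappable loop's score is the
#' maximum predicted probability over its mapped pairs. The recovery fraction
#' is the share of mappable loops scoring at or above the threshold.
#'
#' @param model an `epi_model`.
#' @param loops loop table (e.g. ChIA-PET / Hi-TrAC / 5C BEDPE).
#' @param enhancers,promoters merged element tables.
#' @param profile an [rt_profile()].
#' @param scheme the [feature_scheme()] the model was trained with.
#' @param threshold call threshold (default 0.5).
#' @return list with `loop_scores` (loop coordinates + `score` + `call`),
#'   `recovery` fraction, `n_mappable`, and `n_unmappable`.
#' @export
score_reference_loops <- function(model, loops, enhancers, promoters, profile,
                                  scheme = feature_scheme(), threshold = 0.5) {
  mapped <- map_loops_to_pairs(loops, enhancers, promoters)
  if (nrow(mapped) == 0)
    stopf("no loop could be mapped to an enhancer-promoter pair")
  fm <- encode_dataset(mapped, profile, scheme)
  mapped$score <- predict(model, fm)
  per_loop <- mapped[, .(score = max(score)), by = loop_id]
  out <- data.table::data.table(
    chrom = loops$chrom[per_loop$loop_id],
    start1 = loops$start1[per_loop$loop_id],
    end1 = loops$end1[per_loop$loop_id],
    start2 = loops$start2[per_loop$loop_id],
    end2 = loops$end2[per_loop$loop_id],
    loop_id = per_loop$loop_id,
    score = per_loop$score)
  out[, call := score >= threshold]
  data.table::setorder(out, loop_id)
  list(loop_scores = out[], recovery = mean(out$call),
       n_mappable = nrow(out), n_unmappable = nrow(loops) - nrow(out),
       threshold = threshold)
}

#' Combine per-platform models by score-threshold union
#'
#' A loop is called by the combination when ANY model scores it at or above
#' the threshold — the union rule, reflecting complementary platforms
#' recovering distinct interactions. Inputs are the `loop_scores` tables of
#' [score_reference_loops()] runs over the same loop catalogue.
#'
#' @param score_tables named list of per-model `loop_scores` tables.
#' @param threshold call threshold (default 0.5).
#' @return list with `combined` (per-loop max score + combined call +
#'   per-model calls), `recovery` of the combination, and `per_model`
#'   recovery fractions.
#' @export
combine_models <- function(score_tables, threshold = 0.5) {
  stopifnot(length(score_tables) >= 1, !is.null(names(score_tables)))
  ids <- lapply(score_tables, function(t) t$loop_id)
  if (length(unique(lapply(ids, sort))) > 1)
    stopf("score tables cover different loop sets")
  base <- data.table::copy(score_tables[[1]])[, .(chrom, start1, end1,
                                                  start2, end2, loop_id)]
  data.table::setorder(base, loop_id)
  calls <- matrix(FALSE, nrow(base), length(score_tables),
                  dimnames = list(NULL, names(score_tables)))
  scores <- matrix(NA_real_, nrow(base), length(score_tables))
  for (m in seq_along(score_tables)) {
    t <- score_tables[[m]]
    o <- match(base$loop_id, t$loop_id)
    scores[, m] <- t$score[o]
    calls[, m] <- scores[, m] >= threshold
  }
  base$score <- apply(scores, 1, max)
  base$call <- rowSums(calls) > 0
  for (m in colnames(calls)) base[[paste0("call_", m)]] <- calls[, m]
  list(combined = base[], recovery = mean(base$call),
       per_model = colMeans(calls), threshold = threshold)
}
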