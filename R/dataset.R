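#' Dataset construction configuration
#'
#' Defaults follow the published protocol: elements within 500 bp merged,
#' negatives distance-matched at a 1:20 positive:negative ratio. Distance
#' bins default to 15 log-spaced bins spanning the candidate distance bounds
#' (5 kb to 2 Mb).
#'
#' @param merge_gap element merge gap in bp.
#' @param neg_pos_ratio negatives drawn per positive (>= 1).
#' @param min_distance,max_distance candidate distance bounds in bp
#'   (midpoint-to-midpoint).
#' @param n_bins number of log-spaced distance bins (ignored when
#'   `distance_bins` is given).
#' @param distance_bins optional explicit strictly increasing bin edges in bp.
#' @param seed integer seed for negative sampling.
#' @return a `dataset_config` list.
#' @export
dataset_config <- function(merge_gap = 500, neg_pos_ratio = 20,
                           min_distance = 5e3, max_distance = 2e6,
                           n_bins = 15, distance_bins = NULL, seed = 1) {
  if (neg_pos_ratio < 1) stopf("neg_pos_ratio must be >= 1")
  if (min_distance >= max_distance) stopf("min_distance must be < max_distance")
  if (is.null(distance_bins))
    distance_bins <- exp(seq(log(min_distance), log(max_distance),
                             length.out = n_bins + 1))
  if (any(diff(distance_bins) <= 0))
    stopf("distance bin edges must be strictly increasing")
  structure(list(merge_gap = merge_gap, neg_pos_ratio = as.integer(neg_pos_ratio),
                 min_distance = min_distance, max_distance = max_distance,
                 distance_bins = distance_bins, seed = as.integer(seed)),
            class = "dataset_config")
}

# canonical identity of a pair: both element coordinate tuples
pair_key <- function(pairs) {
  paste(pairs$chrom, pairs$enh_start, pairs$enh_end,
        pairs$prom_start, pairs$prom_end, sep = ":")
}

# recompute midpoint-to-midpoint distance from coordinates
pair_distance <- function(pairs) {
  abs((pairs$enh_start + pairs$enh_end) / 2 -
        (pairs$prom_start + pairs$prom_end) / 2)
}

empty_pairs <- function() {
  data.table::data.table(chrom = character(), enh_start = numeric(),
                         enh_end = numeric(), prom_start = numeric(),
                         prom_end = numeric(), distance = numeric(),
                         label = character(), source = character())
}

# Map each loop to its enhancer-promoter readings: one anchor must overlap
# >= 1 enhancer and the other >= 1 promoter (either orientation); multiple
# overlapped elements yield the cross-product. Returns pair rows tagged with
# loop_id (not deduplicated across loops).
map_loops_to_pairs <- function(loops, enhancers, promoters) {
  if (nrow(loops) == 0) return(cbind(empty_pairs()[, -c("label", "source")],
                                     data.table::data.table(loop_id = integer())))
  anchors_a <- data.table::data.table(chrom = loops$chrom,
                                      start = loops$start1, end = loops$end1)
  anchors_b <- data.table::data.table(chrom = loops$chrom,
                                      start = loops$start2, end = loops$end2)
  cross <- function(anch_e, anch_p) {
    he <- gi_overlaps(anch_e, enhancers)
    hp <- gi_overlaps(anch_p, promoters)
    data.table::setnames(he, c("loop_id", "enh_idx"))
    data.table::setnames(hp, c("loop_id", "prom_idx"))
    merge(he, hp, by = "loop_id", allow.cartesian = TRUE)
  }
  m <- data.table::rbindlist(list(cross(anchors_a, anchors_b),
                                  cross(anchors_b, anchors_a)))
  if (nrow(m) == 0) return(cbind(empty_pairs()[, -c("label", "source")],
                                 data.table::data.table(loop_id = integer())))
  out <- data.table::data.table(
    chrom = loops$chrom[m$loop_id],
    enh_start = enhancers$start[m$enh_idx],
    enh_end = enhancers$end[m$enh_idx],
    prom_start = promoters$start[m$prom_idx],
    prom_end = promoters$end[m$prom_idx],
    loop_id = m$loop_id)
  out$distance <- pair_distance(out)
  unique(out)
}

#' Call positive EPI pairs from loops
#'
#' A loop yields a positive pair when one anchor overlaps at least one
#' (merged) enhancer and the other anchor at least one (merged) promoter, in
#' either orientation; the overlapped merged element, not the raw anchor,
#' becomes the pair's region. Multiple overlaps produce the cross-product of
#' pairs; duplicates across loops are removed.
#'
#' @param loops loop table (see [read_bedpe()]).
#' @param enhancers,promoters merged element tables (see [merge_elements()]).
#' @param source provenance tag stored with each pair.
#' @return positive pair table; attribute `n_unmatched` counts loops that
#'   produced no pair.
#' @export
call_positive_epis <- function(loops, enhancers, promoters, source = "loops") {
  mapped <- map_loops_to_pairs(loops, enhancers, promoters)
  n_unmatched <- nrow(loops) - length(unique(mapped$loop_id))
  out <- unique(mapped[, -"loop_id"])
  out[, `:=`(label = "positive", source = source)]
  if (nrow(out) == 0) out <- empty_pairs()
  data.table::setorder(out, chrom, enh_start, prom_start)
  data.table::setattr(out, "n_unmatched", n_unmatched)
  out[]
}

#' Enumerate candidate enhancer-promoter pairs
#'
#' All same-chromosome enhancer x promoter pairs whose midpoint distance lies
#' in `[min_distance, max_distance]`, excluding pairs whose elements overlap
#' each other.
#'
#' @param enhancers,promoters merged element tables.
#' @param min_distance,max_distance distance bounds in bp.
#' @return unlabeled candidate pair table.
#' @export
enumerate_candidates <- function(enhancers, promoters,
                                 min_distance = 5e3, max_distance = 2e6) {
  validate_intervals(enhancers, "enhancer")
  validate_intervals(promoters, "promoter")
  chroms <- intersect(unique(enhancers$chrom), unique(promoters$chrom))
  res <- lapply(chroms, function(ch) {
    e <- enhancers[chrom == ch]
    p <- promoters[chrom == ch]
    idx <- data.table::CJ(ei = seq_len(nrow(e)), pi = seq_len(nrow(p)))
    out <- data.table::data.table(
      chrom = ch,
      enh_start = e$start[idx$ei], enh_end = e$end[idx$ei],
      prom_start = p$start[idx$pi], prom_end = p$end[idx$pi])
    out$distance <- pair_distance(out)
    out <- out[distance >= min_distance & distance <= max_distance]
    # exclude element pairs that overlap each other
    out[!(enh_start < prom_end & prom_start < enh_end)]
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0) return(empty_pairs())
  out[, `:=`(label = "unlabeled", source = "candidates")]
  data.table::setorder(out, chrom, enh_start, prom_start)
  out[]
}

# drop candidates that coincide with any loop-supported pair ("non-Hi-C
# overlapping pairs"): excluded when both elements overlap the two anchors of
# a single loop in an enhancer-promoter reading
exclude_loop_pairs <- function(candidates, loops, enhancers, promoters) {
  mapped <- map_loops_to_pairs(loops, enhancers, promoters)
  candidates[!pair_key(candidates) %in% pair_key(mapped)]
}

assign_distance_bin <- function(distance, edges) {
  findInterval(distance, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Distance-matched negative sampling
#'
#' For each distance bin, draws `neg_pos_ratio` negatives per positive,
#' uniformly without replacement from the candidates in that bin. A bin with
#' too few candidates contributes everything it has and the shortfall is
#' recorded. Reproducible given `cfg$seed`.
#'
#' @param positives positive pair table.
#' @param candidates candidate pair table; must exclude all positives (and,
#'   per protocol, all loop-supported pairs — see the construction pipeline).
#' @param cfg a [dataset_config()].
#' @return negative pair table (`label = "negative"`); attribute `shortfall`
#'   is a per-bin table of requested/available counts.
#' @export
sample_negatives <- function(positives, candidates, cfg = dataset_config()) {
  if (nrow(positives) == 0) stopf("no positives to match")
  if (nrow(candidates) == 0) stopf("no candidates to sample from")
  if (any(pair_key(candidates) %in% pair_key(positives)))
    stopf("candidates must exclude all positive pairs")
  edges <- cfg$distance_bins
  cand <- data.table::copy(candidates)
  data.table::setorder(cand, chrom, enh_start, enh_end, prom_start, prom_end)
  pos_bin <- assign_distance_bin(positives$distance, edges)
  cand_bin <- assign_distance_bin(cand$distance, edges)
  need <- table(factor(pos_bin, levels = seq_len(length(edges) - 1))) *
    cfg$neg_pos_ratio
  picks <- local_seed(cfg$seed, {
    lapply(seq_len(length(edges) - 1), function(b) {
      nb <- as.integer(need[b])
      if (nb == 0) return(integer())
      avail <- which(cand_bin == b)
      if (length(avail) <= nb) avail else sort(sample(avail, nb))
    })
  })
  shortfall <- data.table::data.table(
    bin = seq_len(length(edges) - 1),
    requested = as.integer(need),
    drawn = lengths(picks))
  shortfall[, shortfall := requested - drawn]
  neg <- cand[unlist(picks)]
  neg[, `:=`(label = "negative", source = "distance_matched")]
  data.table::setattr(neg, "shortfall", shortfall[])
  neg[]
}

#' Build a labelled EPI dataset from loops and annotations
#'
#' End-to-end dataset construction: merge elements, call positives from
#' loops, enumerate distance-bounded candidates, remove loop-supported pairs,
#' and draw distance-matched negatives.
#'
#' @param loops loop table.
#' @param enhancers,promoters raw element tables (merged internally).
#' @param cfg a [dataset_config()].
#' @param source provenance tag.
#' @return list with `pairs` (positives + negatives), `positives`,
#'   `negatives`, `candidates` (after exclusion), `enhancers`, `promoters`
#'   (merged), and `shortfall`.
#' @export
build_epi_dataset <- function(loops, enhancers, promoters,
                              cfg = dataset_config(), source = "loops") {
  enh <- merge_elements(enhancers, cfg$merge_gap)
  prom <- merge_elements(promoters, cfg$merge_gap)
  positives <- call_positive_epis(loops, enh, prom, source = source)
  positives <- positives[distance >= cfg$min_distance &
                           distance <= cfg$max_distance]
  candidates <- enumerate_candidates(enh, prom, cfg$min_distance,
                                     cfg$max_distance)
  candidates <- exclude_loop_pairs(candidates, loops, enh, prom)
  negatives <- sample_negatives(positives, candidates, cfg)
  pairs <- data.table::rbindlist(list(positives, negatives))
  list(pairs = pairs, positives = positives, negatives = negatives,
       candidates = candidates, enhancers = enh, promoters = prom,
       shortfall = attr(negatives, "shortfall"))
}

#' Write / read a labelled pair table
#'
#' Tab-separated with header columns `chrom`, `enh_start`, `enh_end`,
#' `prom_start`, `prom_end`, `distance`, `label`, `source`.
#'
#' @param pairs pair table.
#' @param path file path.
#' @return `path` invisibly / the pair table.
#' @export
write_pair_table <- function(pairs, path) {
  data.table::fwrite(pairs, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  dt[]
}
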