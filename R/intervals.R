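#' Genomic intervals
#'
#' Intervals are plain `data.table`s with columns `chrom`, `start`, `end`,
#' using the BED convention throughout: 0-based, half-open `[start, end)`.
#' Any 1-based external format is converted at the package boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like 0-based half-open coordinates.
#' @param ... further columns carried along (e.g. `name`, `score`).
#' @return a `data.table` with at least `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_intervals("chr1", 100, 200)
genomic_intervals <- function(chrom, start, end, ...) {
  gi <- data.table::data.table(chrom = as.character(chrom),
                               start = as.numeric(start),
                               end = as.numeric(end), ...)
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(gi)))
    stopf("%s table needs chrom/start/end columns", what)
  if (nrow(gi) == 0) return(invisible(gi))
  bad <- which(!is.finite(gi$start) | !is.finite(gi$end) |
                 gi$start < 0 | gi$start >= gi$end |
                 is.na(gi$chrom) | gi$chrom == "")
  if (length(bad))
    stopf("invalid %s at row %d: need 0 <= start < end and non-empty chrom",
          what, bad[1])
  invisible(gi)
}

# interval midpoints (may be half-integers; distances stay exact under doubles)
gi_mid <- function(gi) (gi$start + gi$end) / 2

# convert 0-based half-open intervals to a GRanges (1-based closed) and back
gi_to_gr <- function(gi) {
  GenomicRanges::GRanges(gi$chrom,
                         IRanges::IRanges(gi$start + 1, gi$end))
}

gr_to_gi <- function(gr) {
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = as.numeric(GenomicRanges::start(gr)) - 1,
                         end = as.numeric(GenomicRanges::end(gr)))
}

#' Merge nearby elements of one class
#'
#' Collapses intervals whose gap (`next.start - prev.end`) is at most
#' `merge_gap` base pairs into one interval (overlap counts as gap <= 0).
#' This is the element pre-processing step applied to enhancer and promoter
#' annotations before positive-pair calling, with a default gap of 500 bp.
#'
#' @param intervals interval table (one element class).
#' @param merge_gap maximum gap in bp that still merges (default 500).
#' @return sorted, non-overlapping interval table; consecutive intervals on a
#'   chromosome are separated by more than `merge_gap` bp.
#' @export
#' @examples
#' merge_elements(genomic_intervals("chr1", c(100, 650), c(200, 700)))
merge_elements <- function(intervals, merge_gap = 500) {
  validate_intervals(intervals, "element")
  if (nrow(intervals) == 0) return(data.table::copy(intervals)[, .(chrom, start, end)])
  gr <- gi_to_gr(intervals)
  # reduce() keeps ranges apart when the gap is >= min.gapwidth;
  # we merge when gap <= merge_gap, hence min.gapwidth = merge_gap + 1
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = merge_gap + 1)
  out <- gr_to_gi(red)
  data.table::setorder(out, chrom, start)
  out[]
}

# overlap hits between two 0-based interval tables; returns data.table of
# (query_idx, subject_idx) with any-overlap (>= 1 bp)
gi_overlaps <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(gi_to_gr(query), gi_to_gr(subject))
  data.table::data.table(query_idx = S4Vectors::queryHits(hits),
                         subject_idx = S4Vectors::subjectHits(hits))
}
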