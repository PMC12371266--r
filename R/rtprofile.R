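#' Replication-timing profile
#'
#' A queryable per-chromosome step signal: non-overlapping sorted intervals
#' (0-based half-open) each carrying one finite RT value. By the Repli-seq
#' log-ratio convention, positive values are early-replicating and negative
#' values late-replicating.
#'
#' @param intervals table with columns `chrom`, `start`, `end`, `value`.
#' @param sample_id sample identifier string.
#' @param group optional group label (e.g. `"ALL"`, `"normal"`).
#' @return an `rt_profile` object.
#' @export
rt_profile <- function(intervals, sample_id = "sample", group = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  validate_intervals(intervals, "RT profile")
  if (nrow(intervals) > 0 && !all(is.finite(intervals$value)))
    stopf("RT profile contains non-finite values")
  dt <- data.table::as.data.table(intervals)[, .(chrom, start, end, value)]
  data.table::setorder(dt, chrom, start)
  # reject overlap within a chromosome
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom]
  if (nrow(ov) && any(ov$V1))
    stopf("RT profile has overlapping intervals on %s",
          ov$chrom[which(ov$V1)[1]])
  chroms <- split(dt[, .(start, end, value)], dt$chrom)
  structure(list(chroms = chroms, sample_id = sample_id, group = group),
            class = "rt_profile")
}

#' @export
print.rt_profile <- function(x, ...) {
  nint <- sum(vapply(x$chroms, nrow, integer(1)))
  cat(sprintf("rt_profile '%s'%s: %d interval(s) on %d chromosome(s)\n",
              x$sample_id,
              if (is.null(x$group)) "" else sprintf(" [%s]", x$group),
              nint, length(x$chroms)))
  invisible(x)
}

#' Read an RT profile from bedGraph, wig, or bigWig
#'
#' The format is auto-detected from the file extension unless given. Parsing
#' of the track formats is delegated to rtracklayer; coordinates are converted
#' to the package's 0-based half-open convention at this boundary.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"bedGraph"`, `"wig"`, `"bigWig"`.
#' @param sample_id,group see [rt_profile()].
#' @return an `rt_profile`.
#' @export
read_rt_profile <- function(path, format = c("auto", "bedGraph", "wig", "bigWig"),
                            sample_id = NULL, group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bedgraph = , bdg = "bedGraph",
                     wig = "wig",
                     bw = , bigwig = "bigWig",
                     stopf("cannot detect RT format from extension '.%s'", ext))
  }
  gr <- rtracklayer::import(path, format = format)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    value = as.numeric(gr$score))
  rt_profile(dt, sample_id = sample_id %||% basename(path), group = group)
}

#' Whether bigWig reading is available on this platform
#' @return logical flag.
#' @export
has_bigwig_support <- function() {
  isTRUE(tryCatch(.Platform$OS.type == "unix", error = function(e) FALSE))
}

#' Write an RT profile as bedGraph
#' @param profile an `rt_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rt_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "rt_profile"))
  dt <- data.table::rbindlist(lapply(names(profile$chroms), function(ch) {
    cbind(data.table::data.table(chrom = ch), profile$chroms[[ch]])
  }))
  data.table::fwrite(dt[, .(chrom, start = format_coord(start),
                            end = format_coord(end), value)],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean RT signal over genomic regions
#'
#' Length-weighted mean of the profile over the intersection of each region
#' with covered bases. A region whose covered fraction falls below
#' `min_coverage` yields `NA`, the missing marker (a value, not an error);
#' imputation is applied later, at feature-encoding time.
#'
#' @param profile an `rt_profile`.
#' @param chrom chromosome name (scalar).
#' @param start,end numeric vectors of 0-based half-open region bounds
#'   (recycled to common length). Regions may extend beyond coverage or
#'   before base 0; only the overlap with covered bases contributes, and the
#'   coverage fraction is computed against the full requested width.
#' @param min_coverage minimum covered fraction (default 0.5).
#' @return numeric vector of means with `NA` as the missing marker.
#' @export
mean_signal <- function(profile, chrom, start, end, min_coverage = 0.5) {
  stopifnot(inherits(profile, "rt_profile"), length(chrom) == 1)
  n <- max(length(start), length(end))
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  pc <- profile$chroms[[chrom]]
  if (is.null(pc)) return(rep(NA_real_, n))
  region_means_cpp(start, end, pc$start, pc$end, pc$value, min_coverage)
}

# length-weighted mean RT per chromosome, used to impute missing markers
profile_chrom_means <- function(profile) {
  vapply(profile$chroms, function(pc) {
    w <- pc$end - pc$start
    sum(w * pc$value) / sum(w)
  }, numeric(1))
}

#' Chromosomes covered by a profile
#' @param profile an `rt_profile`.
#' @return character vector of chromosome names.
#' @export
profile_chroms <- function(profile) names(profile$chroms)
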