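#' Read a BED3+ file
#'
#' Tab-separated, 0-based half-open coordinates. `track`, `browser` and `#`
#' comment lines are skipped; columns beyond the third are ignored.
#'
#' @param path file path.
#' @return interval table in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("BED parse error, line %d: fewer than 3 fields", i)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stopf("BED parse error, line %d: non-integer coordinates", i)
    if (s < 0 || s >= e)
      stopf("BED parse error, line %d: need 0 <= start < end", i)
    j <- j + 1L
    out[[j]] <- list(chrom = f[1], start = s, end = e)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0)
    res <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric())
  res[]
}

#' Write intervals as BED3
#' @param gi interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gi, path) {
  validate_intervals(gi)
  data.table::fwrite(gi[, .(chrom, start = format_coord(start),
                            end = format_coord(end))],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BEDPE loop file
#'
#' Keeps intra-chromosomal records only; anchors are normalized so the
#' left-most anchor comes first. Inter-chromosomal records are dropped with a
#' counted warning (their count is also returned as an attribute).
#'
#' @param path file path.
#' @return loop table with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `score` (NA when absent), plus attribute `n_skipped`
#'   (inter-chromosomal records dropped).
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- vector("list", sum(keep))
  j <- 0L
  skipped <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stopf("BEDPE parse error, line %d: fewer than 6 fields", i)
    co <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (anyNA(co) || any(co != floor(co)))
      stopf("BEDPE parse error, line %d: non-integer coordinates", i)
    if (co[1] < 0 || co[1] >= co[2] || co[3] < 0 || co[3] >= co[4])
      stopf("BEDPE parse error, line %d: need 0 <= start < end", i)
    if (f[1] != f[4]) { skipped <- skipped + 1L; next }
    sc <- if (length(f) >= 8) suppressWarnings(as.numeric(f[8])) else NA_real_
    j <- j + 1L
    rows[[j]] <- list(chrom = f[1], start1 = co[1], end1 = co[2],
                      start2 = co[3], end2 = co[4], score = sc)
  }
  res <- data.table::rbindlist(rows[seq_len(j)])
  if (nrow(res) == 0)
    res <- data.table::data.table(chrom = character(), start1 = numeric(),
                                  end1 = numeric(), start2 = numeric(),
                                  end2 = numeric(), score = numeric())
  res <- normalize_loops(res)
  if (skipped > 0)
    warnf("dropped %d inter-chromosomal BEDPE record(s)", skipped)
  data.table::setattr(res, "n_skipped", skipped)
  res[]
}

# order anchors left-to-right within each loop
normalize_loops <- function(loops) {
  if (nrow(loops) == 0) return(loops)
  flip <- loops$start2 < loops$start1
  if (any(flip)) {
    s1 <- loops$start1[flip]; e1 <- loops$end1[flip]
    loops$start1[flip] <- loops$start2[flip]
    loops$end1[flip] <- loops$end2[flip]
    loops$start2[flip] <- s1
    loops$end2[flip] <- e1
  }
  loops
}

#' Write loops as BEDPE
#' @param loops loop table (`chrom`, `start1`, `end1`, `start2`, `end2`,
#'   optional `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  sc <- if ("score" %in% names(loops)) loops$score else rep(NA_real_, nrow(loops))
  out <- data.table::data.table(
    chrom1 = loops$chrom, start1 = format_coord(loops$start1),
    end1 = format_coord(loops$end1),
    chrom2 = loops$chrom, start2 = format_coord(loops$start2),
    end2 = format_coord(loops$end2),
    name = ".", score = ifelse(is.na(sc), ".", as.character(sc)))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
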