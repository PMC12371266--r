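#' Multi-scale RT feature scheme
#'
#' Each pair is encoded per anchor (promoter, enhancer) as an optional
#' anchor-region mean plus, for every window size `w`, `bins_per_side`
#' consecutive windows of width `w` tiling upstream (leftward) from the
#' anchor start and the same number tiling downstream (rightward) from the
#' anchor end. The default totals 2 x (1 + 6 x 40) = 482 features.
#'
#' @param window_sizes window widths in bp, one per scale.
#' @param bins_per_side windows per side per scale.
#' @param include_anchor_mean include the anchor-region mean feature.
#' @param imputation policy for missing markers: `"chrom_mean"` (default,
#'   chromosome-wide length-weighted mean), `"zero"`, or `"none"` (keep NA).
#' @param min_coverage minimum covered fraction before a window is treated as
#'   missing (see [mean_signal()]).
#' @return a `feature_scheme` object.
#' @export
feature_scheme <- function(window_sizes = c(500, 1000, 2000, 5000, 10000, 50000),
                           bins_per_side = 20, include_anchor_mean = TRUE,
                           imputation = c("chrom_mean", "zero", "none"),
                           min_coverage = 0.5) {
  stopifnot(length(window_sizes) >= 1, all(window_sizes > 0),
            bins_per_side >= 1)
  structure(list(window_sizes = as.numeric(window_sizes),
                 bins_per_side = as.integer(bins_per_side),
                 include_anchor_mean = isTRUE(include_anchor_mean),
                 imputation = match.arg(imputation),
                 min_coverage = min_coverage),
            class = "feature_scheme")
}

#' Scheme dimensionality
#' @param scheme a [feature_scheme()].
#' @return number of features per pair.
#' @export
scheme_dim <- function(scheme) {
  2L * (as.integer(scheme$include_anchor_mean) +
          length(scheme$window_sizes) * 2L * scheme$bins_per_side)
}

#' Feature names of a scheme
#'
#' Names are parseable back into their coordinates:
#' `{prom|enh}_anchor` or `{prom|enh}_{up|down}_w{scale}_b{bin}`.
#'
#' @param scheme a [feature_scheme()].
#' @return character vector of length [scheme_dim()].
#' @export
feature_names <- function(scheme) {
  one_anchor <- function(a) {
    nm <- character(0)
    if (scheme$include_anchor_mean) nm <- paste0(a, "_anchor")
    for (w in scheme$window_sizes) {
      b <- sprintf("%02d", seq_len(scheme$bins_per_side))
      nm <- c(nm, paste0(a, "_up_w", format_coord(w), "_b", b),
              paste0(a, "_down_w", format_coord(w), "_b", b))
    }
    nm
  }
  c(one_anchor("prom"), one_anchor("enh"))
}

#' Group feature columns by anchor and by scale
#'
#' Every feature belongs to exactly one anchor group (`promoter`/`enhancer`)
#' and one scale group (`scale_<w>`, or `scale_anchor` for anchor means).
#'
#' @param scheme a [feature_scheme()].
#' @return named list of character vectors of column names.
#' @export
feature_groups <- function(scheme) {
  nm <- feature_names(scheme)
  groups <- list(promoter = nm[startsWith(nm, "prom_")],
                 enhancer = nm[startsWith(nm, "enh_")])
  if (scheme$include_anchor_mean)
    groups$scale_anchor <- nm[endsWith(nm, "_anchor")]
  for (w in scheme$window_sizes) {
    tag <- paste0("_w", format_coord(w), "_")
    groups[[paste0("scale_", format_coord(w))]] <- nm[grepl(tag, nm, fixed = TRUE)]
  }
  groups
}

#' Human-readable scheme fingerprint
#' @param scheme a [feature_scheme()].
#' @return single string identifying the scheme (dimension + name hash).
#' @export
scheme_fingerprint <- function(scheme) {
  nm <- feature_names(scheme)
  sprintf("d%d;w=%s;b=%d;anchor=%s;h=%d",
          length(nm), paste(format_coord(scheme$window_sizes), collapse = ","),
          scheme$bins_per_side, scheme$include_anchor_mean,
          str_hash(paste(nm, collapse = ",")))
}

# window bounds for one anchor of the pairs: list of (start, end) per feature
# column, in feature_names order for that anchor
anchor_windows <- function(a_start, a_end, scheme) {
  cols <- list()
  if (scheme$include_anchor_mean)
    cols[[length(cols) + 1]] <- list(start = a_start, end = a_end)
  for (w in scheme$window_sizes) {
    for (i in seq_len(scheme$bins_per_side))  # upstream, nearest bin first
      cols[[length(cols) + 1]] <- list(start = a_start - i * w,
                                       end = a_start - (i - 1) * w)
    for (i in seq_len(scheme$bins_per_side))  # downstream
      cols[[length(cols) + 1]] <- list(start = a_end + (i - 1) * w,
                                       end = a_end + i * w)
  }
  cols
}

#' Encode a set of pairs as a feature matrix
#'
#' Rows follow the input pair order; encoding is deterministic. Windows
#' reaching past profile coverage (or before base 0) are truncated and become
#' missing when their covered fraction falls below the scheme threshold;
#' missing markers are then imputed per the scheme policy.
#'
#' @param pairs pair table (see [build_epi_dataset()]).
#' @param profile an [rt_profile()].
#' @param scheme a [feature_scheme()].
#' @return an `epi_fm` object: list with `x` (numeric matrix, named columns),
#'   `meta` (the pair table), and `scheme`.
#' @export
encode_dataset <- function(pairs, profile, scheme = feature_scheme()) {
  nm <- feature_names(scheme)
  x <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(nm),
              dimnames = list(NULL, nm))
  if (nrow(pairs) > 0) {
    missing_chroms <- setdiff(unique(pairs$chrom), profile_chroms(profile))
    if (length(missing_chroms))
      stopf("profile is missing chromosome(s): %s",
            paste(missing_chroms, collapse = ", "))
    cmeans <- profile_chrom_means(profile)
    for (ch in unique(pairs$chrom)) {
      rows <- which(pairs$chrom == ch)
      wins <- c(anchor_windows(pairs$prom_start[rows], pairs$prom_end[rows], scheme),
                anchor_windows(pairs$enh_start[rows], pairs$enh_end[rows], scheme))
      for (j in seq_along(wins)) {
        x[rows, j] <- mean_signal(profile, ch, wins[[j]]$start, wins[[j]]$end,
                                  min_coverage = scheme$min_coverage)
      }
      if (scheme$imputation == "chrom_mean") {
        xi <- x[rows, , drop = FALSE]
        xi[is.na(xi)] <- cmeans[[ch]]
        x[rows, ] <- xi
      }
    }
    if (scheme$imputation == "zero") x[is.na(x)] <- 0
  }
  structure(list(x = x, meta = data.table::as.data.table(pairs),
                 scheme = scheme),
            class = "epi_fm")
}

#' Encode a single pair
#' @param pair one-row pair table.
#' @param profile an [rt_profile()].
#' @param scheme a [feature_scheme()].
#' @return named numeric feature vector of length [scheme_dim()].
#' @export
encode_pair <- function(pair, profile, scheme = feature_scheme()) {
  stopifnot(nrow(pair) == 1)
  encode_dataset(pair, profile, scheme)$x[1, ]
}

#' @export
print.epi_fm <- function(x, ...) {
  cat(sprintf("epi_fm: %d pair(s) x %d feature(s)", nrow(x$x), ncol(x$x)))
  if ("label" %in% names(x$meta))
    cat(sprintf(" | %d positive / %d negative",
                sum(x$meta$label == "positive"),
                sum(x$meta$label == "negative")))
  cat("\n")
  invisible(x)
}

# 0/1 labels for training; errors on unlabeled rows
fm_labels <- function(fm) {
  lab <- fm$meta$label
  if (is.null(lab) || any(!lab %in% c("positive", "negative")))
    stopf("feature matrix must carry positive/negative labels")
  as.integer(lab == "positive")
}

#' Subset an encoded dataset
#' @param fm an `epi_fm`.
#' @param rows row indices (default all).
#' @param cols feature column names (default all).
#' @return an `epi_fm`.
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(fm$x))
  x <- fm$x[rows, , drop = FALSE]
  if (!is.null(cols)) {
    missing <- setdiff(cols, colnames(x))
    if (length(missing))
      stopf("unknown feature column(s): %s", paste(head(missing, 3), collapse = ", "))
    x <- x[, cols, drop = FALSE]
  }
  structure(list(x = x, meta = fm$meta[rows], scheme = fm$scheme),
            class = "epi_fm")
}

#' Write / read a feature matrix as a tab-separated table
#'
#' Metadata columns come first, then one column per feature.
#'
#' @param fm an `epi_fm`.
#' @param path file path.
#' @param scheme scheme used to re-interpret columns on read.
#' @return `path` invisibly / an `epi_fm`.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- cbind(fm$meta, data.table::as.data.table(fm$x))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, scheme = feature_scheme()) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  nm <- feature_names(scheme)
  missing <- setdiff(nm, names(dt))
  if (length(missing))
    stopf("feature table does not match scheme (missing %d column(s), e.g. %s)",
          length(missing), missing[1])
  meta <- dt[, setdiff(names(dt), nm), with = FALSE]
  structure(list(x = as.matrix(dt[, nm, with = FALSE]), meta = meta,
                 scheme = scheme),
            class = "epi_fm")
}

#' Write / read a feature scheme as a key=value config file
#' @param scheme a [feature_scheme()].
#' @param path file path.
#' @return `path` invisibly / a `feature_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  writeLines(c(
    paste0("window_sizes = ", paste(format_coord(scheme$window_sizes), collapse = ",")),
    paste0("bins_per_side = ", scheme$bins_per_side),
    paste0("include_anchor_mean = ", scheme$include_anchor_mean),
    paste0("imputation = ", scheme$imputation),
    paste0("min_coverage = ", scheme$min_coverage)), path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  kv <- parse_config(path)
  feature_scheme(
    window_sizes = as.numeric(strsplit(kv$window_sizes, ",")[[1]]),
    bins_per_side = as.integer(kv$bins_per_side),
    include_anchor_mean = as.logical(kv$include_anchor_mean),
    imputation = kv$imputation,
    min_coverage = as.numeric(kv$min_coverage))
}
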