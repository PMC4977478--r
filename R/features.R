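#' Feature-window specification
#'
#' Defines the windowed feature layout: for each of M histone marks, the
#' RPKM values of the `2 * flank_bins` bins around a center bin. With the
#' defaults (100 bp bins, `flank_bins = 10`) each mark contributes a
#' 20-dimensional vector spanning -1 kb to +1 kb, and the feature count is
#' `M * 20` — 480 features for 24 marks, 220 for 11, 180 for 9.
#'
#' A 2 kb window of 100 bp bins cannot be centered symmetrically on a single
#' bin, so the window covers bin offsets `-flank_bins .. flank_bins - 1`
#' (-10..+9 by default) relative to the center bin; the offset of every
#' column is recorded in the feature matrix's `column_map` so the layout is
#' auditable.
#'
#' @param marks ordered character vector of mark names.
#' @param flank_bins bins on each side of the center bin.
#' @param bin_width bin width in bp.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(marks, flank_bins = 10, bin_width = 100) {
  stopifnot(length(marks) >= 1L, !anyDuplicated(marks),
            flank_bins >= 1L, bin_width > 0)
  structure(list(marks = as.character(marks),
                 flank_bins = as.integer(flank_bins),
                 bin_width = as.integer(bin_width)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %d marks x %d window bins = %d features (%d bp bins)\n",
              length(x$marks), 2L * x$flank_bins, n_features(x), x$bin_width))
  invisible(x)
}

#' Total feature count of a feature spec
#' @param spec a [feature_spec].
#' @return integer, `M * 2 * flank_bins`.
#' @export
n_features <- function(spec) {
  length(spec$marks) * 2L * spec$flank_bins
}

#' Extract the windowed signal vector around one bin
#'
#' Returns the track values at bin offsets `-flank_bins .. flank_bins - 1`
#' relative to `center_bin` (0-based). Offsets falling outside the
#' chromosome are padded with zeros so windows near chromosome ends keep
#' their full length.
#'
#' @param track a [binned_track].
#' @param chrom chromosome name.
#' @param center_bin 0-based center bin index.
#' @param flank_bins bins on each side.
#' @return Numeric vector of length `2 * flank_bins`.
#' @export
extract_window <- function(track, chrom, center_bin, flank_bins = 10) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop(sprintf("track has no chromosome %s", chrom))
  if (center_bin < 0L || center_bin >= length(v)) {
    stop(sprintf("center_bin %d out of range for %s (%d bins)",
                 center_bin, chrom, length(v)))
  }
  idx <- center_bin + seq(-flank_bins, flank_bins - 1L) + 1L  # 1-based
  out <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

#' Assemble the windowed feature matrix at a set of genomic bins
#'
#' Builds the n x (M * 2 * flank_bins) matrix whose row for location
#' (chrom, bin) concatenates, mark by mark in `spec$marks` order, the
#' windowed RPKM vector from [extract_window()]. Column order is mark-major:
#' mark 1 at offsets -10..+9, then mark 2, and so on.
#'
#' @param tracks named list of [binned_track]s, one per mark in `spec`.
#' @param locations data.frame with columns `chrom` and `bin` (0-based bin
#'   indices).
#' @param spec a [feature_spec].
#' @return An object of class `feature_matrix`: list with `samples` (the
#'   numeric matrix), `locations`, and `column_map` (data.frame `column`,
#'   `mark`, `offset`). Rows with any zero-padded window bin are flagged in
#'   `locations$edge_padded`.
#' @export
assemble_features <- function(tracks, locations, spec) {
  missing <- setdiff(spec$marks, names(tracks))
  if (length(missing) > 0L) {
    stop(sprintf("no track supplied for mark(s): %s",
                 paste(missing, collapse = ", ")))
  }
  w <- 2L * spec$flank_bins
  offsets <- seq(-spec$flank_bins, spec$flank_bins - 1L)
  n <- nrow(locations)
  X <- matrix(0, nrow = n, ncol = n_features(spec))
  edge <- logical(n)
  for (m in seq_along(spec$marks)) {
    tr <- tracks[[spec$marks[m]]]
    cols <- (m - 1L) * w + seq_len(w)
    for (chr in unique(locations$chrom)) {
      v <- tr$values[[chr]]
      if (is.null(v)) stop(sprintf("track %s has no chromosome %s",
                                   spec$marks[m], chr))
      rows <- which(locations$chrom == chr)
      # n_rows x w index matrix into the padded value vector; index 1 is the
      # zero guard for out-of-chromosome bins
      idx <- outer(locations$bin[rows], offsets, `+`) + 2L
      idx[idx < 2L | idx > length(v) + 1L] <- 1L
      X[rows, cols] <- c(0, v)[idx]
      edge[rows] <- edge[rows] | apply(idx == 1L, 1L, any)
    }
  }
  column_map <- data.frame(
    column = seq_len(ncol(X)),
    mark = rep(spec$marks, each = w),
    offset = rep(offsets, times = length(spec$marks)),
    stringsAsFactors = FALSE)
  colnames(X) <- paste0(column_map$mark, "@", column_map$offset)
  locations <- as.data.frame(locations)
  locations$edge_padded <- edge
  structure(list(samples = X, locations = locations, column_map = column_map),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%d marks)\n",
              nrow(x$samples), ncol(x$samples), length(unique(x$column_map$mark))))
  invisible(x)
}

#' Write a feature matrix as delimited text
#'
#' Tab-separated with a header naming each column `mark@offset`, preceded by
#' the location columns `chrom` and `bin`.
#'
#' @param fm a [assemble_features()] feature matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- cbind(fm$locations[c("chrom", "bin")], as.data.frame(fm$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subset the columns of a feature matrix, keeping the column_map consistent
# (columns renumbered, original order preserved).
subset_features <- function(fm, cols) {
  cols <- sort(unique(as.integer(cols)))
  stopifnot(all(cols >= 1L), all(cols <= ncol(fm$samples)))
  cm <- fm$column_map[cols, , drop = FALSE]
  cm$original_column <- cm$column
  cm$column <- seq_len(nrow(cm))
  rownames(cm) <- NULL
  structure(list(samples = fm$samples[, cols, drop = FALSE],
                 locations = fm$locations, column_map = cm),
            class = "feature_matrix")
}
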