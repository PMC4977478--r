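#' Read sets
#'
#' A read set holds aligned-read intervals for one ChIP-seq library
#' (one histone-modification replicate) plus the library size used for
#' depth normalization.
#'
#' @param intervals a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), typically from [read_bed()].
#' @param total_mapped total mapped reads in the library; defaults to the
#'   number of intervals.
#' @return An object of class `read_set`.
#' @export
read_set <- function(intervals, total_mapped = nrow(intervals)) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (total_mapped < nrow(intervals)) {
    stop("total_mapped cannot be smaller than the number of stored reads")
  }
  structure(list(intervals = as.data.frame(intervals)[c("chrom", "start", "end")],
                 total_mapped = as.double(total_mapped)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads on %d chromosome(s), total_mapped = %g\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              x$total_mapped))
  invisible(x)
}

#' Binned genomic signal track
#'
#' Fixed-width bin values for one histone mark, one numeric vector per
#' chromosome. Bin `i` (0-based) covers `[i * bin_width, (i+1) * bin_width)`.
#'
#' @param mark histone-modification name.
#' @param values named list of per-chromosome numeric vectors.
#' @param bin_width bin width in bp.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(mark, values, bin_width = 100) {
  stopifnot(is.list(values), !is.null(names(values)), bin_width > 0)
  if (any(unlist(values, use.names = FALSE) < 0)) {
    stop("track values must be non-negative")
  }
  structure(list(mark = mark, bin_width = as.integer(bin_width),
                 values = values),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s: %d bp bins, %s\n", x$mark, x$bin_width,
              paste(sprintf("%s (%d bins)", names(x$values),
                            lengths(x$values)), collapse = ", ")))
  invisible(x)
}

#' Count reads into fixed-width genomic bins
#'
#' Each read is assigned to exactly one bin — the bin containing its 5'-most
#' coordinate (`assign = "start"`, the default) or its midpoint
#' (`assign = "midpoint"`). Reads whose assigned coordinate falls outside the
#' declared chromosome length, or on an undeclared chromosome, are dropped
#' with a warning.
#'
#' @param reads a [read_set].
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param bin_width bin width in bp.
#' @param assign `"start"` or `"midpoint"` read-to-bin assignment rule.
#' @return Named list of per-chromosome integer count vectors of length
#'   `ceiling(length / bin_width)`.
#' @export
bin_reads <- function(reads, chrom_sizes, bin_width = 100,
                      assign = c("start", "midpoint")) {
  assign <- match.arg(assign)
  stopifnot(bin_width > 0, length(chrom_sizes) > 0)
  iv <- reads$intervals
  pos <- if (assign == "start") iv$start else (iv$start + iv$end) %/% 2L
  counts <- lapply(chrom_sizes, function(len) {
    integer(ceiling(len / bin_width))
  })
  dropped <- 0L
  for (chr in names(chrom_sizes)) {
    sel <- iv$chrom == chr
    p <- pos[sel]
    ok <- p >= 0L & p < chrom_sizes[[chr]]
    dropped <- dropped + sum(!ok)
    b <- p[ok] %/% bin_width + 1L
    tab <- tabulate(b, nbins = length(counts[[chr]]))
    counts[[chr]] <- counts[[chr]] + tab
  }
  dropped <- dropped + sum(!(iv$chrom %in% names(chrom_sizes)))
  if (dropped > 0L) {
    warning(sprintf("%d read(s) outside the declared chromosomes were dropped",
                    dropped))
  }
  counts
}

#' RPKM-normalize binned read counts
#'
#' Reads per kilobase of bin per million mapped reads:
#' `count / (bin_width/1000) / (total_mapped/1e6)`. For 100 bp bins this is
#' `count * 1e7 / total_mapped`.
#'
#' @param counts per-chromosome count list from [bin_reads()].
#' @param total_mapped library size (must be positive).
#' @param bin_width bin width in bp.
#' @param mark mark name recorded on the returned track.
#' @return A [binned_track] in RPKM units.
#' @export
rpkm_normalize <- function(counts, total_mapped, bin_width = 100,
                           mark = "mark") {
  if (total_mapped <= 0) stop("total_mapped must be positive to RPKM-normalize")
  scale <- 1 / (bin_width / 1000) / (total_mapped / 1e6)
  binned_track(mark, lapply(counts, function(v) as.double(v) * scale),
               bin_width)
}

#' Average replicate tracks of one mark
#'
#' Element-wise arithmetic mean of RPKM tracks; replicates must share the
#' mark, bin width and chromosome layout.
#'
#' @param tracks list of [binned_track]s for the same mark.
#' @return A single averaged [binned_track].
#' @export
average_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  first <- tracks[[1L]]
  for (tr in tracks[-1L]) {
    if (!identical(tr$mark, first$mark) ||
        !identical(tr$bin_width, first$bin_width) ||
        !identical(names(tr$values), names(first$values)) ||
        !identical(lengths(tr$values), lengths(first$values))) {
      stop("replicate tracks must share mark, bin width and chromosomes")
    }
  }
  vals <- lapply(names(first$values), function(chr) {
    Reduce(`+`, lapply(tracks, function(tr) tr$values[[chr]])) / length(tracks)
  })
  names(vals) <- names(first$values)
  binned_track(first$mark, vals, first$bin_width)
}

#' Subtract an input-control track
#'
#' Optional input normalization: per-bin subtraction of the control RPKM,
#' floored at zero. Off by default in the pipeline; the appropriate
#' treatment of input libraries is assay-dependent.
#'
#' @param track,control [binned_track]s with identical layout.
#' @return A [binned_track].
#' @export
subtract_control <- function(track, control) {
  if (!identical(names(track$values), names(control$values)) ||
      !identical(lengths(track$values), lengths(control$values))) {
    stop("track and control must share chromosome layout")
  }
  vals <- lapply(names(track$values), function(chr) {
    pmax(track$values[[chr]] - control$values[[chr]], 0)
  })
  names(vals) <- names(track$values)
  binned_track(track$mark, vals, track$bin_width)
}

#' Write a binned track as tab-separated text
#'
#' Columns: chrom, bin_start, value. Zero bins are included so the file
#' round-trips the full layout.
#'
#' @param track a [binned_track].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    data.frame(chrom = chr,
               bin_start = (seq_along(v) - 1L) * track$bin_width,
               value = v)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
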