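#' Peak-call tables
#'
#' Peak calls are stored as a plain `data.frame` of class `"peak_calls"` with
#' columns `chrom` (character), `start`, `end` (0-based half-open, integers),
#' `summit` (integer base position inside `[start, end)`) and `element_class`
#' (one of `"DHS"`, `"TSS"`, `"P300"`, `"CBP"`, `"TFBS"`, `"UNKNOWN"`).
#' Strand is ignored throughout: none of the geometric rules used here
#' (summit distance, any-bp overlap) depend on it.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer base positions, 0-based half-open (BED semantics).
#' @param element_class functional-element class label, recycled.
#' @param summit integer summit positions; defaults to the interval midpoint
#'   `floor((start + end) / 2)`.
#' @return A `peak_calls` data.frame.
#' @export
peak_calls <- function(chrom, start, end, element_class = "UNKNOWN",
                       summit = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L)) {
    stop("peak starts must be >= 0 (0-based coordinates)")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("invalid interval at row %d: start (%d) >= end (%d)",
                 bad, start[bad], end[bad]))
  }
  element_class <- match_element_class(element_class)
  if (is.null(summit)) {
    summit <- (start + end) %/% 2L
  }
  summit <- as.integer(summit)
  if (any(summit < start | summit >= end)) {
    bad <- which(summit < start | summit >= end)[1L]
    stop(sprintf("summit at row %d (%d) lies outside [%d, %d)",
                 bad, summit[bad], start[bad], end[bad]))
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    summit = summit,
                    element_class = rep_len(element_class, length(start)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_calls", "data.frame")
  out
}

ELEMENT_CLASSES <- c("DHS", "TSS", "P300", "CBP", "TFBS", "UNKNOWN")

match_element_class <- function(x) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), ELEMENT_CLASSES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown element class: %s (expected one of %s)",
                 paste(bad, collapse = ", "),
                 paste(ELEMENT_CLASSES, collapse = ", ")))
  }
  x
}

empty_peak_calls <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), summit = integer(0),
                    element_class = character(0), stringsAsFactors = FALSE)
  class(out) <- c("peak_calls", "data.frame")
  out
}

#' Read a BED3+ file as peak calls
#'
#' Parses a tab-separated BED file (3 or more columns). Lines beginning with
#' `#`, `track` or `browser` are skipped. Coordinates are taken as written
#' (0-based, half-open). The peak summit defaults to the interval midpoint;
#' set `summit_col` to the 1-based index of a column holding an absolute
#' summit position to use a caller-provided summit instead.
#'
#' @param path path to a BED file.
#' @param element_class class label attached to every record.
#' @param summit_col optional 1-based column index containing an absolute
#'   summit base position.
#' @return A [peak_calls] data.frame, one row per BED record, input order
#'   preserved.
#' @export
read_bed <- function(path, element_class = "UNKNOWN", summit_col = NULL) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_peak_calls())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                 lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: start/end are not integers",
                 lineno[which(is.na(start) | is.na(end))[1L]]))
  }
  if (any(start >= end)) {
    stop(sprintf("invalid interval at BED line %d: start >= end",
                 lineno[which(start >= end)[1L]]))
  }
  summit <- NULL
  if (!is.null(summit_col)) {
    if (any(nf < summit_col)) {
      stop(sprintf("BED line %d has no column %d for the summit",
                   lineno[which(nf < summit_col)[1L]], summit_col))
    }
    summit <- suppressWarnings(
      as.integer(vapply(fields, `[[`, "", summit_col)))
    if (anyNA(summit)) {
      stop(sprintf("malformed summit at BED line %d",
                   lineno[which(is.na(summit))[1L]]))
    }
  }
  peak_calls(chrom, start, end, element_class, summit = summit)
}

#' Write peak calls as BED
#'
#' Writes `chrom`, `start`, `end` (and the class label as the BED name
#' column) tab-separated, no header, so that [read_bed()] round-trips the
#' coordinate triple exactly.
#'
#' @param peaks a [peak_calls] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$element_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peaks_to_granges <- function(peaks, use_summit = FALSE) {
  if (nrow(peaks) == 0L) return(GenomicRanges::GRanges())
  if (use_summit) {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(start = peaks$summit + 1L,
                                            width = 1L))
  } else {
    # BED half-open -> 1-based closed
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(start = peaks$start + 1L,
                                            end = peaks$end))
  }
}

#' Summit-to-summit distance between two peaks
#'
#' Distances throughout the pipeline are measured between peak summits, which
#' anchors every rule ("distal to TSS", "within 2.5 kb of a marker") on the
#' experimentally localized peak position. Peaks on different chromosomes are
#' at infinite distance by convention, so no cross-chromosome rule ever fires.
#'
#' @param a,b single-row [peak_calls].
#' @return Non-negative distance in bp, or `Inf` across chromosomes.
#' @export
center_distance <- function(a, b) {
  if (a$chrom != b$chrom) return(Inf)
  abs(a$summit - b$summit)
}

# Distance from each query summit to the nearest reference summit (Inf when
# no reference summit shares the chromosome). Vectorized over queries.
nearest_summit_distance <- function(query, reference) {
  n <- nrow(query)
  if (n == 0L) return(numeric(0))
  out <- rep(Inf, n)
  if (nrow(reference) == 0L) return(out)
  ref_split <- split(reference$summit, reference$chrom)
  for (chr in names(ref_split)) {
    idx <- which(query$chrom == chr)
    if (length(idx) == 0L) next
    ref <- sort(ref_split[[chr]])
    pos <- query$summit[idx]
    j <- findInterval(pos, ref)
    d_lo <- ifelse(j >= 1L, pos - ref[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(ref), ref[pmin(j + 1L, length(ref))] - pos, Inf)
    out[idx] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}

#' Is a site distal to every reference peak?
#'
#' @param site single-row [peak_calls].
#' @param reference reference [peak_calls] (e.g. TSS).
#' @param min_dist minimum summit-to-summit distance in bp (strict `>`).
#' @return `TRUE` iff the nearest reference summit is more than `min_dist`
#'   away. An empty reference is vacuously distal (with a warning).
#' @export
is_distal <- function(site, reference, min_dist = 1000) {
  if (nrow(reference) == 0L) {
    warning("empty reference set: site is vacuously distal")
    return(TRUE)
  }
  nearest_summit_distance(site, reference) > min_dist
}

#' Does a site overlap any reference interval?
#'
#' Overlap means sharing at least one base (half-open semantics: `[a,b)` and
#' `[b,c)` do not overlap). With `summit_only = TRUE` the test instead asks
#' whether the site's summit falls inside a reference interval.
#'
#' @param site single-row [peak_calls].
#' @param reference reference [peak_calls].
#' @param summit_only require the site summit to be contained in a reference
#'   interval rather than any-bp overlap.
#' @return logical.
#' @export
overlaps_any <- function(site, reference, summit_only = FALSE) {
  length(which_overlap(site, reference, summit_only)) > 0L
}

# Indices of `query` rows that overlap >= 1 bp of `reference` (or whose
# summit is contained in a reference interval when summit_only).
which_overlap <- function(query, reference, summit_only = FALSE) {
  if (nrow(query) == 0L || nrow(reference) == 0L) return(integer(0))
  q <- peaks_to_granges(query, use_summit = summit_only)
  r <- peaks_to_granges(reference)
  # disjoint chromosome sets are an expected no-overlap case, not a problem
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, r))
  unique(S4Vectors::queryHits(hits))
}
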