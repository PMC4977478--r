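#' Build the true-positive-marker (TPM) set
#'
#' TPMs are the experimentally supported enhancer markers used to validate
#' predictions: DHS, p300, CBP and TFBS peaks whose summits are more than
#' `min_dist` bp from every TSS summit. A prediction near a TPM is counted
#' as validated; everything else is counted as an error, since a
#' non-marker, non-TSS site is known not to be an enhancer.
#'
#' @param dhs,p300,cbp,tfbs marker [peak_calls] (any may be empty).
#' @param tss TSS [peak_calls].
#' @param min_dist minimum summit distance from any TSS, bp (strict `>`).
#' @return [peak_calls] with the distal markers.
#' @export
build_tpm_set <- function(dhs, p300, cbp, tfbs, tss, min_dist = 1000) {
  pool <- do.call(rbind, lapply(list(dhs, p300, cbp, tfbs), as.data.frame))
  class(pool) <- c("peak_calls", "data.frame")
  if (nrow(pool) == 0L) return(empty_peak_calls())
  out <- pool[nearest_summit_distance(pool, tss) > min_dist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

prediction_summits <- function(locations, bin_width = 100) {
  if (!is.null(locations$summit)) return(as.integer(locations$summit))
  if (!is.null(locations$bin)) {
    return(as.integer(locations$bin * bin_width + bin_width %/% 2L))
  }
  stop("locations need a 'summit' or 'bin' column")
}

# TRUE for each location whose summit is within `radius` bp (inclusive,
# summit-to-summit, same chromosome) of some TPM summit.
validated_flags <- function(locations, tpm, radius = 2500, bin_width = 100) {
  q <- data.frame(chrom = locations$chrom,
                  summit = prediction_summits(locations, bin_width))
  nearest_summit_distance(q, tpm) <= radius
}

#' Validate enhancer predictions against TPMs
#'
#' A prediction is validated iff some TPM summit lies within `radius` bp
#' (inclusive, summit-to-summit, same chromosome) of the predicted
#' location's summit (the center of its bin, when given as bins).
#'
#' @param locations data.frame of predicted locations with `chrom` and
#'   either `summit` (bp) or `bin` (0-based bin index).
#' @param tpm TPM [peak_calls] from [build_tpm_set()].
#' @param radius validation radius in bp.
#' @param bin_width bin width used to convert bins to summits.
#' @return An object of class `validation_result`: `n_predictions`,
#'   `n_validated`, `rate` (`NA` — undefined, not zero — when there are no
#'   predictions) and `defined`.
#' @export
validate_predictions <- function(locations, tpm, radius = 2500,
                                 bin_width = 100) {
  n <- nrow(locations)
  if (n == 0L) {
    return(structure(list(n_predictions = 0L, n_validated = 0L,
                          rate = NA_real_, defined = FALSE),
                     class = "validation_result"))
  }
  ok <- validated_flags(locations, tpm, radius, bin_width)
  structure(list(n_predictions = n, n_validated = sum(ok),
                 rate = sum(ok) / n, defined = TRUE),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  if (!x$defined) {
    cat("<validation_result> no predictions (rate undefined)\n")
  } else {
    cat(sprintf("<validation_result> %d / %d predictions validated (%.2f%%)\n",
                x$n_validated, x$n_predictions, 100 * x$rate))
  }
  invisible(x)
}

#' Sweep the decision threshold
#'
#' For each threshold (strictly descending), counts the locations whose
#' score strictly exceeds it and their validation rate. As the threshold
#' decreases, the prediction and validated counts are non-decreasing. A
#' threshold with no predictions reports `NA` (undefined) rate.
#'
#' @param scores raw model scores, aligned with `locations`.
#' @param locations data.frame with `chrom` and `bin` (or `summit`).
#' @param tpm TPM [peak_calls].
#' @param thresholds strictly descending numeric vector.
#' @param radius validation radius, bp.
#' @param bin_width bin width, bp.
#' @return data.frame: `threshold`, `n_predictions`, `n_validated`, `rate`.
#' @export
threshold_sweep <- function(scores, locations, tpm, thresholds,
                            radius = 2500, bin_width = 100) {
  stopifnot(length(scores) == nrow(locations))
  if (length(thresholds) > 1L && any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly descending")
  }
  ok <- validated_flags(locations, tpm, radius, bin_width)
  rows <- lapply(thresholds, function(th) {
    sel <- scores > th
    n <- sum(sel)
    v <- sum(ok & sel)
    data.frame(threshold = th, n_predictions = n, n_validated = v,
               rate = if (n > 0L) v / n else NA_real_)
  })
  do.call(rbind, rows)
}

#' Operating point at a matched prediction count
#'
#' Builds a descending threshold grid from the score quantiles, sweeps it,
#' and returns the row whose prediction count is closest to `n_target`
#' (ties go to the higher threshold). Comparing models at matched
#' prediction counts removes the dependence of the raw-score scale on the
#' feature set and architecture.
#'
#' @param scores raw model scores.
#' @param locations data.frame with `chrom` and `bin` (or `summit`).
#' @param tpm TPM [peak_calls].
#' @param n_target prediction count to match.
#' @param radius validation radius, bp.
#' @param bin_width bin width, bp.
#' @param n_thresholds quantile grid size.
#' @return one-row data.frame: `threshold`, `n_predictions`,
#'   `n_validated`, `validation_rate`.
#' @export
operating_point <- function(scores, locations, tpm, n_target,
                            radius = 2500, bin_width = 100,
                            n_thresholds = 50) {
  qs <- stats::quantile(scores, probs = seq(1, 0, length.out = n_thresholds),
                        names = FALSE)
  thresholds <- sort(unique(qs), decreasing = TRUE)
  sweep <- threshold_sweep(scores, locations, tpm, thresholds,
                           radius = radius, bin_width = bin_width)
  best <- which.min(abs(sweep$n_predictions - n_target))
  data.frame(threshold = sweep$threshold[best],
             n_predictions = sweep$n_predictions[best],
             n_validated = sweep$n_validated[best],
             validation_rate = sweep$rate[best])
}

#' Histogram-intersection overlap of two score distributions
#'
#' Bins both samples on a shared grid of `n_bins` equal-width bins spanning
#' the pooled range and returns `sum_b min(p_a(b), p_b(b))` where `p` are
#' the per-sample bin frequencies. 1 for identical distributions, 0 for
#' disjoint supports. Used to quantify how strongly the signal
#' distributions of two functional classes overlap.
#'
#' @param values_a,values_b non-empty numeric samples.
#' @param n_bins number of shared histogram bins.
#' @return overlap fraction in `[0, 1]`.
#' @export
distribution_overlap <- function(values_a, values_b, n_bins = 100) {
  stopifnot(length(values_a) > 0L, length(values_b) > 0L)
  pooled <- range(c(values_a, values_b))
  if (pooled[1L] == pooled[2L]) return(1)
  breaks <- seq(pooled[1L], pooled[2L], length.out = n_bins + 1L)
  pa <- graphics::hist(values_a, breaks = breaks, plot = FALSE)$counts
  pb <- graphics::hist(values_b, breaks = breaks, plot = FALSE)$counts
  sum(pmin(pa / length(values_a), pb / length(values_b)))
}

#' Per-site windowed mean signal
#'
#' Mean track value over a `window_bins`-wide window at each peak's summit
#' bin. `window_bins = 1` gives the peak-bin value itself; an even window of
#' width w covers offsets `-w/2 .. w/2 - 1`.
#'
#' @param track a [binned_track].
#' @param peaks [peak_calls].
#' @param window_bins odd or even total window width in bins.
#' @return numeric vector, one mean per peak.
#' @export
site_signal <- function(track, peaks, window_bins = 1) {
  stopifnot(window_bins >= 1L)
  offsets <- if (window_bins == 1L) 0L else
    seq(-(window_bins %/% 2L), length.out = window_bins)
  vapply(seq_len(nrow(peaks)), function(i) {
    v <- track$values[[peaks$chrom[i]]]
    if (is.null(v)) stop(sprintf("track has no chromosome %s", peaks$chrom[i]))
    idx <- peaks$summit[i] %/% track$bin_width + offsets + 1L
    vals <- numeric(length(idx))
    okv <- idx >= 1L & idx <= length(v)
    vals[okv] <- v[idx[okv]]
    mean(vals)
  }, numeric(1L))
}

#' Class-distribution overlap of neighborhood-averaged signal
#'
#' The histogram-intersection overlap of two site classes computed on
#' per-site window means instead of single peak-bin values; with a window
#' of 1 bin this reduces exactly to [distribution_overlap()] on peak-bin
#' values.
#'
#' @param track a [binned_track].
#' @param sites_a,sites_b [peak_calls] for the two classes.
#' @param window_bins total window width in bins.
#' @param n_bins shared histogram bins.
#' @return overlap fraction in `[0, 1]`.
#' @export
neighborhood_average_overlap <- function(track, sites_a, sites_b,
                                         window_bins = 20, n_bins = 100) {
  distribution_overlap(site_signal(track, sites_a, window_bins),
                       site_signal(track, sites_b, window_bins),
                       n_bins = n_bins)
}

#' Write predictions as a BED file
#'
#' One record per predicted bin: chrom, bin start, bin end, and the raw
#' score in the BED score column.
#'
#' @param locations data.frame with `chrom` and `bin`.
#' @param scores aligned raw scores.
#' @param path output path.
#' @param bin_width bin width, bp.
#' @return `path`, invisibly.
#' @export
write_predictions_bed <- function(locations, scores, path, bin_width = 100) {
  df <- data.frame(locations$chrom, locations$bin * bin_width,
                   (locations$bin + 1L) * bin_width,
                   sprintf("%.6g", scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
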