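#' Select positive (enhancer) training sites
#'
#' Training positives are p300 co-activator peaks that overlap a DNase-I
#' hypersensitive site and whose summit is distal (more than `min_dist` bp,
#' summit-to-summit) from every transcription start site. Distal
#' DHS-supported p300 binding marks active enhancers while excluding
#' promoter-proximal p300 binding.
#'
#' @param p300 p300 [peak_calls].
#' @param dhs DHS [peak_calls].
#' @param tss TSS [peak_calls].
#' @param min_dist minimum summit distance to any TSS, bp.
#' @param summit_only use summit-containment instead of any-bp overlap for
#'   the DHS filter.
#' @return The selected subset of `p300`.
#' @export
select_positive_training <- function(p300, dhs, tss, min_dist = 1000,
                                     summit_only = FALSE) {
  if (nrow(p300) == 0L) return(p300)
  keep_overlap <- which_overlap(p300, dhs, summit_only = summit_only)
  distal <- nearest_summit_distance(p300, tss) > min_dist
  p300[intersect(keep_overlap, which(distal)), , drop = FALSE]
}

#' Select negative (non-enhancer) training sites
#'
#' Negatives are the union of (i) TSS that overlap a DHS — promoters in open
#' chromatin, the hard negatives a p300-trained classifier must reject — and
#' (ii) `n_random` random 100 bp bins whose centers are more than `min_dist`
#' bp from every DHS and TSS summit (quiescent background). Background draws
#' are rejection-sampled and reproducible from `seed`.
#'
#' @param tss TSS [peak_calls].
#' @param dhs DHS [peak_calls].
#' @param chrom_sizes named chromosome lengths, bp.
#' @param n_random number of random background bins.
#' @param min_dist minimum summit distance of a background bin from any
#'   DHS/TSS summit, bp.
#' @param seed integer seed for the background draw.
#' @param bin_width width of the random background bins, bp.
#' @return [peak_calls] with element classes `TSS` and `UNKNOWN`
#'   (background).
#' @export
select_negative_training <- function(tss, dhs, chrom_sizes, n_random,
                                     min_dist = 1000, seed = 1,
                                     bin_width = 100) {
  stopifnot(n_random >= 0)
  tss_open <- tss[which_overlap(tss, dhs), , drop = FALSE]
  if (n_random == 0L) return(tss_open)
  avoid <- rbind(as.data.frame(tss)[c("chrom", "start", "end", "summit",
                                      "element_class")],
                 as.data.frame(dhs)[c("chrom", "start", "end", "summit",
                                      "element_class")])
  class(avoid) <- c("peak_calls", "data.frame")
  bg <- withr::with_seed(seed, {
    draw_background_bins(avoid, chrom_sizes, n_random, min_dist, bin_width)
  })
  out <- rbind(as.data.frame(tss_open), as.data.frame(bg))
  class(out) <- c("peak_calls", "data.frame")
  out
}

draw_background_bins <- function(avoid, chrom_sizes, n_random, min_dist,
                                 bin_width) {
  got <- empty_peak_calls()
  attempts <- 0L
  max_attempts <- 1000L
  probs <- chrom_sizes / sum(chrom_sizes)
  while (nrow(got) < n_random && attempts < max_attempts) {
    attempts <- attempts + 1L
    n_draw <- 2L * (n_random - nrow(got))
    chr <- sample(names(chrom_sizes), n_draw, replace = TRUE, prob = probs)
    bin <- floor(stats::runif(n_draw) * (chrom_sizes[chr] %/% bin_width))
    start <- as.integer(bin * bin_width)
    cand <- peak_calls(chr, start, start + bin_width, "UNKNOWN")
    ok <- nearest_summit_distance(cand, avoid) > min_dist
    cand <- cand[ok, , drop = FALSE]
    got <- rbind(as.data.frame(got), as.data.frame(cand))
    got <- got[!duplicated(got[c("chrom", "start")]), , drop = FALSE]
    class(got) <- c("peak_calls", "data.frame")
  }
  if (nrow(got) < n_random) {
    stop(sprintf(paste0("could not place %d background bins distal to ",
                        "DHS/TSS after %d draws (achieved %d)"),
                 n_random, max_attempts, nrow(got)))
  }
  out <- got[seq_len(n_random), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Labeled dataset
#'
#' Bundles a [assemble_features()] feature matrix with binary labels
#' (1 = enhancer, 0 = non-enhancer) and a per-row provenance class.
#'
#' @param features a `feature_matrix`.
#' @param labels integer vector in `{0, 1}`, one per row.
#' @param provenance character vector, one per row, in
#'   `{P300, CBP, TFBS, TSS, RANDOM_BG}`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, provenance) {
  stopifnot(nrow(features$samples) == length(labels),
            length(labels) == length(provenance),
            all(labels %in% c(0L, 1L)))
  pos <- provenance %in% c("P300", "CBP", "TFBS")
  neg <- provenance %in% c("TSS", "RANDOM_BG")
  if (!all(pos | neg)) stop("unknown provenance class")
  if (any(labels[pos] != 1L) || any(labels[neg] != 0L)) {
    stop("labels inconsistent with provenance classes")
  }
  structure(list(features = features, labels = as.integer(labels),
                 provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("<labeled_dataset> %d rows (%d positive / %d negative): %s\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

peak_locations <- function(peaks, bin_width = 100) {
  data.frame(chrom = peaks$chrom, bin = peaks$summit %/% as.integer(bin_width),
             stringsAsFactors = FALSE)
}

provenance_of <- function(peaks) {
  ifelse(peaks$element_class == "UNKNOWN", "RANDOM_BG", peaks$element_class)
}

#' Build the training set at a fixed class ratio
#'
#' Assembles features at every peak's summit bin and subsamples the
#' negatives to `ratio` negatives per positive. Subsampling is uniform
#' within each negative provenance class (TSS vs. random background), so
#' the TSS:background proportion of the input pool is preserved.
#'
#' @param positives positive [peak_calls] (from
#'   [select_positive_training()]).
#' @param negatives negative [peak_calls] (from
#'   [select_negative_training()]).
#' @param tracks named list of [binned_track]s.
#' @param spec a [feature_spec].
#' @param ratio negatives per positive (the working default is 1:10).
#' @param seed seed for the negative subsample.
#' @return A [labeled_dataset].
#' @export
build_training_set <- function(positives, negatives, tracks, spec,
                               ratio = 10, seed = 1) {
  if (nrow(positives) == 0L) stop("no positive training sites")
  n_neg <- round(ratio * nrow(positives))
  if (nrow(negatives) < n_neg) {
    stop(sprintf("need %d negatives for a 1:%g ratio but only %d available",
                 n_neg, ratio, nrow(negatives)))
  }
  prov_neg <- provenance_of(negatives)
  keep <- withr::with_seed(seed, {
    # proportional (stratified) allocation across negative classes
    idx_by_class <- split(seq_len(nrow(negatives)), prov_neg)
    alloc <- round(lengths(idx_by_class) / nrow(negatives) * n_neg)
    # fix rounding so the total is exact
    while (sum(alloc) != n_neg) {
      j <- which.max(lengths(idx_by_class) - alloc)
      alloc[j] <- alloc[j] + sign(n_neg - sum(alloc))
    }
    unlist(Map(function(idx, k) sort(sample(idx, min(k, length(idx)))),
               idx_by_class, alloc), use.names = FALSE)
  })
  negatives <- negatives[keep, , drop = FALSE]
  peaks <- rbind(as.data.frame(positives), as.data.frame(negatives))
  fm <- assemble_features(tracks, peak_locations(peaks, spec$bin_width), spec)
  labels <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  labeled_dataset(fm, labels, provenance_of(peaks))
}

#' Build the test set
#'
#' Positives are all known distal DHS-overlapping co-activator and TF
#' binding sites (p300, CBP, TFBS); negatives are TSS. Duplicate sites
#' appearing in more than one positive class are deduplicated by
#' (chromosome, summit bin), keeping the first occurrence in p300, CBP,
#' TFBS order. Element classes unavailable for a cell type are passed as
#' empty peak sets.
#'
#' @param p300,cbp,tfbs positive-class [peak_calls].
#' @param dhs,tss DHS and TSS [peak_calls].
#' @param tracks named list of [binned_track]s.
#' @param spec a [feature_spec].
#' @param min_dist TSS-distal threshold, bp.
#' @param dhs_filter_tss also require test TSS to overlap a DHS (off by
#'   default; training negatives are DHS-filtered but test TSS are taken
#'   as-is).
#' @return A [labeled_dataset].
#' @export
build_test_set <- function(p300, cbp, tfbs, dhs, tss, tracks, spec,
                           min_dist = 1000, dhs_filter_tss = FALSE) {
  pos_pool <- list(p300, cbp, tfbs)
  pos <- do.call(rbind, lapply(pos_pool, as.data.frame))
  class(pos) <- c("peak_calls", "data.frame")
  if (nrow(pos) > 0L) {
    keep <- intersect(which_overlap(pos, dhs),
                      which(nearest_summit_distance(pos, tss) > min_dist))
    pos <- pos[sort(keep), , drop = FALSE]
    bin <- pos$summit %/% spec$bin_width
    pos <- pos[!duplicated(data.frame(pos$chrom, bin)), , drop = FALSE]
  }
  neg <- tss
  if (dhs_filter_tss && nrow(neg) > 0L) {
    neg <- neg[which_overlap(neg, dhs), , drop = FALSE]
  }
  peaks <- rbind(as.data.frame(pos), as.data.frame(neg))
  class(peaks) <- c("peak_calls", "data.frame")
  fm <- assemble_features(tracks, peak_locations(peaks, spec$bin_width), spec)
  labels <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  labeled_dataset(fm, labels, provenance_of(peaks))
}

#' Write a labeled dataset as delimited text
#'
#' Tab-separated: location columns, label, provenance, then one column per
#' feature named `mark@offset`.
#'
#' @param dataset a [labeled_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- cbind(dataset$features$locations[c("chrom", "bin")],
              label = dataset$labels, provenance = dataset$provenance,
              as.data.frame(dataset$features$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
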