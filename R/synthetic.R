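#' Default synthetic mark panel
#'
#' Twelve histone marks with per-class Gaussian-bump enrichment parameters.
#' Four marks are informative — their expected peak-bin read count differs
#' between enhancer-class sites (p300/CBP/TFBS) and the non-enhancer
#' classes — and eight are class-independent noise: flat at planted sites,
#' with decoy enrichment domains placed at positions uncorrelated with any
#' site, so their signal distribution is identical for enhancer and
#' non-enhancer locations. Informative marks also carry decoy domains (at
#' somewhat lower amplitude): enhancer-associated chromatin signal occurs
#' at plenty of non-enhancer loci, which is what makes single marks
#' ambiguous and the combinatorial code across marks informative — a decoy
#' lights one mark, a true enhancer lights all four. Informative marks are
#' given the wider flanks characteristic of enhancer chromatin
#' (H3K4me1-like), with amplitudes around 20 expected reads at the peak bin
#' versus 2 at promoters over a background of ~1 read per bin; these
#' defaults are illustrative signal shapes, not measured biology.
#'
#' @return data.frame with columns `mark`, `enhancer_amplitude`,
#'   `tss_amplitude`, `decoy_amplitude`, `sigma` (Gaussian width in bp).
#' @export
default_mark_table <- function() {
  data.frame(
    mark = c("H3K4me1", "H3K27ac", "H3K4me2", "H3K9ac",
             "H3K4me3", "H3K27me3", "H3K36me3", "H3K9me3",
             "H4K20me1", "H3K79me2", "H2AZ", "H2BK120ac"),
    enhancer_amplitude = c(20, 18, 16, 14, 0, 0, 0, 0, 0, 0, 0, 0),
    tss_amplitude = c(2, 2, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0),
    decoy_amplitude = c(12, 11, 10, 9, 5, 5, 5, 5, 5, 5, 5, 5),
    sigma = c(400, 300, 250, 200, 200, 400, 400, 400, 300, 300, 200, 250),
    stringsAsFactors = FALSE)
}

#' Synthetic-epigenome specification
#'
#' Describes a fully synthetic study genome: chromosome sizes, how many
#' sites of each functional class to plant, the per-mark enrichment model
#' (see [default_mark_table()]), and the Poisson background. Reads for each
#' mark are drawn per 100 bp bin from a Poisson whose mean is the background
#' rate plus a Gaussian bump `amplitude * exp(-d^2 / (2 sigma^2))` for every
#' nearby planted site. DHS peaks are co-placed at every enhancer-class
#' site, and (by default) at TSS sites as well, mirroring the open chromatin
#' found at both enhancers and active promoters. Marks with a nonzero
#' `decoy_amplitude` additionally receive `n_decoy_sites` Gaussian bumps at
#' per-mark random positions independent of the planted sites, so
#' class-independent marks still carry realistic structured signal.
#'
#' @param chrom_sizes named chromosome lengths in bp.
#' @param n_sites named site counts for classes `P300`, `CBP`, `TFBS`,
#'   `TSS`.
#' @param marks mark parameter table, as in [default_mark_table()].
#' @param background_rate expected background reads per bin.
#' @param min_spacing minimum distance between planted site summits, bp.
#' @param n_decoy_sites number of per-mark decoy enrichment domains.
#' @param site_strength_shape Gamma shape parameter for the per-site,
#'   per-mark enrichment strength multiplier (mean 1). Real functional
#'   sites express each mark at widely varying levels, which makes the
#'   class-conditional signal distributions overlap substantially instead
#'   of separating cleanly; smaller shape = more dispersion. `Inf` disables
#'   the dispersion.
#' @param enhancer_bimodal_offset distance in bp between an enhancer-class
#'   site's summit and each of its two flanking enrichment peaks. Histone
#'   marks at active enhancers flank the nucleosome-free region where the
#'   co-activator binds, giving a characteristic double-peaked profile with
#'   a central dip, whereas generic enrichment domains (the decoys here)
#'   are single bumps — so the enhancer's signature lives in the spatial
#'   profile across the window, not in the central bin alone. `0` makes
#'   enhancer bumps unimodal.
#' @param peak_width reported peak-call interval width, bp.
#' @param dhs_width reported DHS interval width, bp.
#' @param dhs_at_tss also co-place a DHS at every TSS site.
#' @param reads_per_mark declared library size (total mapped reads) used for
#'   RPKM normalization. The synthetic chromosomes stand in for a small
#'   window of a genome-scale experiment, so the library size is declared
#'   rather than equal to the reads drawn inside the window; the default of
#'   1e7 puts RPKM values on the scale of real ChIP-seq libraries.
#' @param n_replicates independent read replicates per mark.
#' @param bin_width bin width, bp.
#' @param seed integer seed; the whole genome is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(chrom_sizes = c(chr1 = 2.5e6, chr2 = 2.5e6),
                           n_sites = c(P300 = 200, CBP = 50, TFBS = 50,
                                       TSS = 150),
                           marks = default_mark_table(),
                           background_rate = 1, min_spacing = 5000,
                           n_decoy_sites = 200, site_strength_shape = 2,
                           enhancer_bimodal_offset = 300,
                           peak_width = 300, dhs_width = 1000,
                           dhs_at_tss = TRUE, reads_per_mark = 1e7,
                           n_replicates = 1, bin_width = 100, seed = 1) {
  # accept list forms (e.g. from YAML/JSON configs)
  chrom_sizes <- unlist(chrom_sizes)
  n_sites <- unlist(n_sites)
  marks <- as.data.frame(marks)
  stopifnot(all(chrom_sizes > 0), all(n_sites >= 0),
            all(c("P300", "CBP", "TFBS", "TSS") %in% names(n_sites)),
            all(marks$sigma > 0), all(marks$enhancer_amplitude >= 0),
            all(marks$tss_amplitude >= 0), background_rate >= 0,
            n_replicates >= 1, reads_per_mark > 0, n_decoy_sites >= 0,
            site_strength_shape > 0, enhancer_bimodal_offset >= 0)
  if (is.null(marks$decoy_amplitude)) marks$decoy_amplitude <- 0
  structure(list(chrom_sizes = chrom_sizes, n_sites = n_sites, marks = marks,
                 background_rate = background_rate,
                 min_spacing = min_spacing,
                 n_decoy_sites = as.integer(n_decoy_sites),
                 site_strength_shape = site_strength_shape,
                 enhancer_bimodal_offset = as.integer(enhancer_bimodal_offset),
                 peak_width = as.integer(peak_width),
                 dhs_width = as.integer(dhs_width), dhs_at_tss = dhs_at_tss,
                 reads_per_mark = reads_per_mark,
                 n_replicates = as.integer(n_replicates),
                 bin_width = as.integer(bin_width), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Marks whose class-conditional amplitudes differ
#' @param spec a [synthetic_spec].
#' @return character vector of informative mark names.
#' @export
informative_marks <- function(spec) {
  spec$marks$mark[spec$marks$enhancer_amplitude != spec$marks$tss_amplitude]
}

# Uniform placement of n summits on [margin, len - margin] with pairwise
# spacing >= min_spacing (exact construction: sorted uniforms plus offsets).
place_summits <- function(len, n, min_spacing, margin) {
  if (n == 0L) return(integer(0))
  free <- len - 2 * margin - (n - 1) * min_spacing
  if (free <= 0) {
    stop(sprintf(paste0("chromosome of %d bp cannot hold %d sites at ",
                        "%d bp spacing"), len, n, min_spacing))
  }
  u <- sort(stats::runif(n, 0, free))
  as.integer(round(margin + u + (seq_len(n) - 1L) * min_spacing))
}

#' Generate a synthetic epigenome
#'
#' Plants the sites, draws per-mark Poisson read counts around them, and
#' materializes reads as `bin_width` intervals at their bins. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @return An object of class `synthetic_truth`: `peaks` (named list of
#'   [peak_calls] for `P300`, `CBP`, `TFBS`, `TSS`, `DHS`), `reads` (named
#'   list, one list of replicate [read_set]s per mark), `sites` (all
#'   planted sites with their true classes) and `spec`.
#' @export
generate_epigenome <- function(spec) {
  withr::with_seed(spec$seed, generate_epigenome_impl(spec))
}

generate_epigenome_impl <- function(spec) {
  classes <- c("P300", "CBP", "TFBS", "TSS")
  n_total <- sum(spec$n_sites[classes])
  margin <- 2000
  # allocate sites to chromosomes proportionally to length
  alloc <- round(spec$chrom_sizes / sum(spec$chrom_sizes) * n_total)
  while (sum(alloc) != n_total) {
    alloc[which.max(spec$chrom_sizes)] <-
      alloc[which.max(spec$chrom_sizes)] + sign(n_total - sum(alloc))
  }
  site_rows <- lapply(names(spec$chrom_sizes), function(chr) {
    s <- place_summits(spec$chrom_sizes[[chr]], alloc[[chr]],
                       spec$min_spacing, margin)
    data.frame(chrom = chr, summit = s, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_rows)
  sites$class <- sample(rep(classes, times = spec$n_sites[classes]))
  half <- spec$peak_width %/% 2L
  site_peaks <- peak_calls(sites$chrom, sites$summit - half,
                           sites$summit - half + spec$peak_width,
                           sites$class, summit = sites$summit)
  peaks <- lapply(classes, function(cl) {
    out <- site_peaks[site_peaks$element_class == cl, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(peaks) <- classes
  dhs_sites <- sites$class %in% c("P300", "CBP", "TFBS") |
    (spec$dhs_at_tss & sites$class == "TSS")
  dhalf <- spec$dhs_width %/% 2L
  peaks$DHS <- peak_calls(sites$chrom[dhs_sites],
                          sites$summit[dhs_sites] - dhalf,
                          sites$summit[dhs_sites] - dhalf + spec$dhs_width,
                          "DHS", summit = sites$summit[dhs_sites])
  is_enh <- sites$class %in% c("P300", "CBP", "TFBS")
  strength <- function(n) {
    if (is.infinite(spec$site_strength_shape)) return(rep(1, n))
    stats::rgamma(n, shape = spec$site_strength_shape,
                  rate = spec$site_strength_shape)
  }
  reads <- lapply(seq_len(nrow(spec$marks)), function(m) {
    amp <- ifelse(is_enh, spec$marks$enhancer_amplitude[m],
                  spec$marks$tss_amplitude[m]) * strength(nrow(sites))
    bumps <- data.frame(chrom = sites$chrom, summit = sites$summit,
                        amplitude = amp, bimodal = is_enh,
                        stringsAsFactors = FALSE)
    if (spec$marks$decoy_amplitude[m] > 0 && spec$n_decoy_sites > 0L) {
      # per-mark decoy domains, uncorrelated with the planted sites
      dchr <- sample(names(spec$chrom_sizes), spec$n_decoy_sites,
                     replace = TRUE,
                     prob = spec$chrom_sizes / sum(spec$chrom_sizes))
      dpos <- as.integer(floor(stats::runif(spec$n_decoy_sites) *
                                 spec$chrom_sizes[dchr]))
      bumps <- rbind(bumps,
                     data.frame(chrom = dchr, summit = dpos,
                                amplitude = spec$marks$decoy_amplitude[m] *
                                  strength(spec$n_decoy_sites),
                                bimodal = FALSE,
                                stringsAsFactors = FALSE))
    }
    lapply(seq_len(spec$n_replicates), function(rep_i) {
      draw_mark_reads(spec, bumps, spec$marks$sigma[m])
    })
  })
  names(reads) <- spec$marks$mark
  structure(list(peaks = peaks, reads = reads, sites = site_peaks,
                 spec = spec),
            class = "synthetic_truth")
}

# One replicate of Poisson reads for one mark: per-bin mean = background +
# sum of bumps (truncated at 4 sigma around the furthest mode), one
# bin_width read per count. Enhancer-class bumps are double Gaussians at
# +/- enhancer_bimodal_offset (each mode at half amplitude); everything
# else is a single Gaussian.
draw_mark_reads <- function(spec, bumps, sigma) {
  bw <- spec$bin_width
  off <- spec$enhancer_bimodal_offset
  parts <- lapply(names(spec$chrom_sizes), function(chr) {
    nbins <- as.integer(ceiling(spec$chrom_sizes[[chr]] / bw))
    lambda <- rep(spec$background_rate, nbins)
    rows <- which(bumps$chrom == chr & bumps$amplitude > 0)
    reach <- ceiling((4 * sigma + off) / bw)
    for (i in rows) {
      center_bin <- bumps$summit[i] %/% bw
      b <- max(0L, center_bin - reach):min(nbins - 1L, center_bin + reach)
      d <- (b * bw + bw / 2) - bumps$summit[i]
      shape <- if (isTRUE(bumps$bimodal[i]) && off > 0) {
        0.5 * (exp(-(d - off)^2 / (2 * sigma^2)) +
                 exp(-(d + off)^2 / (2 * sigma^2)))
      } else {
        exp(-d^2 / (2 * sigma^2))
      }
      lambda[b + 1L] <- lambda[b + 1L] + bumps$amplitude[i] * shape
    }
    counts <- stats::rpois(nbins, lambda)
    nz <- which(counts > 0L)
    starts <- rep.int((nz - 1L) * bw, counts[nz])
    data.frame(chrom = chr, start = starts, end = starts + bw,
               stringsAsFactors = FALSE)
  })
  iv <- do.call(rbind, parts)
  read_set(iv, total_mapped = max(spec$reads_per_mark, nrow(iv)))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  np <- vapply(x$peaks, nrow, integer(1L))
  cat(sprintf("<synthetic_truth> %s bp genome; sites: %s; %d marks x %d replicate(s)\n",
              format(sum(x$spec$chrom_sizes), big.mark = ",",
                     scientific = FALSE),
              paste(sprintf("%s=%d", names(np), np), collapse = ", "),
              length(x$reads), x$spec$n_replicates))
  invisible(x)
}

#' RPKM tracks from a synthetic truth
#'
#' Convenience wrapper running each mark's replicates through
#' [bin_reads()], [rpkm_normalize()] and [average_replicates()].
#'
#' @param truth a `synthetic_truth`.
#' @return Named list of [binned_track]s, one per mark.
#' @export
rpkm_tracks <- function(truth) {
  spec <- truth$spec
  out <- lapply(names(truth$reads), function(mark) {
    reps <- lapply(truth$reads[[mark]], function(rs) {
      rpkm_normalize(bin_reads(rs, spec$chrom_sizes, spec$bin_width),
                     rs$total_mapped, spec$bin_width, mark = mark)
    })
    average_replicates(reps)
  })
  names(out) <- names(truth$reads)
  out
}

#' Every bin of a genome as a location table
#'
#' @param chrom_sizes named chromosome lengths, bp.
#' @param bin_width bin width, bp.
#' @return data.frame with `chrom` and 0-based `bin`, suitable for
#'   [assemble_features()].
#' @export
genome_bins <- function(chrom_sizes, bin_width = 100) {
  parts <- lapply(names(chrom_sizes), function(chr) {
    data.frame(chrom = chr,
               bin = seq_len(ceiling(chrom_sizes[[chr]] / bin_width)) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Export a synthetic epigenome as BED files
#'
#' Writes one peak BED per element class (`peaks_<class>.bed`) and one read
#' BED per mark replicate (`reads_<mark>_rep<i>.bed`); the files round-trip
#' through [read_bed()].
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_epigenome <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cl in names(truth$peaks)) {
    p <- file.path(dir, sprintf("peaks_%s.bed", cl))
    write_bed(truth$peaks[[cl]], p)
    files[sprintf("peaks_%s", cl)] <- p
  }
  for (mark in names(truth$reads)) {
    for (i in seq_along(truth$reads[[mark]])) {
      p <- file.path(dir, sprintf("reads_%s_rep%d.bed", mark, i))
      rs <- truth$reads[[mark]][[i]]
      utils::write.table(rs$intervals, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files[sprintf("reads_%s_rep%d", mark, i)] <- p
    }
  }
  sizes <- data.frame(chrom = names(truth$spec$chrom_sizes),
                      length = as.integer(truth$spec$chrom_sizes))
  p <- file.path(dir, "chrom_sizes.tsv")
  utils::write.table(sizes, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files["chrom_sizes"] <- p
  invisible(files)
}
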