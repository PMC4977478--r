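# compact geometry: p300 at 10 kb with DHS on top, TSS far or near
geom_fixture <- function() {
  list(
    p300_ok = peak_calls("chr1", 9900, 10200, "P300"),       # summit 10050
    p300_nodhs = peak_calls("chr1", 29900, 30200, "P300"),
    p300_near_tss = peak_calls("chr1", 49900, 50200, "P300"),  # summit 50050
    dhs = peak_calls("chr1", c(9800, 49800), c(10400, 50400), "DHS"),
    tss = peak_calls("chr1", 50700, 50900, "TSS")              # summit 50800
  )
}

test_that("positive selection requires DHS overlap and TSS distality", {
  g <- geom_fixture()
  p300 <- rbind(g$p300_ok, g$p300_nodhs, g$p300_near_tss)
  class(p300) <- c("peak_calls", "data.frame")
  sel <- select_positive_training(p300, g$dhs, g$tss, min_dist = 1000)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$summit, 10050L)   # overlaps DHS, TSS 40 kb away
  # 750 bp from the TSS summit -> excluded even though DHS-overlapping
  expect_false(50050L %in% sel$summit)
})

test_that("negative selection unions DHS-overlapping TSS with distal background", {
  dhs <- peak_calls("chr1", c(5000, 20000), c(6000, 21000), "DHS")
  tss <- peak_calls("chr1", c(5200, 40000), c(5400, 40200), "TSS")
  only_tss <- select_negative_training(tss, dhs, c(chr1 = 100000),
                                       n_random = 0, seed = 1)
  expect_equal(nrow(only_tss), 1L)            # the DHS-overlapping TSS only
  expect_equal(only_tss$element_class, "TSS")

  both <- select_negative_training(tss, dhs, c(chr1 = 100000),
                                   n_random = 25, seed = 2)
  bg <- both[both$element_class == "UNKNOWN", ]
  expect_equal(nrow(bg), 25L)
  # every background bin center is > 1 kb from all DHS and TSS summits
  avoid <- rbind(as.data.frame(dhs), as.data.frame(tss))
  class(avoid) <- c("peak_calls", "data.frame")
  expect_true(all(enhancerDNN:::nearest_summit_distance(bg, avoid) > 1000))
  # determinism
  again <- select_negative_training(tss, dhs, c(chr1 = 100000),
                                    n_random = 25, seed = 2)
  expect_identical(as.data.frame(both), as.data.frame(again))
})

test_that("background sampling errors when the eligible space is exhausted", {
  dhs <- peak_calls("chr1", 0, 4000, "DHS", summit = 2000)
  tss <- peak_calls("chr1", 4000, 8000, "TSS", summit = 6000)
  expect_error(
    select_negative_training(tss, dhs, c(chr1 = 8000), n_random = 50, seed = 1),
    "background")
})

test_that("build_training_set enforces the class ratio with aligned provenance", {
  fx <- small_truth()
  truth <- fx$truth; tracks <- fx$tracks
  fs <- feature_spec(names(tracks))
  pos <- select_positive_training(truth$peaks$P300, truth$peaks$DHS,
                                  truth$peaks$TSS)
  neg <- select_negative_training(truth$peaks$TSS, truth$peaks$DHS,
                                  truth$spec$chrom_sizes, n_random = 300,
                                  seed = 5)
  ds <- build_training_set(pos, neg, tracks, fs, ratio = 10, seed = 6)
  expect_equal(sum(ds$labels == 0L), 10L * sum(ds$labels == 1L))
  expect_equal(sum(ds$labels == 1L), nrow(pos))
  expect_true(all(ds$labels[ds$provenance %in% c("P300", "CBP", "TFBS")] == 1L))
  expect_true(all(ds$labels[ds$provenance %in% c("TSS", "RANDOM_BG")] == 0L))
  # no training positive within 1 kb of any TSS summit
  pos_rows <- ds$features$locations[ds$labels == 1L, ]
  pos_pk <- peak_calls(pos_rows$chrom, pos_rows$bin * 100L,
                       pos_rows$bin * 100L + 100L)
  expect_true(all(enhancerDNN:::nearest_summit_distance(
    pos_pk, truth$peaks$TSS) > 1000 - 50))  # bin-center quantization slack

  # subsampling is stratified: TSS fraction preserved within rounding
  frac_in <- mean(enhancerDNN:::provenance_of(neg) == "TSS")
  frac_out <- mean(ds$provenance[ds$labels == 0L] == "TSS")
  expect_lt(abs(frac_in - frac_out), 0.02)

  ds2 <- build_training_set(pos, neg, tracks, fs, ratio = 10, seed = 6)
  expect_identical(ds$features$samples, ds2$features$samples)
  expect_error(build_training_set(pos[0, ], neg, tracks, fs), "no positive")
  expect_error(build_training_set(pos, neg[1:20, ], tracks, fs, ratio = 10),
               "only")
})

test_that("ratio 1 with equal pools keeps every row", {
  fx <- small_truth()
  tracks <- fx$tracks; truth <- fx$truth
  fs <- feature_spec(names(tracks))
  n <- min(nrow(truth$peaks$P300), nrow(truth$peaks$TSS))
  pos <- truth$peaks$P300[seq_len(n), ]
  neg <- truth$peaks$TSS[seq_len(n), ]
  ds <- build_training_set(pos, neg, tracks, fs, ratio = 1, seed = 1)
  expect_equal(length(ds$labels), 2L * n)
})

test_that("build_test_set pools positive classes, dedupes, and keeps TSS as-is", {
  fx <- small_truth()
  truth <- fx$truth; tracks <- fx$tracks
  fs <- feature_spec(names(tracks))
  ts <- build_test_set(truth$peaks$P300, truth$peaks$CBP, truth$peaks$TFBS,
                       truth$peaks$DHS, truth$peaks$TSS, tracks, fs)
  expect_equal(sum(ts$labels == 0L), nrow(truth$peaks$TSS))
  expect_true(all(ts$provenance[ts$labels == 1L] %in% c("P300", "CBP", "TFBS")))

  # empty CBP/TFBS: positives from p300 only
  empty <- enhancerDNN:::empty_peak_calls()
  p_only <- build_test_set(truth$peaks$P300, empty, empty,
                           truth$peaks$DHS, truth$peaks$TSS, tracks, fs)
  expect_true(all(p_only$provenance[p_only$labels == 1L] == "P300"))

  # a duplicate peak in both p300 and TFBS collapses to one row
  dup <- build_test_set(truth$peaks$P300, empty, truth$peaks$P300,
                        truth$peaks$DHS, truth$peaks$TSS, tracks, fs)
  expect_equal(sum(dup$labels == 1L), sum(p_only$labels == 1L))
})

test_that("datasets export as delimited text with label and provenance", {
  fx <- small_truth()
  tracks <- fx$tracks; truth <- fx$truth
  fs <- feature_spec(names(tracks))
  ds <- build_training_set(truth$peaks$P300, truth$peaks$TSS, tracks, fs,
                           ratio = 0.5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(df), length(ds$labels))
  expect_true(all(c("chrom", "bin", "label", "provenance") %in% names(df)))
})
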