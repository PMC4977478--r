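test_that("TPM set pools markers and drops TSS-proximal ones", {
  tss <- peak_calls("chr1", 50000, 50200, "TSS")          # summit 50100
  dhs <- peak_calls("chr1", c(52900, 80000), c(53300, 80400), "DHS")
  p300 <- peak_calls("chr1", 50800, 51000, "P300")        # summit 50900: 800 bp
  empty <- enhancerDNN:::empty_peak_calls()
  tpm <- build_tpm_set(dhs, p300, empty, empty, tss)
  # DHS at 53100 is 3 kb from TSS -> in; p300 at 900 bp -> out
  expect_equal(sort(tpm$summit), c(53100L, 80200L))
  expect_equal(nrow(build_tpm_set(empty, empty, empty, empty, tss)), 0L)
})

test_that("validation applies the inclusive 2.5 kb summit rule", {
  tpm <- peak_calls("chr1", 99000, 101000, "DHS")         # summit 100000
  near <- data.frame(chrom = "chr1", summit = 102400)     # 2400 bp
  far <- data.frame(chrom = "chr1", summit = 102600)      # 2600 bp
  exact <- data.frame(chrom = "chr1", summit = 102500)    # inclusive boundary
  expect_equal(validate_predictions(near, tpm)$rate, 1)
  expect_equal(validate_predictions(far, tpm)$rate, 0)
  expect_equal(validate_predictions(exact, tpm)$rate, 1)
  at_summit <- data.frame(chrom = "chr1", summit = c(100000, 100000))
  expect_equal(validate_predictions(at_summit, tpm)$rate, 1)
  # empty prediction set: undefined, not zero
  res <- validate_predictions(data.frame(chrom = character(0),
                                         summit = integer(0)), tpm)
  expect_false(res$defined)
  expect_true(is.na(res$rate))
})

test_that("validation counts match a brute-force all-pairs scan", {
  withr::with_seed(77, {
    n <- 400
    chroms <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    pred <- data.frame(chrom = chroms,
                       summit = sample.int(2e5, n, replace = TRUE))
    tn <- 60
    tpos <- sample.int(2e5, tn, replace = TRUE)
    tpm <- peak_calls(sample(c("chr1", "chr2"), tn, replace = TRUE),
                      tpos, tpos + 200L, "DHS")
    res <- validate_predictions(pred, tpm, radius = 2500)
    brute <- sum(vapply(seq_len(n), function(i) {
      any(tpm$chrom == pred$chrom[i] &
            abs(tpm$summit - pred$summit[i]) <= 2500)
    }, logical(1)))
    expect_identical(res$n_validated, brute)
    # duplicating the TPM set changes nothing
    tpm2 <- rbind(as.data.frame(tpm), as.data.frame(tpm))
    class(tpm2) <- c("peak_calls", "data.frame")
    expect_equal(validate_predictions(pred, tpm2, radius = 2500)$rate,
                 res$rate)
  })
})

test_that("threshold sweeps are monotone and flag empty-prediction rows", {
  withr::with_seed(78, {
    locs <- data.frame(chrom = "chr1", bin = 0:999)
    scores <- runif(1000)
    tpos <- sample(seq(0, 99000, by = 1000), 30)
    tpm <- peak_calls("chr1", tpos, tpos + 100L, "DHS")
    th <- seq(1.1, -0.1, by = -0.1)
    sw <- threshold_sweep(scores, locs, tpm, th)
    expect_equal(nrow(sw), length(th))
    expect_true(all(diff(sw$n_predictions) >= 0))
    expect_true(all(diff(sw$n_validated) >= 0))
    expect_equal(sw$n_predictions[1], 0L)         # above max score
    expect_true(is.na(sw$rate[1]))
    expect_equal(sw$n_predictions[nrow(sw)], 1000L)  # below min score
    expect_error(threshold_sweep(scores, locs, tpm, c(0.1, 0.5)),
                 "descending")
  })
})

test_that("operating_point matches the requested prediction count", {
  withr::with_seed(79, {
    locs <- data.frame(chrom = "chr1", bin = 0:499)
    scores <- runif(500)
    tpm <- peak_calls("chr1", 10000, 10100, "DHS")
    op <- operating_point(scores, locs, tpm, n_target = 100)
    expect_lt(abs(op$n_predictions - 100), 15)
    expect_equal(op$n_validated / op$n_predictions, op$validation_rate)
  })
})

test_that("histogram-intersection overlap behaves at its extremes", {
  withr::with_seed(80, {
    x <- rnorm(5000)
    expect_equal(distribution_overlap(x, x), 1)
    expect_equal(distribution_overlap(runif(2000, 0, 1),
                                      runif(2000, 5, 6)), 0)
    # uniforms on [0,1] and [0.5,1.5]: exact density intersection is 0.5
    o <- distribution_overlap(runif(20000, 0, 1), runif(20000, 0.5, 1.5))
    expect_lt(abs(o - 0.5), 0.03)
    expect_equal(distribution_overlap(rep(3, 10), rep(3, 4)), 1)
  })
})

test_that("overlap is symmetric and affine-invariant", {
  withr::with_seed(81, {
    a <- rgamma(3000, 2); b <- rgamma(3000, 4)
    expect_equal(distribution_overlap(a, b), distribution_overlap(b, a))
    expect_equal(distribution_overlap(2 * a + 7, 2 * b + 7),
                 distribution_overlap(a, b))
  })
})

test_that("neighborhood averaging reduces to peak values at window 1", {
  fx <- small_truth()
  tr <- fx$tracks[["H3K4me1"]]
  enh <- fx$truth$peaks$P300
  tss <- fx$truth$peaks$TSS
  o1 <- neighborhood_average_overlap(tr, enh, tss, window_bins = 1)
  peak_o <- distribution_overlap(site_signal(tr, enh, 1),
                                 site_signal(tr, tss, 1))
  expect_identical(o1, peak_o)
  o20 <- neighborhood_average_overlap(tr, enh, tss, window_bins = 20)
  expect_gte(o20, 0); expect_lte(o20, 1)
  # constant track: distributions identical regardless of class
  ct <- const_track(2, nbins = 10000, chroms = c("chrA", "chrB"))
  expect_equal(neighborhood_average_overlap(ct, enh, tss, 20), 1)
})

test_that("predictions export as BED with scores", {
  locs <- data.frame(chrom = c("chr1", "chr2"), bin = c(10L, 20L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_predictions_bed(locs, c(0.5, 1.25), path)
  df <- utils::read.table(path, sep = "\t")
  expect_equal(df$V2, c(1000L, 2000L))
  expect_equal(df$V3, c(1100L, 2100L))
  expect_equal(df$V4, c(0.5, 1.25))
})
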