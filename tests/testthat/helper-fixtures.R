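# Shared fixtures, built in code at test time.

# peak_calls from a compact spec: list of c(start, end) per chromosome
make_peaks <- function(positions, chrom = "chr1", class = "UNKNOWN") {
  if (length(positions) == 0L) return(enhancerDNN:::empty_peak_calls())
  starts <- vapply(positions, `[[`, numeric(1), 1L)
  ends <- vapply(positions, `[[`, numeric(1), 2L)
  peak_calls(rep_len(chrom, length(starts)), starts, ends, class)
}

# a constant-valued track over one or more chromosomes
const_track <- function(value, nbins = 50, chroms = "chr1", mark = "M1",
                        bin_width = 100) {
  vals <- lapply(chroms, function(ch) rep(value, nbins))
  names(vals) <- chroms
  binned_track(mark, vals, bin_width)
}

# brute-force all-pairs overlap oracle (any shared bp, half-open)
brute_overlaps <- function(a, b) {
  any(vapply(seq_len(nrow(b)), function(j) {
    a$chrom == b$chrom[j] && a$start < b$end[j] && b$start[j] < a$end
  }, logical(1)))
}

# random small network for oracle comparisons
random_net <- function(layer_sizes, seed) {
  net <- init_network(layer_sizes, seed = seed)
  withr::with_seed(seed + 1000L, {
    net$weights <- lapply(net$weights, function(w) {
      matrix(stats::rnorm(length(w)), nrow = nrow(w))
    })
  })
  net
}

# central-finite-difference gradient of the batch MSE loss wrt every weight
# and bias, independent of the analytic backprop path
numeric_gradients <- function(model, X, y, eps = 1e-6) {
  loss_at <- function(m) {
    mean((enhancerDNN:::forward_pass(m, X)$score - y)^2)
  }
  dW <- lapply(model$weights, function(w) array(0, dim(w)))
  db <- lapply(model$biases, function(b) numeric(length(b)))
  for (l in seq_along(model$weights)) {
    for (i in seq_along(model$weights[[l]])) {
      up <- model; up$weights[[l]][i] <- up$weights[[l]][i] + eps
      dn <- model; dn$weights[[l]][i] <- dn$weights[[l]][i] - eps
      dW[[l]][i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    for (i in seq_along(model$biases[[l]])) {
      up <- model; up$biases[[l]][i] <- up$biases[[l]][i] + eps
      dn <- model; dn$biases[[l]][i] <- dn$biases[[l]][i] - eps
      db[[l]][i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
  }
  list(dW = dW, db = db)
}

# small synthetic genome shared across tests (cached per session)
.fixture_env <- new.env(parent = emptyenv())
small_truth <- function() {
  if (is.null(.fixture_env$truth)) {
    spec <- synthetic_spec(
      chrom_sizes = c(chrA = 6e5, chrB = 4e5),
      n_sites = c(P300 = 25, CBP = 6, TFBS = 6, TSS = 18),
      n_decoy_sites = 20, min_spacing = 5000, seed = 42)
    .fixture_env$truth <- generate_epigenome(spec)
    .fixture_env$tracks <- rpkm_tracks(.fixture_env$truth)
  }
  list(truth = .fixture_env$truth, tracks = .fixture_env$tracks)
}
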