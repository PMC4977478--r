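#' Connection-weight importance scores
#'
#' Assigns the output neuron importance 1 and propagates importance backward
#' layer by layer: the score of neuron i is `S_i = sum_j |w_ij| * S_j` over
#' the neurons j of the next layer that i feeds into. Biases play no part.
#' The input-layer scores are the per-feature importances; they equal, for
#' each input, the sum over all directed paths to the output of the product
#' of absolute weights along the path (see [path_product_oracle()]).
#'
#' @param model a `dnn_model`.
#' @return An object of class `importance_scores`: list with `per_neuron`
#'   (one non-negative vector per layer, input layer first, output last) and
#'   `per_feature` (the input-layer vector).
#' @export
importance_scores <- function(model) {
  L <- length(model$weights)
  per_neuron <- vector("list", L + 1L)
  S <- 1
  per_neuron[[L + 1L]] <- S
  for (l in seq(L, 1L)) {
    S <- as.numeric(abs(model$weights[[l]]) %*% S)
    per_neuron[[l]] <- S
  }
  structure(list(per_neuron = per_neuron, per_feature = per_neuron[[1L]]),
            class = "importance_scores")
}

#' @export
print.importance_scores <- function(x, ...) {
  cat(sprintf("<importance_scores> %d input features, %d layers\n",
              length(x$per_feature), length(x$per_neuron)))
  invisible(x)
}

#' Brute-force path-product reference for importance scores
#'
#' Independent reference implementation: enumerates every directed path from
#' an input neuron to the output and sums the product of absolute weights
#' along each path. Exponential in depth — intended only for small networks
#' (at most `max_paths` paths per input) as a cross-check of
#' [importance_scores()].
#'
#' @param model a `dnn_model`.
#' @param max_paths refuse networks with more paths per input than this.
#' @return numeric vector of per-input-feature scores.
#' @export
path_product_oracle <- function(model, max_paths = 1e5) {
  sizes <- model$layer_sizes
  L <- length(model$weights)
  inner <- sizes[-1L]  # choices at layers 2..output
  if (prod(inner) > max_paths) {
    stop(sprintf("network has %g paths per input (budget %g)",
                 prod(inner), max_paths))
  }
  # every path is a choice of one neuron per downstream layer
  combos <- as.matrix(expand.grid(lapply(inner, seq_len)))
  vapply(seq_len(sizes[1L]), function(i) {
    total <- 0
    for (p in seq_len(nrow(combos))) {
      idx <- c(i, combos[p, ])
      prod_w <- 1
      for (l in seq_len(L)) {
        prod_w <- prod_w * abs(model$weights[[l]][idx[l], idx[l + 1L]])
      }
      total <- total + prod_w
    }
    total
  }, numeric(1L))
}

#' Rank features by importance
#'
#' Stable descending sort of the per-feature scores; ties are broken by
#' ascending feature index. The result is the ordered feature list used to
#' build reduced top-k models.
#'
#' @param scores an `importance_scores` object or a numeric vector.
#' @return An object of class `ordered_features`: list with `ranking`
#'   (feature indices, most important first) and `scores` (aligned values).
#' @export
rank_features <- function(scores) {
  s <- if (inherits(scores, "importance_scores")) scores$per_feature else scores
  ord <- order(-s, seq_along(s))
  structure(list(ranking = ord, scores = s[ord]),
            class = "ordered_features")
}

#' @export
print.ordered_features <- function(x, ...) {
  cat(sprintf("<ordered_features> %d features; top score %.4g (feature %d)\n",
              length(x$ranking), x$scores[1L], x$ranking[1L]))
  invisible(x)
}

#' Aggregate feature importances to per-mark importances
#'
#' The importance of a histone mark is the sum of the scores of its window
#' features, so the total over marks equals the total over features.
#'
#' @param scores an `importance_scores` object or per-feature numeric
#'   vector.
#' @param column_map the feature matrix `column_map` (columns `column`,
#'   `mark`, `offset`).
#' @return Named numeric vector of per-mark scores, in first-appearance
#'   order of the marks.
#' @export
aggregate_by_mark <- function(scores, column_map) {
  s <- if (inherits(scores, "importance_scores")) scores$per_feature else scores
  stopifnot(length(s) == nrow(column_map))
  marks <- unique(column_map$mark)
  out <- vapply(marks, function(m) sum(s[column_map$mark == m]), numeric(1L))
  names(out) <- marks
  out
}

#' Keep only the top-k features of a dataset
#'
#' Projects the dataset onto the `k` highest-ranked features, preserving the
#' original column order; labels and provenance are unchanged, and the
#' retained `column_map` records each column's original index.
#'
#' @param dataset a [labeled_dataset] (or a bare `feature_matrix`).
#' @param ol an `ordered_features` ranking over the dataset's columns.
#' @param k number of features to keep.
#' @return Object of the same class as `dataset` with `k` columns.
#' @export
reduce_features <- function(dataset, ol, k) {
  fm <- if (inherits(dataset, "labeled_dataset")) dataset$features else dataset
  p <- ncol(fm$samples)
  if (k < 1L || k > p) {
    stop(sprintf("k must be between 1 and %d (got %g)", p, k))
  }
  keep <- ol$ranking[seq_len(k)]
  reduced <- subset_features(fm, keep)
  if (inherits(dataset, "labeled_dataset")) {
    labeled_dataset(reduced, dataset$labels, dataset$provenance)
  } else {
    reduced
  }
}

#' Retrain and evaluate reduced top-k models
#'
#' For each k in `k_values`, keeps the top-k features, retrains a network
#' with the hidden architecture of `config` (per-k seeds derived from
#' `config$seed`), predicts over the evaluation locations, and records the
#' validation rate at the threshold whose prediction count is closest to
#' `n_target` (rates are compared at matched prediction counts, since the
#' threshold scale changes with the feature set).
#'
#' @param dataset training [labeled_dataset] (full feature set).
#' @param ol an `ordered_features` ranking.
#' @param k_values integer vector of feature counts to evaluate.
#' @param config a [train_config()].
#' @param eval_features `feature_matrix` of candidate locations to score
#'   (same column layout as the training features).
#' @param tpm true-positive-marker [peak_calls] (see [build_tpm_set()]).
#' @param n_target prediction count at which rates are compared.
#' @param radius validation radius in bp.
#' @param n_thresholds size of the score-quantile threshold grid.
#' @return data.frame with one row per k: `k`, `threshold`,
#'   `n_predictions`, `n_validated`, `validation_rate`.
#' @export
top_k_sweep <- function(dataset, ol, k_values, config, eval_features, tpm,
                        n_target, radius = 2500, n_thresholds = 50) {
  p <- ncol(dataset$features$samples)
  stopifnot(all(k_values >= 1L), all(k_values <= p))
  rows <- lapply(seq_along(k_values), function(i) {
    k <- k_values[i]
    cfg <- config
    cfg$seed <- config$seed + i
    train_k <- reduce_features(dataset, ol, k)
    model_k <- train_dnn(train_k, config = cfg)
    eval_k <- reduce_features(eval_features, ol, k)
    scores <- predict(model_k, eval_k)
    op <- operating_point(scores, eval_k$locations, tpm,
                          n_target = n_target, radius = radius,
                          n_thresholds = n_thresholds)
    cbind(k = k, op)
  })
  do.call(rbind, rows)
}
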