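#' Softplus activation
#'
#' `softplus(x) = log(1 + exp(x))`, evaluated overflow-safely as
#' `max(x, 0) + log1p(exp(-|x|))` so that large arguments return
#' approximately `x` instead of `Inf`.
#'
#' @param x numeric vector or matrix.
#' @return numeric of the same shape.
#' @export
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# d/dx softplus(x) = logistic(x)
softplus_grad <- function(x) stats::plogis(x)

#' Training configuration for the enhancer network
#'
#' Defaults follow the published operating point of the model: mini-batches
#' of 100 samples, dropout rate 0.5 on the hidden layers, 5 epochs, and
#' three hidden layers of 600/500/400 neurons. Learning rate, momentum and
#' initialization scale are not pinned by that operating point and default
#' to plain SGD at 0.01 with fan-in-scaled uniform initialization.
#'
#' @param batch_size mini-batch size.
#' @param dropout_rate probability of dropping a hidden unit, in `[0, 1)`.
#' @param epochs full passes over the training data.
#' @param learning_rate SGD step size.
#' @param momentum classical momentum coefficient (0 = plain SGD).
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param output_activation `"softplus"` (default; raw scores are >= 0) or
#'   `"linear"` for an unbounded output unit.
#' @param input_init_scale multiplier on the fan-in-scaled initialization
#'   range of the input layer only (input weights ~
#'   U(-s/sqrt(fan_in), +s/sqrt(fan_in)) with `s = input_init_scale`;
#'   hidden layers always use `s = 1`). The small default starts the input
#'   weights near zero so their magnitudes accumulate from gradient signal
#'   alone, which keeps the connection-weight importance analysis of the
#'   trained network a readout of learned structure rather than of the
#'   random starting point; hidden layers keep full-scale initialization to
#'   preserve gradient flow.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 100, dropout_rate = 0.5, epochs = 5,
                         learning_rate = 0.01, momentum = 0,
                         hidden_sizes = c(600, 500, 400),
                         output_activation = c("softplus", "linear"),
                         input_init_scale = 0.01, seed = 1) {
  output_activation <- match.arg(output_activation)
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1, momentum >= 0, momentum < 1,
            input_init_scale > 0)
  structure(list(batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 hidden_sizes = as.integer(hidden_sizes),
                 output_activation = output_activation,
                 input_init_scale = input_init_scale,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly on `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`
#' (fan-in-scaled, zero-mean); biases start at zero. `weights[[l]]` has one
#' row per neuron of layer `l` and one column per neuron of layer `l + 1`,
#' so entry `(i, j)` is the connection weight w_ij from neuron i to neuron j
#' of the next layer.
#'
#' @param layer_sizes integer vector `(inputs, hidden..., 1)`; the final
#'   layer must have size 1.
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @param output_activation output unit activation identifier.
#' @param input_init_scale multiplier on the input layer's initialization
#'   range (see [train_config()]).
#' @return An object of class `dnn_model` (untrained).
#' @export
init_network <- function(layer_sizes, seed = NULL,
                         output_activation = "softplus",
                         input_init_scale = 1) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  if (layer_sizes[length(layer_sizes)] != 1L) {
    stop("the output layer must have exactly one neuron")
  }
  draw <- function() {
    L <- length(layer_sizes) - 1L
    weights <- vector("list", L)
    biases <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      s <- (if (l == 1L) input_init_scale else 1) / sqrt(fan_in)
      weights[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1L],
                                          -s, s),
                             nrow = fan_in, ncol = layer_sizes[l + 1L])
      biases[[l]] <- numeric(layer_sizes[l + 1L])
    }
    list(weights = weights, biases = biases)
  }
  wb <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(layer_sizes = layer_sizes, weights = wb$weights,
                 biases = wb$biases, activation = "softplus",
                 output_activation = output_activation,
                 config = NULL, history = NULL),
            class = "dnn_model")
}

#' @export
print.dnn_model <- function(x, ...) {
  cat(sprintf("<dnn_model> layers %s, softplus hidden units, %s output%s\n",
              paste(x$layer_sizes, collapse = "-"), x$output_activation,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", final training MSE %.4g",
                        x$history$mse[length(x$history$mse)])))
  invisible(x)
}

# Forward pass over a batch matrix X (n x inputs). dropout_masks, when
# given, is a list of 0/1 vectors (one per hidden layer); surviving units
# are scaled by 1/(1 - dropout_rate) (inverted dropout), so prediction needs
# no rescaling. Returns the cache needed for backpropagation.
forward_pass <- function(model, X, dropout_masks = NULL, dropout_rate = 0) {
  L <- length(model$weights)
  Z <- vector("list", L)
  A <- vector("list", L + 1L)  # A[[1]] = input
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z[[l]] <- sweep(A[[l]] %*% model$weights[[l]], 2L, model$biases[[l]], `+`)
    h <- softplus(Z[[l]])
    if (!is.null(dropout_masks)) {
      h <- sweep(h, 2L, dropout_masks[[l]] / (1 - dropout_rate), `*`)
    }
    A[[l + 1L]] <- h
  }
  Z[[L]] <- sweep(A[[L]] %*% model$weights[[L]], 2L, model$biases[[L]], `+`)
  out <- if (model$output_activation == "softplus") softplus(Z[[L]]) else Z[[L]]
  A[[L + 1L]] <- out
  list(score = as.numeric(out), Z = Z, A = A)
}

# Mean-squared-error loss and analytic gradients for one batch, consistent
# with forward_pass (including the dropout scaling). Used by the SGD loop
# and checked against central finite differences in the test suite.
network_gradients <- function(model, X, y, dropout_masks = NULL,
                              dropout_rate = 0) {
  n <- nrow(X)
  L <- length(model$weights)
  fw <- forward_pass(model, X, dropout_masks, dropout_rate)
  err <- fw$score - y
  loss <- mean(err^2)
  dW <- vector("list", L)
  db <- vector("list", L)
  # delta at the output pre-activation
  d_out <- matrix(2 * err / n, ncol = 1L)
  if (model$output_activation == "softplus") {
    d_out <- d_out * softplus_grad(fw$Z[[L]])
  }
  delta <- d_out
  for (l in seq(L, 1L)) {
    dW[[l]] <- crossprod(fw$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      dA <- delta %*% t(model$weights[[l]])
      if (!is.null(dropout_masks)) {
        dA <- sweep(dA, 2L, dropout_masks[[l - 1L]] / (1 - dropout_rate), `*`)
      }
      delta <- dA * softplus_grad(fw$Z[[l - 1L]])
    }
  }
  list(loss = loss, dW = dW, db = db, score = fw$score)
}

#' Train the enhancer network
#'
#' Mini-batch stochastic gradient descent on the mean squared error between
#' the raw network output and the 0/1 label, with fresh Bernoulli dropout
#' masks drawn per batch on the hidden layers (inverted scaling, so
#' prediction uses the weights unchanged). Fully deterministic given
#' `config$seed`: initialization, per-epoch shuffles and masks all derive
#' from it.
#'
#' @param x a [labeled_dataset], or a numeric feature matrix.
#' @param y binary labels (ignored when `x` is a labeled dataset).
#' @param config a [train_config()].
#' @return A trained `dnn_model`; `$history$mse` holds the end-of-epoch
#'   training MSE (computed without dropout).
#' @export
train_dnn <- function(x, y = NULL, config = train_config()) {
  if (inherits(x, "labeled_dataset")) {
    y <- x$labels
    x <- x$features$samples
  }
  stopifnot(is.matrix(x), nrow(x) >= 1L, length(y) == nrow(x),
            all(y %in% c(0, 1)))
  y <- as.numeric(y)
  sizes <- c(ncol(x), config$hidden_sizes, 1L)
  n <- nrow(x)
  withr::with_seed(config$seed, {
    model <- init_network(sizes, output_activation = config$output_activation,
                          input_init_scale = config$input_init_scale)
    if (config$output_activation == "softplus") {
      # start the output at the label base rate so the imbalanced negative
      # gradient cannot push the softplus unit into its dead zone early on
      ybar <- min(max(mean(y), 1e-3), 1 - 1e-3)
      model$biases[[length(model$biases)]] <- log(expm1(ybar))
    }
    vel_W <- lapply(model$weights, function(w) w * 0)
    vel_b <- lapply(model$biases, function(b) b * 0)
    n_hidden <- length(config$hidden_sizes)
    mse_log <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        masks <- NULL
        if (config$dropout_rate > 0) {
          masks <- lapply(config$hidden_sizes, function(k) {
            stats::rbinom(k, 1L, 1 - config$dropout_rate)
          })
        }
        g <- network_gradients(model, x[rows, , drop = FALSE], y[rows],
                               masks, config$dropout_rate)
        if (!is.finite(g$loss)) {
          stop(sprintf(paste0("non-finite training loss in epoch %d; ",
                              "consider lowering learning_rate (%g)"),
                       epoch, config$learning_rate))
        }
        for (l in seq_along(model$weights)) {
          vel_W[[l]] <- config$momentum * vel_W[[l]] -
            config$learning_rate * g$dW[[l]]
          vel_b[[l]] <- config$momentum * vel_b[[l]] -
            config$learning_rate * g$db[[l]]
          model$weights[[l]] <- model$weights[[l]] + vel_W[[l]]
          model$biases[[l]] <- model$biases[[l]] + vel_b[[l]]
        }
      }
      mse_log[epoch] <- mean((forward_pass(model, x)$score - y)^2)
    }
    model$config <- config
    model$history <- list(mse = mse_log)
    model
  })
}

#' Predict raw enhancer scores
#'
#' Runs the network forward with no dropout; one raw score per row. Under
#' the default softplus output unit, scores are non-negative and unbounded
#' above; they are compared against a threshold by [classify()].
#'
#' @param object a trained `dnn_model`.
#' @param newdata a `feature_matrix` or numeric matrix whose column count
#'   matches the model input layer.
#' @param ... unused.
#' @return numeric vector of raw scores.
#' @export
predict.dnn_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$samples else newdata
  stopifnot(is.matrix(X))
  if (ncol(X) != object$layer_sizes[1L]) {
    stop(sprintf("feature count (%d) does not match model input size (%d)",
                 ncol(X), object$layer_sizes[1L]))
  }
  if (nrow(X) == 0L) return(numeric(0))
  # chunked so genome-wide matrices do not allocate huge activation caches
  chunk <- 20000L
  out <- numeric(nrow(X))
  for (s in seq(1L, nrow(X), by = chunk)) {
    rows <- s:min(s + chunk - 1L, nrow(X))
    out[rows] <- forward_pass(object, X[rows, , drop = FALSE])$score
  }
  out
}

#' Threshold raw scores into class labels
#'
#' Label 1 (enhancer) iff `score > threshold`, strictly: a score equal to
#' the threshold is not called.
#'
#' @param scores numeric raw scores.
#' @param threshold decision threshold.
#' @return integer vector in `{0, 1}`.
#' @export
classify <- function(scores, threshold) {
  as.integer(scores > threshold)
}

#' Persist a model to a single text file
#'
#' Versioned plain-text container holding the layer sizes, activation
#' identifiers, training configuration, and full-precision weights and
#' biases. [read_model()] restores an identical model.
#'
#' @param model a `dnn_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  header <- list(format = "enhancerDNN-model", version = 1L,
                 layer_sizes = model$layer_sizes,
                 activation = model$activation,
                 output_activation = model$output_activation,
                 config = unclass(model$config),
                 history = model$history)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA, null = "null")), con)
  for (l in seq_along(model$weights)) {
    writeLines(sprintf("@weights %d", l), con)
    utils::write.table(format(model$weights[[l]], digits = 17L),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(sprintf("@biases %d", l), con)
    writeLines(paste(format(model$biases[[l]], digits = 17L),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Restore a model written by [write_model()]
#'
#' @param path path to a model file.
#' @return A `dnn_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  if (!identical(header$format, "enhancerDNN-model")) {
    stop(sprintf("%s is not a model file", path))
  }
  sizes <- as.integer(header$layer_sizes)
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  i <- 2L
  for (l in seq_len(L)) {
    stopifnot(identical(lines[i], sprintf("@weights %d", l)))
    block <- lines[i + seq_len(sizes[l])]
    weights[[l]] <- matrix(as.numeric(unlist(strsplit(block, "\t"))),
                           nrow = sizes[l], ncol = sizes[l + 1L],
                           byrow = TRUE)
    i <- i + sizes[l] + 1L
    stopifnot(identical(lines[i], sprintf("@biases %d", l)))
    biases[[l]] <- as.numeric(strsplit(lines[i + 1L], "\t")[[1L]])
    i <- i + 2L
  }
  config <- header$config
  if (!is.null(config)) {
    config <- train_config(batch_size = config$batch_size,
                           dropout_rate = config$dropout_rate,
                           epochs = config$epochs,
                           learning_rate = config$learning_rate,
                           momentum = config$momentum,
                           hidden_sizes = config$hidden_sizes,
                           output_activation = config$output_activation,
                           input_init_scale = config$input_init_scale,
                           seed = config$seed)
  }
  structure(list(layer_sizes = sizes, weights = weights, biases = biases,
                 activation = header$activation,
                 output_activation = header$output_activation,
                 config = config,
                 history = header$history),
            class = "dnn_model")
}
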