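#' Default end-to-end run configuration
#'
#' A plain nested list (YAML-serializable) describing one full run: the
#' input source (a synthetic-genome description, or paths to BED inputs),
#' feature layout, training hyperparameters, evaluation settings and the
#' global seed from which every stage seed is derived.
#'
#' @param seed global integer seed.
#' @param outdir output directory for artifacts.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1, outdir = "enhancer_run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    # set `inputs` to read BED files instead of simulating:
    # list(chrom_sizes = "chrom_sizes.tsv",
    #      peaks = list(P300 = "p300.bed", TSS = "...", DHS = "...",
    #                   CBP = NULL, TFBS = NULL),
    #      reads = list(H3K4me1 = c("rep1.bed", "rep2.bed"), ...))
    inputs = NULL,
    synthetic = list(),   # overrides for synthetic_spec() arguments
    flank_bins = 10L,
    bin_width = 100L,
    ratio = 10,
    n_random = 3000L,
    min_dist = 1000L,
    radius = 2500L,
    n_target = 3000L,
    n_thresholds = 50L,
    k_values = NULL,      # e.g. c(240, 80, 10) to run the top-k sweep
    # 30 epochs on the desk-scale training set gives roughly the same number
    # of SGD updates as the published 5-epoch genome-scale training
    train = list(batch_size = 100L, dropout_rate = 0.5, epochs = 30L,
                 learning_rate = 0.01, momentum = 0,
                 hidden_sizes = c(600L, 500L, 400L),
                 output_activation = "softplus", input_init_scale = 0.01),
    export_inputs = FALSE
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config a configuration list (see [default_run_config()]).
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(normalize_run_config(config), path)
  invisible(path)
}

# named numeric vectors lose their names through YAML/JSON scalars; store
# the two name-carrying synthetic fields as lists
normalize_run_config <- function(config) {
  for (f in c("chrom_sizes", "n_sites")) {
    if (!is.null(config$synthetic[[f]])) {
      config$synthetic[[f]] <- as.list(unlist(config$synthetic[[f]]))
    }
  }
  config
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  utils::modifyList(base, cfg)
}

load_bed_inputs <- function(inputs) {
  sizes_df <- utils::read.table(inputs$chrom_sizes, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  chrom_sizes <- stats::setNames(sizes_df$length, sizes_df$chrom)
  peak_of <- function(cl) {
    p <- inputs$peaks[[cl]]
    if (is.null(p)) empty_peak_calls() else read_bed(p, cl)
  }
  peaks <- lapply(c("P300", "CBP", "TFBS", "TSS", "DHS"), peak_of)
  names(peaks) <- c("P300", "CBP", "TFBS", "TSS", "DHS")
  reads <- lapply(names(inputs$reads), function(mark) {
    lapply(inputs$reads[[mark]], function(p) {
      if (!file.exists(p)) {
        stop(sprintf("stage features: read file for mark %s not found: %s",
                     mark, p))
      }
      read_set(read_bed(p))
    })
  })
  names(reads) <- names(inputs$reads)
  list(chrom_sizes = chrom_sizes, peaks = peaks, reads = reads)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full enhancer-prediction workflow
#'
#' Executes every stage in order — simulate (or load BED inputs), bin and
#' normalize reads, build the labeled training set, train the network,
#' compute importance scores, predict genome-wide, evaluate against the
#' TPM set, and optionally retrain reduced top-k models — and writes all
#' artifacts plus a `manifest.json` (configuration, seed, versions, stage
#' counts) that suffices to reproduce the run.
#'
#' @param config configuration list from [default_run_config()] /
#'   [read_run_config()].
#' @return Invisibly, a list with the trained model, ordered feature list,
#'   per-mark importances, evaluation tables and artifact paths.
#' @export
run_full <- function(config) {
  config <- normalize_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  if (is.null(config$inputs)) {
    syn_args <- utils::modifyList(list(seed = config$seed),
                                  as.list(config$synthetic))
    syn <- do.call(synthetic_spec, syn_args)
    truth <- generate_epigenome(syn)
    stage_msg("simulate", "%d sites on %s bp", nrow(truth$sites),
              format(sum(syn$chrom_sizes), big.mark = ",",
                     scientific = FALSE))
    if (isTRUE(config$export_inputs)) {
      export_epigenome(truth, file.path(outdir, "inputs"))
    }
    chrom_sizes <- syn$chrom_sizes
    peaks <- truth$peaks
    tracks <- rpkm_tracks(truth)
  } else {
    loaded <- load_bed_inputs(config$inputs)
    chrom_sizes <- loaded$chrom_sizes
    peaks <- loaded$peaks
    tracks <- lapply(names(loaded$reads), function(mark) {
      reps <- lapply(loaded$reads[[mark]], function(rs) {
        rpkm_normalize(bin_reads(rs, chrom_sizes, config$bin_width),
                       rs$total_mapped, config$bin_width, mark = mark)
      })
      average_replicates(reps)
    })
    names(tracks) <- names(loaded$reads)
    stage_msg("features", "loaded %d marks from BED inputs", length(tracks))
  }

  fspec <- feature_spec(names(tracks), flank_bins = config$flank_bins,
                        bin_width = config$bin_width)
  stage_msg("features", "%d marks x %d window bins = %d features",
            length(fspec$marks), 2L * fspec$flank_bins, n_features(fspec))

  positives <- select_positive_training(peaks$P300, peaks$DHS, peaks$TSS,
                                        min_dist = config$min_dist)
  negatives <- select_negative_training(peaks$TSS, peaks$DHS, chrom_sizes,
                                        n_random = config$n_random,
                                        min_dist = config$min_dist,
                                        seed = config$seed + 2L,
                                        bin_width = config$bin_width)
  training <- build_training_set(positives, negatives, tracks, fspec,
                                 ratio = config$ratio,
                                 seed = config$seed + 3L)
  stage_msg("datasets", "%d positives, %d negatives (1:%g)",
            sum(training$labels == 1L), sum(training$labels == 0L),
            config$ratio)

  tc <- config$train
  cfg <- train_config(batch_size = tc$batch_size,
                      dropout_rate = tc$dropout_rate, epochs = tc$epochs,
                      learning_rate = tc$learning_rate,
                      momentum = tc$momentum, hidden_sizes = tc$hidden_sizes,
                      output_activation = tc$output_activation,
                      input_init_scale = tc$input_init_scale,
                      seed = config$seed + 1L)
  model <- train_dnn(training, config = cfg)
  model_path <- file.path(outdir, "model.txt")
  write_model(model, model_path)
  stage_msg("train", "epoch MSE: %s",
            paste(sprintf("%.4f", model$history$mse), collapse = " "))

  imp <- importance_scores(model)
  ol <- rank_features(imp)
  cm <- training$features$column_map
  ol_df <- data.frame(rank = seq_along(ol$ranking), feature = ol$ranking,
                      mark = cm$mark[ol$ranking],
                      offset = cm$offset[ol$ranking], score = ol$scores)
  utils::write.table(ol_df, file.path(outdir, "ordered_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mark_imp <- aggregate_by_mark(imp, cm)
  utils::write.table(data.frame(mark = names(mark_imp),
                                importance = as.numeric(mark_imp)),
                     file.path(outdir, "mark_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("importance", "top mark: %s", names(which.max(mark_imp)))

  locations <- genome_bins(chrom_sizes, config$bin_width)
  eval_features <- assemble_features(tracks, locations, fspec)
  scores <- predict(model, eval_features)
  tpm <- build_tpm_set(peaks$DHS, peaks$P300, peaks$CBP, peaks$TFBS,
                       peaks$TSS, min_dist = config$min_dist)
  sweep <- threshold_sweep(
    scores, locations, tpm,
    thresholds = sort(unique(stats::quantile(
      scores, probs = seq(1, 0, length.out = config$n_thresholds),
      names = FALSE)), decreasing = TRUE),
    radius = config$radius, bin_width = config$bin_width)
  utils::write.table(sweep, file.path(outdir, "threshold_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  op <- operating_point(scores, locations, tpm, n_target = config$n_target,
                        radius = config$radius,
                        bin_width = config$bin_width,
                        n_thresholds = config$n_thresholds)
  utils::write.table(op, file.path(outdir, "validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  called <- scores > op$threshold
  write_predictions_bed(locations[called, , drop = FALSE], scores[called],
                        file.path(outdir, "predictions.bed"),
                        bin_width = config$bin_width)
  stage_msg("evaluate", "%d predictions, validation rate %.3f",
            op$n_predictions, op$validation_rate)

  topk <- NULL
  if (!is.null(config$k_values)) {
    topk <- top_k_sweep(training, ol, as.integer(config$k_values), cfg,
                        eval_features, tpm, n_target = config$n_target,
                        radius = config$radius,
                        n_thresholds = config$n_thresholds)
    utils::write.table(topk, file.path(outdir, "topk_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_msg("sweep", "%d reduced models evaluated", nrow(topk))
  }

  manifest <- list(
    config = config,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("enhancerDNN")),
    r_version = R.version.string,
    counts = list(n_positives = sum(training$labels == 1L),
                  n_negatives = sum(training$labels == 0L),
                  n_features = n_features(fspec),
                  n_tpm = nrow(tpm),
                  n_eval_locations = nrow(locations)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_run_config(config, file.path(outdir, "config.yaml"))

  invisible(list(model = model, ordered_features = ol_df,
                 mark_importance = mark_imp, sweep = sweep,
                 operating_point = op, topk = topk, tpm = tpm,
                 outdir = outdir))
}
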