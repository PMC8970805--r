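# Config-driven orchestration of the full pipeline:
# simulate -> denoise -> scalogram -> (tune) -> train -> features ->
# classify -> evaluate.

pipeline_defaults <- function() {
  list(
    data = list(n_trials_per_class = 140, fs = 128, duration = 9,
                mu_freq = 10, beta_freq = 20, erd_depth = 0.5,
                imagery_window = c(3, 8), noise_exponent = 1, snr_db = 5),
    mspca = list(wavelet_id = "db4", levels = 4, retention_rule = "kaiser",
                 center = TRUE, scale = FALSE),
    tfr = list(wavelet_omega0 = 6, f_min = 4, f_max = 40, n_freqs = 64,
               spacing = "log", out_size = c(32, 32),
               normalization = "per_image"),
    net = list(backbone_depth = "tiny", fpn_levels = 3, feature_dim = 256,
               epochs = 30, batch_size = 16, learning_rate = 0.02,
               momentum = 0.9, val_fraction = 0.2),
    aoa = list(N = 3, Mt = 2),
    id3 = list(n_bins = 4, max_depth = 3, min_samples = 2),
    eval = list(n_iterations = 5, test_fraction = 0.5, tune = FALSE,
                denoise = TRUE))
}

validate_section <- function(section, user, defaults, allowed) {
  unknown <- setdiff(names(user), allowed)
  if (length(unknown) > 0)
    mi_stop("config", "unknown key %s.%s", section, unknown[1])
  merged <- utils::modifyList(defaults, user)
  merged
}

#' Assemble and validate a pipeline configuration
#'
#' Nested sections `data`, `mspca`, `tfr`, `net`, `aoa`, `id3`, `eval` mirror
#' the per-module configuration types; omitted keys take defaults, unknown
#' keys are rejected, and invariant breaches raise errors naming
#' `section.key`.
#'
#' @param ... Named sections (lists); plus `seed` (global integer seed) and
#'   `output_dir` (optional artifact directory).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1, output_dir = NULL) {
  user <- list(...)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown) > 0)
    mi_stop("config", "unknown section '%s'", unknown[1])
  check_number(seed, "seed", integer = TRUE)
  cfg <- list(seed = as.integer(seed), output_dir = output_dir)
  for (s in names(defs)) {
    sect <- validate_section(s, user[[s]] %||% list(), defs[[s]],
                             names(defs[[s]]))
    # run each section through its module validator to surface breaches early
    ok <- tryCatch({
      switch(s,
        data = do.call(synth_config, c(sect, list(seed = seed))),
        mspca = do.call(mspca_config, sect),
        tfr = do.call(tfr_config, sect),
        net = do.call(net_config, c(sect, list(seed = seed))),
        aoa = do.call(aoa_config, c(sect, list(seed = seed))),
        id3 = {
          check_number(sect$n_bins, "n_bins", lower = 2, integer = TRUE)
          check_number(sect$min_samples, "min_samples", lower = 1, integer = TRUE)
          sect
        },
        eval = {
          check_number(sect$n_iterations, "n_iterations", lower = 1, integer = TRUE)
          check_number(sect$test_fraction, "test_fraction", lower = 0.05,
                       upper = 0.95)
          sect
        })
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      mi_stop("config", "%s.%s", s, conditionMessage(ok))
    cfg[[s]] <- sect
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' An empty file yields all defaults; see [pipeline_config()] for validation.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) mi_stop("io", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  seed <- raw$seed %||% 1
  output_dir <- raw$output_dir
  raw$seed <- NULL; raw$output_dir <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed, output_dir = output_dir)))
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$output_dir <- x$output_dir %||% NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

stratified_split <- function(labels, test_fraction, seed) {
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    ids <- which(labels == cl)
    k <- round(length(ids) * test_fraction)
    test_idx <- c(test_idx, sample(ids, k))
  }
  list(train = setdiff(seq_along(labels), test_idx), test = sort(test_idx))
}

subset_scalograms <- function(ss, ids) {
  ss$images <- ss$images[, , , ids, drop = FALSE]
  ss$labels <- ss$labels[ids]
  ss
}

#' Run the full pipeline once
#'
#' Stages in order: synthetic generation (or a provided trial set), MSPCA
#' denoising, scalogram images, optional AOA hyperparameter tuning, focal-loss
#' network training on a stratified train split, feature extraction,
#' discretization + ID3 tree induction, and held-out evaluation. Deterministic
#' given the global seed, which fans out to per-stage seeds via
#' [derive_seed()].
#'
#' @param cfg A [pipeline_config()].
#' @param trials Optional [eeg_trial_set()] overriding the synthetic `data`
#'   section (e.g. loaded with [read_trials()]).
#' @param iteration Offset added to the global seed, used by [run_experiment()]
#'   for independent repetitions.
#' @return List of class `pipeline_result`: `metrics`
#'   ([metrics_from_cm()] result), `cm`, `net_val_accuracy`, `tree`,
#'   `tuned` (hyperparameters used), `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), trials = NULL,
                         iteration = 0) {
  if (!inherits(cfg, "pipeline_config")) mi_stop("config", "cfg must be a pipeline_config")
  seed <- cfg$seed + iteration
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      mi_stop("stage", "stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ts <- stage("simulate", {
    if (!is.null(trials)) trials else
      generate_mi_eeg(do.call(synth_config,
                              c(cfg$data, list(seed = derive_seed(seed, "simulate")))))
  })
  if (isTRUE(cfg$eval$denoise))
    ts <- stage("denoise", mspca_denoise(ts, do.call(mspca_config, cfg$mspca)))
  ss <- stage("scalogram", batch_scalograms(ts, do.call(tfr_config, cfg$tfr)))

  sp <- stratified_split(ss$labels, cfg$eval$test_fraction,
                         derive_seed(seed, "split"))
  train_ss <- subset_scalograms(ss, sp$train)
  test_ss <- subset_scalograms(ss, sp$test)

  net_cfg <- do.call(net_config, c(cfg$net, list(seed = derive_seed(seed, "train"))))
  hyper <- list()
  tuned <- NULL
  if (isTRUE(cfg$eval$tune)) {
    tuned <- stage("tune", {
      tune_cfg <- do.call(aoa_config,
                          c(cfg$aoa, list(seed = derive_seed(seed, "tune"))))
      tune_hyperparameters(function(hp) {
        net <- build_feature_extractor(net_cfg)
        train_network(net, train_ss, cfg = net_cfg, hyper = hp)$val_accuracy
      }, cfg = tune_cfg)
    })
    hyper <- tuned$best
  }

  net <- stage("train", {
    train_network(build_feature_extractor(net_cfg), train_ss,
                  cfg = net_cfg, hyper = hyper)
  })
  ftr <- stage("features", extract_features(net, train_ss))
  fte <- stage("features", extract_features(net, test_ss))

  disc <- stage("classify", fit_discretizer(ftr, cfg$id3$n_bins))
  tree <- stage("classify", build_tree(apply_discretizer(disc, ftr),
                                       max_depth = cfg$id3$max_depth,
                                       min_samples = cfg$id3$min_samples))
  pred <- stage("classify",
                as.integer(predict(tree, apply_discretizer(disc, fte))))
  cm <- stage("evaluate", confusion(test_ss$labels, pred))
  metrics <- metrics_from_cm(cm)

  manifest <- list(config_hash = config_hash(cfg), seed = seed,
                   iteration = iteration,
                   package_version = tryCatch(
                     as.character(utils::packageVersion("miclass")),
                     error = function(e) "dev"),
                   n_train = length(sp$train), n_test = length(sp$test),
                   hyper = if (length(hyper)) hyper else "defaults",
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(list(metrics = metrics, cm = cm,
                 net_val_accuracy = net$val_accuracy,
                 net_train_accuracy = net$train_accuracy,
                 tree = tree, tuned = tuned, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  held-out: ")
  print(x$metrics)
  cat(sprintf("  network validation accuracy: %.3f\n", x$net_val_accuracy))
  invisible(x)
}

#' Repeated-iteration experiment with averaged report
#'
#' Executes `cfg$eval$n_iterations` independent repetitions (fresh synthetic
#' data, fresh split, fresh seed per iteration) and assembles the
#' per-iteration plus Average metric table. A failed iteration is logged and
#' marked missing, not fatal.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `experiment_report`: `iterations` (list of
#'   `pipeline_result`), `table` (per-iteration + Average metric rows),
#'   `failed` (indices), `manifest`.
#' @export
run_experiment <- function(cfg = pipeline_config()) {
  n <- cfg$eval$n_iterations
  results <- vector("list", n)
  failed <- integer(0)
  for (it in seq_len(n)) {
    results[[it]] <- tryCatch(run_pipeline(cfg, iteration = it - 1),
                              error = function(e) e)
    if (inherits(results[[it]], "error")) {
      mi_warn("iteration", "iteration %d failed: %s", it,
              conditionMessage(results[[it]]))
      failed <- c(failed, it)
    }
  }
  ok <- setdiff(seq_len(n), failed)
  tab <- iteration_report(lapply(results[ok], function(r) r$metrics))
  report <- structure(
    list(iterations = results, table = tab, failed = failed,
         manifest = list(config_hash = config_hash(cfg), seed = cfg$seed,
                         n_iterations = n)),
    class = "experiment_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(cfg$output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(table = tab, failed = failed, manifest = report$manifest,
           confusions = lapply(results[ok], function(r)
             unclass(r$cm))),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$table, row.names = FALSE)
  if (length(x$failed)) cat("failed iterations:", x$failed, "\n")
  invisible(x)
}
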