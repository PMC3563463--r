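# Run configuration and the pipeline stages behind the command-line
# interface (inst/cli/histocascade.R): generate -> extract -> experiment ->
# rank. All randomness flows from the config seed.

#' Read and validate a run configuration
#'
#' YAML with optional fields: `stain_matrix` (9 numbers row-major + `I0`),
#' `detection` (`min_distance`, `min_area`), `texture` (`fo_window`,
#' `glcm_window`, `gabor_half_width`), `experiment` (`n_trials`, `n_folds`),
#' `dataset` (`n_per_class`, `image_size`), `cascade` (YAML path), and
#' `seed`. Missing fields take the package defaults.
#'
#' @param path YAML config path, or `NULL` for all defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  get <- function(x, name, default) if (is.null(x[[name]])) default else x[[name]]
  sm <- if (is.null(cfg$stain_matrix)) default_stain_matrix() else {
    m <- matrix(as.numeric(unlist(cfg$stain_matrix$matrix)), 3, 3, byrow = TRUE)
    stain_matrix(m[1, ], m[2, ], m[3, ], I0 = get(cfg$stain_matrix, "I0", 255))
  }
  cascade <- if (is.null(cfg$cascade)) default_cascade() else {
    if (!file.exists(cfg$cascade)) stopf("cascade file not found: %s", cfg$cascade)
    read_cascade(cfg$cascade)
  }
  seed <- get(cfg, "seed", 1L)
  if (seed != round(seed)) stopf("seed must be an integer")
  structure(list(
    stain_matrix = sm,
    min_distance = get(cfg$detection, "min_distance", 5),
    min_area = get(cfg$detection, "min_area", 30),
    fo_window = get(cfg$texture, "fo_window", 3),
    glcm_window = get(cfg$texture, "glcm_window", 9),
    bank = gabor_bank(half_width = get(cfg$texture, "gabor_half_width", 8)),
    n_trials = get(cfg$experiment, "n_trials", 20),
    n_folds = get(cfg$experiment, "n_folds", 3),
    n_per_class = get(cfg$dataset, "n_per_class", 10),
    image_size = get(cfg$dataset, "image_size", 96),
    cascade = cascade,
    seed = as.integer(seed)), class = "run_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf(...), collapse = " ")))
}

#' Pipeline stages
#'
#' `cli_generate()` writes a synthetic dataset with manifest;
#' `cli_extract()` computes the 591-column feature CSV for a manifest;
#' `cli_experiment()` runs the three-strategy comparison on a feature CSV;
#' `cli_rank()` ranks features by AdaBoost for a binary task.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out Output directory or file path.
#' @return Invisibly, the main output path.
#' @export
cli_generate <- function(config, out) {
  log_stage("generate", "seed=%d n_per_class=%d", config$seed, config$n_per_class)
  ds <- generate_dataset(n_per_class = config$n_per_class,
                         image_size = config$image_size,
                         sm = config$stain_matrix, seed = config$seed)
  write_dataset(ds, out)
  log_stage("generate", "wrote %d ROIs to %s", length(ds$rois), out)
  invisible(file.path(out, "manifest.csv"))
}

#' @rdname cli_generate
#' @param manifest Path to a dataset `manifest.csv`.
#' @export
cli_extract <- function(config, manifest, out) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label", "seed") %in% names(man)))
    stopf("schema error: manifest must have path, label, seed columns")
  log_stage("extract", "%d ROIs", nrow(man))
  base <- dirname(manifest)
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    img <- read_roi_png(p)
    rows[[i]] <- extract_features(img, config$stain_matrix,
                                  min_distance = config$min_distance,
                                  min_area = config$min_area,
                                  fo_window = config$fo_window,
                                  glcm_window = config$glcm_window,
                                  bank = config$bank)
  }
  feat <- as.data.frame(do.call(rbind, rows))
  feat$label <- man$label
  feat$roi_id <- sprintf("roi_%03d", seq_len(nrow(man)))
  feat$seed <- man$seed
  write_feature_csv(feat, out)
  log_stage("extract", "wrote %s", out)
  invisible(out)
}

#' @rdname cli_generate
#' @param features Path to a feature CSV.
#' @export
cli_experiment <- function(config, features, out) {
  fm <- feature_matrix(read_feature_csv(features))
  log_stage("experiment", "n=%d trials=%d folds=%d seed=%d",
            nrow(fm$x), config$n_trials, config$n_folds, config$seed)
  report <- run_experiment(fm$x, fm$labels,
                           n_trials = config$n_trials,
                           n_folds = config$n_folds,
                           seed = config$seed, cascade = config$cascade)
  paths <- write_report(report, out)
  log_stage("experiment", "wrote %s", paths[["csv"]])
  invisible(paths[["csv"]])
}

#' @rdname cli_generate
#' @param task Binary task: `"<A>_vs_<B>"` where A and B are `+`-joined
#'   class-label groups (e.g. `"G3+G4+G5_vs_BE+BS+AT+PIN"` or `"G3_vs_G4"`).
#' @export
cli_rank <- function(config, features, task, out) {
  fm <- feature_matrix(read_feature_csv(features))
  sides <- strsplit(task, "_vs_", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stopf("task must be of the form A_vs_B")
  ga <- strsplit(sides[1], "+", fixed = TRUE)[[1]]
  gb <- strsplit(sides[2], "+", fixed = TRUE)[[1]]
  sel <- fm$labels %in% c(ga, gb)
  if (!any(fm$labels %in% ga) || !any(fm$labels %in% gb))
    stopf("task groups not present in the data")
  log_stage("rank", "task=%s n=%d", task, sum(sel))
  rk <- adaboost_rank(fm$x[sel, , drop = FALSE],
                      ifelse(fm$labels[sel] %in% ga, "A", "B"),
                      seed = config$seed)
  rk$task <- task
  write.csv(rk[, c("task", "rank", "feature", "weight")], out, row.names = FALSE)
  log_stage("rank", "wrote %s", out)
  invisible(out)
}
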