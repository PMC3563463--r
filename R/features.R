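# Feature-table assembly: one 588-feature row per ROI (48 architecture +
# 540 texture), plus label and metadata columns, with a stable documented
# header.

#' Extract the full feature vector of one ROI
#'
#' Runs nuclei detection, computes the 48 architecture features on the
#' detected centroids and the 540 texture features on the RGB image, and
#' returns the concatenated named vector.
#'
#' @param image h x w x 3 RGB array (0-255).
#' @param sm A [stain_matrix()].
#' @param centroids Optional n x 2 matrix overriding detection (e.g. ground
#'   truth centroids).
#' @param min_distance,min_area Detection parameters.
#' @param fo_window,glcm_window,bank Texture parameters.
#' @return Named numeric vector of length 588.
#' @export
extract_features <- function(image, sm = default_stain_matrix(),
                             centroids = NULL, min_distance = 5,
                             min_area = 30, fo_window = 3, glcm_window = 9,
                             bank = gabor_bank()) {
  if (is.null(centroids)) {
    cs <- detect_nuclei(image, sm, min_distance = min_distance,
                        min_area = min_area)
    centroids <- cs$centroids
    # density features need >= 8 points; heavily fused tissue (e.g. gland
    # rings merging into annular blobs) can segment into fewer pieces, so
    # retry at finer watershed granularity before giving up
    relax <- list(c(3, 15), c(2, 8), c(1, 4))
    for (r in relax) {
      if (nrow(centroids) >= 8L) break
      cs <- detect_nuclei(image, sm, min_distance = r[1], min_area = r[2])
      centroids <- cs$centroids
    }
  }
  arch <- architecture_vector(centroids, bounds = dim(image)[1:2])
  tex <- texture_vector(image, fo_window = fo_window,
                        glcm_window = glcm_window, bank = bank)
  c(arch, tex)
}

#' Names of all 588 feature columns, in order
#' @param bank Gabor bank in use.
#' @return Character vector of length 588.
#' @export
feature_column_names <- function(bank = gabor_bank()) {
  c(architecture_feature_names(), texture_feature_names(bank))
}

#' Extract a feature table from a dataset
#'
#' One row per ROI: 588 feature columns, a `label` column, and two metadata
#' columns (`roi_id`, `seed`) — 591 columns in total.
#'
#' @param dataset A `roi_dataset` from [generate_dataset()].
#' @param sm A [stain_matrix()].
#' @param use_ground_truth Use the planted centroids instead of detection.
#' @param ... Passed to [extract_features()].
#' @return Data frame with 591 columns.
#' @export
extract_dataset_features <- function(dataset, sm = default_stain_matrix(),
                                     use_ground_truth = FALSE, ...) {
  n <- length(dataset$rois)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    roi <- dataset$rois[[i]]
    cent <- if (use_ground_truth) roi$ground_truth$centroids else NULL
    rows[[i]] <- extract_features(roi$image, sm, centroids = cent, ...)
  }
  feat <- as.data.frame(do.call(rbind, rows))
  stopifnot(identical(names(feat), feature_column_names()))
  feat$label <- dataset$labels
  feat$roi_id <- sprintf("roi_%03d", seq_len(n))
  feat$seed <- dataset$seeds
  feat
}

#' Write / read the feature CSV
#'
#' The header is the stable schema: 588 documented feature names followed by
#' `label`, `roi_id`, `seed`.
#'
#' @param features Data frame from [extract_dataset_features()].
#' @param path CSV path.
#' @return `write_feature_csv`: invisibly, `path`; `read_feature_csv`: the
#'   data frame (schema-checked).
#' @export
write_feature_csv <- function(features, path) {
  expected <- c(feature_column_names(), "label", "roi_id", "seed")
  if (!identical(names(features), expected))
    stopf("feature table does not match the documented 591-column schema")
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c(feature_column_names(), "label", "roi_id", "seed")
  if (!identical(names(x), expected))
    stopf("schema error: feature CSV columns do not match the documented header")
  x
}

#' Split a feature table into features and labels
#'
#' @param features 591-column data frame.
#' @return List with `x` (588 feature columns) and `labels`.
#' @export
feature_matrix <- function(features) {
  list(x = features[, feature_column_names(), drop = FALSE],
       labels = features$label)
}
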