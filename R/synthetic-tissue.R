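# Synthetic H&E-like tissue generator. Nuclei are rendered as 2D Gaussian
# hematoxylin-density blobs (sd = radius / 2) on an eosin background, the
# stain densities are pushed through the Beer-Lambert forward model of the
# stain matrix, and the result is quantized to 8-bit RGB. Ground truth
# (centroids, radii, density maps) is returned alongside, so every
# downstream stage is testable without clinical data.

TISSUE_CLASSES <- c("G3", "G4", "G5", "BE", "BS", "AT", "PIN")
ARRANGEMENTS <- c("gland_ring", "dispersed", "dense_random", "sparse_random")

#' Define a synthetic tissue class
#'
#' A class spec fixes the nuclear density, spatial arrangement, nucleus size,
#' texture noise and eosin (cytoplasm/stroma) stain level of one of the seven
#' tissue classes: Gleason grades G3/G4/G5, benign epithelium (BE), benign
#' stroma (BS), atrophy (AT) and PIN.
#'
#' @param label One of `"G3","G4","G5","BE","BS","AT","PIN"`.
#' @param nuclei_count_mean Mean number of nuclei per ROI (Poisson mean when
#'   `count_poisson = TRUE`, exact count otherwise). Must be >= 0; when
#'   positive, generated counts are floored at 8 so spatial statistics that
#'   need at least 8 points are always defined.
#' @param arrangement Spatial arrangement: `"gland_ring"` (nuclei on jittered
#'   circles mimicking gland cross-sections), `"dispersed"`/`"sparse_random"`
#'   (rejection-sampled with a minimum center distance), or `"dense_random"`
#'   (unconstrained uniform placement, overlaps allowed).
#' @param nucleus_radius Mean nucleus radius in pixels (> 1).
#' @param nucleus_radius_sd Standard deviation of the per-nucleus radius.
#' @param texture_noise_sd Noise level in intensity units; applied in stain
#'   density space with sd `texture_noise_sd / 255`.
#' @param eosin_level Background eosin stain density in OD units.
#' @param count_poisson Draw the nucleus count from a Poisson distribution
#'   (default) or use `round(nuclei_count_mean)` exactly.
#' @param min_sep Minimum center separation for dispersed/sparse placement,
#'   as a multiple of the mean radius (default 1.2).
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, nuclei_count_mean, arrangement,
                       nucleus_radius, nucleus_radius_sd = 0.4,
                       texture_noise_sd = 2, eosin_level = 0.4,
                       count_poisson = TRUE, min_sep = 1.2) {
  label <- match.arg(label, TISSUE_CLASSES)
  arrangement <- match.arg(arrangement, ARRANGEMENTS)
  if (nuclei_count_mean < 0) stopf("nuclei_count_mean must be >= 0")
  if (nuclei_count_mean > 0 && nucleus_radius <= 1)
    stopf("nucleus_radius must exceed 1 pixel")
  structure(list(label = label,
                 nuclei_count_mean = nuclei_count_mean,
                 arrangement = arrangement,
                 nucleus_radius = nucleus_radius,
                 nucleus_radius_sd = nucleus_radius_sd,
                 texture_noise_sd = texture_noise_sd,
                 eosin_level = eosin_level,
                 count_poisson = count_poisson,
                 min_sep = min_sep),
            class = "class_spec")
}

#' Default specs for the seven tissue classes
#'
#' The defaults encode the hierarchical similarity structure of the class
#' groups: the cancer grades (G3, G4 close together, G5 apart) are nuclei
#' dense with low eosin, the confounders (AT, PIN) and normal classes
#' (BE, BS) are sparser with high eosin. See
#' [class_spec_distance_matrix()] for the induced parameter-space geometry.
#'
#' @return Named list of seven [class_spec()] objects.
#' @export
default_class_specs <- function() {
  specs <- list(
    class_spec("G3", 55, "gland_ring",    4.5, 0.4, texture_noise_sd = 4.0, eosin_level = 0.22),
    class_spec("G4", 65, "dense_random",  4.5, 0.4, texture_noise_sd = 4.5, eosin_level = 0.20),
    class_spec("G5", 90, "dense_random",  4.0, 0.4, texture_noise_sd = 7.0, eosin_level = 0.12),
    class_spec("BE", 30, "dispersed",     4.8, 0.4, texture_noise_sd = 1.6, eosin_level = 0.60),
    class_spec("BS", 24, "sparse_random", 4.6, 0.4, texture_noise_sd = 1.3, eosin_level = 0.63),
    class_spec("AT", 28, "gland_ring",    4.5, 0.4, texture_noise_sd = 2.2, eosin_level = 0.50),
    class_spec("PIN", 35, "gland_ring",   4.7, 0.4, texture_noise_sd = 2.6, eosin_level = 0.47)
  )
  setNames(specs, vapply(specs, `[[`, "", "label"))
}

#' Non-overlapping specs for detection evaluation
#'
#' Four classes (epithelium, stroma and Gleason grades 3 and 4 — the classes
#' used for manual-vs-automatic centroid comparison) with wide nucleus
#' spacing so planted nuclei never overlap; used to measure centroid recovery
#' of the detector.
#'
#' @return Named list of four [class_spec()] objects.
#' @export
nonoverlapping_specs <- function() {
  specs <- list(
    class_spec("G3", 35, "dispersed", 5, 0, texture_noise_sd = 2, eosin_level = 0.25, min_sep = 2.8),
    class_spec("G4", 30, "dispersed", 5, 0, texture_noise_sd = 2, eosin_level = 0.22, min_sep = 2.8),
    class_spec("BE", 25, "dispersed", 5, 0, texture_noise_sd = 1.5, eosin_level = 0.55, min_sep = 2.8),
    class_spec("BS", 20, "dispersed", 5, 0, texture_noise_sd = 1.2, eosin_level = 0.60, min_sep = 2.8)
  )
  setNames(specs, vapply(specs, `[[`, "", "label"))
}

# Numeric parameter vector of a spec (the coordinates on which the
# class-hierarchy invariant is asserted).
spec_param_vector <- function(spec) {
  c(nuclei_count_mean = spec$nuclei_count_mean,
    nucleus_radius = spec$nucleus_radius,
    nucleus_radius_sd = spec$nucleus_radius_sd,
    texture_noise_sd = spec$texture_noise_sd,
    eosin_level = spec$eosin_level)
}

#' Between-class parameter distances
#'
#' Euclidean distances between the numeric parameter vectors of a list of
#' class specs, after z-scoring each parameter across the classes (constant
#' parameters contribute zero). The default specs satisfy
#' d(G3,G4) < d(G3,G5) and every within-pair distance among
#' \{AT,PIN\} and \{BE,BS\} is smaller than any cancer-to-non-cancer distance.
#'
#' @param specs List of [class_spec()]s (default [default_class_specs()]).
#' @return A symmetric distance matrix with class labels as dimnames.
#' @export
class_spec_distance_matrix <- function(specs = default_class_specs()) {
  P <- t(vapply(specs, spec_param_vector, numeric(5)))
  s <- apply(P, 2, sd)
  Z <- sweep(P, 2, colMeans(P), "-")
  keep <- s > 0
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, s[keep], "/")
  Z[, !keep] <- 0
  D <- as.matrix(dist(Z))
  dimnames(D) <- list(vapply(specs, `[[`, "", "label"),
                      vapply(specs, `[[`, "", "label"))
  D
}

# ---- placement -------------------------------------------------------------

place_random <- function(n, height, width, margin, min_dist,
                         max_attempts = 200L, max_restarts = 20L) {
  for (restart in seq_len(max_restarts)) {
    pts <- matrix(numeric(0), 0, 2)
    failed <- FALSE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        p <- c(runif(1, margin, height - margin + 1),
               runif(1, margin, width - margin + 1))
        if (nrow(pts) == 0L || min_dist <= 0 ||
            min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_dist) {
          pts <- rbind(pts, p); placed <- TRUE; break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) return(pts)
  }
  stopf("placement error: could not place %d nuclei at separation %.1f px after %d restarts",
        n, min_dist, max_restarts)
}

place_gland_ring <- function(n, height, width, margin, radius_mean) {
  ring_r <- 13
  cap <- max(4L, floor(2 * pi * ring_r / (2.2 * radius_mean)))
  n_rings <- ceiling(n / cap)
  # gland cross-sections may crowd: relax the ring spacing progressively
  # instead of failing when many rings must fit
  ring_margin <- min(ring_r + margin, min(height, width) / 2 - 1)
  min_dist <- 1.6 * ring_r
  centers <- NULL
  while (is.null(centers)) {
    centers <- tryCatch(
      place_random(n_rings, height, width, margin = ring_margin,
                   min_dist = min_dist, max_attempts = 500L),
      error = function(e) NULL)
    if (is.null(centers)) {
      min_dist <- min_dist * 0.8
      if (min_dist < 1) stopf("placement error: cannot place %d gland rings", n_rings)
    }
  }
  pts <- matrix(numeric(0), 0, 2)
  left <- n
  for (g in seq_len(n_rings)) {
    k <- min(cap, left); left <- left - k
    if (k == 0L) break
    ang <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi) +
      rnorm(k, 0, 0.35 * 2 * pi / k)
    rr <- ring_r + rnorm(k, 0, 1.2)
    pts <- rbind(pts, cbind(centers[g, 1] + rr * sin(ang),
                            centers[g, 2] + rr * cos(ang)))
  }
  pts[, 1] <- pmin(pmax(pts[, 1], margin), height - margin + 1)
  pts[, 2] <- pmin(pmax(pts[, 2], margin), width - margin + 1)
  pts
}

# Render Gaussian blobs (sd = radius / 2) into a density map.
render_blobs <- function(centroids, radii, height, width, peak = 1.0) {
  H <- matrix(0, height, width)
  if (nrow(centroids) == 0L) return(H)
  for (i in seq_len(nrow(centroids))) {
    s <- radii[i] / 2
    r0 <- centroids[i, 1]; c0 <- centroids[i, 2]
    rs <- max(1L, floor(r0 - 3 * s)):min(height, ceiling(r0 + 3 * s))
    cs <- max(1L, floor(c0 - 3 * s)):min(width, ceiling(c0 + 3 * s))
    g <- exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * s^2))
    H[rs, cs] <- H[rs, cs] + peak * g
  }
  H
}

# Smooth unit-variance random field (white noise blurred by a Gaussian).
smooth_field <- function(height, width, sigma = 4) {
  w <- matrix(rnorm(height * width), height, width)
  k <- ceiling(3 * sigma)
  g1 <- exp(-((-k):k)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  f <- filter_reflect(w, outer(g1, g1))
  f / sd(as.numeric(f))
}

# ---- generation ------------------------------------------------------------

#' Generate one synthetic ROI
#'
#' Places nuclei according to the class spec, renders hematoxylin-density
#' Gaussian blobs plus an eosin background, converts stain densities to RGB
#' through the forward Beer-Lambert model of `sm`, and quantizes to 8-bit.
#' Identical `(spec, seed)` give bit-identical output.
#'
#' @param spec A [class_spec()].
#' @param height,width Image size in pixels (>= 64).
#' @param sm A [stain_matrix()].
#' @param seed Integer seed controlling all randomness in this ROI.
#' @return A list with `image` (h x w x 3 integer-valued 8-bit array) and
#'   `ground_truth`: a list with `centroids` (n x 2, (row, col)),
#'   `per_nucleus_radius`, `class_label`, `seed`, and `stain_density`
#'   (h x w x 3 array of planted stain amounts, post-noise).
#' @export
generate_roi <- function(spec, height = 96, width = 96,
                         sm = default_stain_matrix(), seed = 1L) {
  if (!inherits(spec, "class_spec")) stopf("spec must be a class_spec")
  if (height < 64 || width < 64) stopf("height and width must be >= 64")
  sm <- as_stain_matrix(sm)  # errors on non-invertible matrices at construction
  with_seed(seed, {
    n <- if (spec$nuclei_count_mean == 0) 0L
         else if (spec$count_poisson) max(rpois(1L, spec$nuclei_count_mean), 8L)
         else max(round(spec$nuclei_count_mean), 8L)
    margin <- spec$nucleus_radius + 2
    pts <- if (n == 0L) matrix(numeric(0), 0, 2)
      else switch(spec$arrangement,
        gland_ring = place_gland_ring(n, height, width, margin, spec$nucleus_radius),
        dense_random = place_random(n, height, width, margin, min_dist = 0),
        dispersed = ,
        sparse_random = place_random(n, height, width, margin,
                                     min_dist = spec$min_sep * spec$nucleus_radius))
    # nudge apart any (near-)duplicate centroids
    if (nrow(pts) > 1L) {
      d <- as.matrix(dist(pts)); diag(d) <- Inf
      while (min(d) < 0.5) {
        i <- which(d == min(d), arr.ind = TRUE)[1, 1]
        pts[i, ] <- pts[i, ] + runif(2, -1, 1)
        pts[i, 1] <- pmin(pmax(pts[i, 1], margin), height - margin + 1)
        pts[i, 2] <- pmin(pmax(pts[i, 2], margin), width - margin + 1)
        d <- as.matrix(dist(pts)); diag(d) <- Inf
      }
    }
    radii <- if (n == 0L) numeric(0)
      else pmax(rnorm(n, spec$nucleus_radius, spec$nucleus_radius_sd), 1.5)

    sd_od <- spec$texture_noise_sd / 255
    H <- render_blobs(pts, radii, height, width) + 0.02
    if (sd_od > 0) H <- H + matrix(rnorm(height * width, 0, 0.3 * sd_od), height, width)
    E <- spec$eosin_level * (1 + 0.15 * smooth_field(height, width))
    if (sd_od > 0) E <- E + matrix(rnorm(height * width, 0, sd_od), height, width)
    H <- pmax(H, 0); E <- pmax(E, 0)
    density <- array(c(H, E, matrix(0, height, width)), dim = c(height, width, 3))

    img_float <- compose_stains(density, sm)
    image <- array(as.integer(round(pmin(pmax(img_float, 0), sm$I0))),
                   dim = dim(img_float))
    list(image = image,
         ground_truth = list(centroids = pts,
                             per_nucleus_radius = radii,
                             class_label = spec$label,
                             seed = as.integer(seed),
                             stain_density = density))
  })
}

#' Generate a balanced labelled dataset
#'
#' Per-image seeds are derived from the master seed by a counter scheme
#' (`seed + image_index`), so generation is reproducible and order
#' independent.
#'
#' @param specs List of [class_spec()]s with distinct labels.
#' @param n_per_class Number of ROIs per class (>= 1).
#' @param image_size Side length of the square ROIs.
#' @param sm A [stain_matrix()].
#' @param seed Master seed.
#' @return An object of class `roi_dataset`: a list with `rois` (list of
#'   [generate_roi()] results), `labels`, and `seeds`.
#' @export
generate_dataset <- function(specs = default_class_specs(), n_per_class,
                             image_size = 96, sm = default_stain_matrix(),
                             seed = 1L) {
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stopf("duplicate labels in specs")
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  idx <- 0L
  rois <- list(); lab <- character(0); seeds <- integer(0)
  for (spec in specs) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- as.integer(seed) + idx
      rois[[idx]] <- generate_roi(spec, image_size, image_size, sm, seed = s)
      lab[idx] <- spec$label
      seeds[idx] <- s
    }
  }
  structure(list(rois = rois, labels = lab, seeds = seeds,
                 image_size = image_size),
            class = "roi_dataset")
}

#' Write a dataset to disk
#'
#' Writes each ROI as an 8-bit RGB PNG with a JSON ground-truth sidecar
#' (`centroids`, `label`, `seed`), plus a `manifest.csv` (path, label, seed).
#'
#' @param dataset A `roi_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$rois)
  paths <- character(n)
  for (i in seq_len(n)) {
    roi <- dataset$rois[[i]]
    base <- sprintf("roi_%03d_%s", i, dataset$labels[i])
    paths[i] <- file.path(dir, paste0(base, ".png"))
    png::writePNG(roi$image / 255, paths[i])
    gt <- roi$ground_truth
    jsonlite::write_json(
      list(centroids = unname(apply(gt$centroids, 1, function(p) c(p[1], p[2]),
                                    simplify = FALSE)),
           label = gt$class_label, seed = gt$seed),
      file.path(dir, paste0(base, ".json")), auto_unbox = TRUE, digits = NA)
  }
  manifest <- data.frame(path = paths, label = dataset$labels,
                         seed = dataset$seeds, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an ROI image written by [write_dataset()]
#'
#' @param path PNG path.
#' @return h x w x 3 array of 8-bit intensities (0-255).
#' @export
read_roi_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
  array(as.integer(round(x[, , 1:3] * 255)), dim = c(dim(x)[1:2], 3))
}
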