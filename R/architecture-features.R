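# Nuclear-architecture features: 48 scalars summarizing the Voronoi
# tessellation (12), Delaunay triangulation (8), minimum spanning tree (4)
# and nuclear density (24) of the detected centroids. Each measurement pool
# is reduced to mean, population standard deviation, disorder
# (1 - 1/(1 + std/mean)) and min/max ratio, or mean/std/disorder for the
# density families.

#' Summary statistics of a measurement pool
#'
#' Computes the mean `B`, population standard deviation `A`, the disorder
#' statistic `1 - 1/(1 + A/B)` (0 when either `A = 0` or `B = 0`), and the
#' minimum-to-maximum ratio (1 when the maximum is 0).
#'
#' @param values Non-empty numeric vector of non-negative measurements.
#' @return Named numeric vector `c(mean, std, disorder, min_max_ratio)`.
#' @export
summarize_stats <- function(values) {
  if (length(values) == 0L) stopf("degenerate input: empty measurement pool")
  B <- mean(values)
  A <- sqrt(mean((values - B)^2))
  disorder <- if (A == 0 || B == 0) 0 else 1 - 1 / (1 + A / B)
  mx <- max(values)
  ratio <- if (mx == 0) 1 else min(values) / mx
  c(mean = B, std = A, disorder = disorder, min_max_ratio = ratio)
}

# Drop duplicated centroids (within eps) with a warning; returns the matrix.
dedupe_centroids <- function(V, eps = 1e-6) {
  V <- as.matrix(V)
  if (nrow(V) > 1L) {
    key <- paste(round(V[, 1] / eps), round(V[, 2] / eps))
    if (anyDuplicated(key)) {
      warning("duplicate centroids removed before graph construction")
      V <- V[!duplicated(key), , drop = FALSE]
    }
  }
  V
}

as_centroids <- function(V) {
  if (inherits(V, "centroid_set")) V <- V$centroids
  dedupe_centroids(V)
}

check_noncollinear <- function(V, n_min) {
  if (nrow(V) < n_min)
    stopf("degenerate geometry: need at least %d distinct centroids (got %d)",
          n_min, nrow(V))
  a <- V[2, ] - V[1, ]
  cr <- (V[, 1] - V[1, 1]) * a[2] - (V[, 2] - V[1, 2]) * a[1]
  if (all(abs(cr) < 1e-9)) stopf("degenerate geometry: centroids are collinear")
}

ring_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# deldir computation shared by the Voronoi and Delaunay functions.
run_deldir <- function(V, bounds = NULL) {
  rw <- if (is.null(bounds)) NULL else c(0.5, bounds[2] + 0.5, 0.5, bounds[1] + 0.5)
  # deldir works in (x, y) = (col, row) coordinates
  deldir::deldir(x = V[, 2], y = V[, 1], rw = rw, suppressMsge = TRUE)
}

#' Voronoi tessellation features
#'
#' Builds the Voronoi tessellation of the centroids (cells clipped to the
#' image rectangle, so areas sum to the image area) and summarizes the pools
#' of cell areas, chord lengths (all pairwise distances between a cell's
#' vertices) and cell perimeters by mean, std, disorder and min/max ratio —
#' 12 features.
#'
#' @param V `centroid_set` or n x 2 matrix of (row, col) centroids; at least
#'   4 non-collinear points.
#' @param bounds `c(height, width)` of the image rectangle.
#' @return List with `tessellation` (a list of cell polygons with `owner`
#'   indices) and `features` (named numeric vector, length 12).
#' @export
voronoi_features <- function(V, bounds) {
  V <- as_centroids(V)
  check_noncollinear(V, 4L)
  dd <- run_deldir(V, bounds)
  tiles <- deldir::tile.list(dd)
  areas <- vapply(tiles, function(t) t$area, 0)
  perims <- vapply(tiles, function(t) ring_perimeter(t$x, t$y), 0)
  chords <- unlist(lapply(tiles, function(t) {
    if (length(t$x) < 2L) return(numeric(0))
    as.numeric(stats::dist(cbind(t$x, t$y)))
  }))
  feats <- c(area = summarize_stats(areas),
             chord = summarize_stats(chords),
             perimeter = summarize_stats(perims))
  names(feats) <- paste0("voronoi_", gsub("\\.", "_", names(feats)))
  polys <- lapply(seq_along(tiles), function(i)
    list(owner = i, row = tiles[[i]]$y, col = tiles[[i]]$x,
         area = tiles[[i]]$area))
  list(tessellation = polys, features = feats)
}

#' Delaunay triangulation features
#'
#' Triangulates the centroids (the dual of the Voronoi tessellation: two
#' centroids are joined iff their cells share a boundary) and summarizes
#' triangle areas and perimeters — 8 features. Also returns the edge set,
#' the carrier graph for the MST.
#'
#' @param V `centroid_set` or n x 2 matrix; at least 3 non-collinear points.
#' @return List with `graph` (list: `vertices` n x 2, `edges` m x 2 index
#'   pairs, `weights` Euclidean lengths) and `features` (length 8).
#' @export
delaunay_features <- function(V) {
  V <- as_centroids(V)
  check_noncollinear(V, 3L)
  dd <- run_deldir(V)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0L) stopf("degenerate geometry: no Delaunay triangles")
  areas <- vapply(tl, function(t) {
    x <- t$x; y <- t$y
    abs((x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])) / 2
  }, 0)
  perims <- vapply(tl, function(t) ring_perimeter(t$x, t$y), 0)
  e <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
             pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  e <- unique(e)
  w <- sqrt((V[e[, 1], 1] - V[e[, 2], 1])^2 + (V[e[, 1], 2] - V[e[, 2], 2])^2)
  feats <- c(area = summarize_stats(areas), perimeter = summarize_stats(perims))
  names(feats) <- paste0("delaunay_", gsub("\\.", "_", names(feats)))
  list(graph = list(vertices = V, edges = e, weights = w), features = feats)
}

#' Minimum spanning tree features
#'
#' Computes the MST on the Delaunay edge set and summarizes its branch
#' lengths — 4 features.
#'
#' @param graph The `graph` element returned by [delaunay_features()].
#' @return List with `graph` (the MST as vertices/edges/weights) and
#'   `features` (length 4).
#' @export
mst_features <- function(graph) {
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(graph$vertices))
    g <- igraph::add_vertices(g, nrow(graph$vertices) - igraph::vcount(g))
  if (igraph::components(g)$no != 1L) stopf("input graph is disconnected")
  igraph::E(g)$weight <- graph$weights
  mst <- igraph::mst(g)
  w <- igraph::E(mst)$weight
  feats <- summarize_stats(w)
  names(feats) <- paste0("mst_branch_", names(feats))
  list(graph = list(vertices = graph$vertices,
                    edges = igraph::as_edgelist(mst),
                    weights = w),
       features = feats)
}

# Counting kernel: neighbors within each radius (<= radius counts as inside).
neighbor_counts <- function(D, radii) {
  vapply(radii, function(r) rowSums(D <= r) - 1L, numeric(nrow(D)))
}

#' Nuclear density features
#'
#' Two families: (1) for each point, the number of neighboring centroids
#' within circles of radius 10, 20, 30, 40 and 50 pixels, each radius pooled
#' over all points and summarized by mean, std and disorder (15 features);
#' (2) for each point, the mean distance to its nearest 3, 5 and 7 neighbors,
#' summarized the same way (9 features). 24 features in total.
#'
#' @param V `centroid_set` or n x 2 matrix with at least 8 points (so 7
#'   neighbors exist).
#' @param radii Circle radii in pixels.
#' @param k_neighbors Neighbor counts for the distance family.
#' @return Named numeric vector of length 24.
#' @export
density_features <- function(V, radii = c(10, 20, 30, 40, 50),
                             k_neighbors = c(3, 5, 7)) {
  V <- as_centroids(V)
  if (nrow(V) < 8L)
    stopf("degenerate input: density features need at least 8 centroids (got %d)", nrow(V))
  D <- as.matrix(stats::dist(V))
  counts <- neighbor_counts(D, radii)
  f1 <- unlist(lapply(seq_along(radii), function(i) {
    s <- summarize_stats(counts[, i])[1:3]
    setNames(s, paste0("density_r", radii[i], "_", names(s)))
  }))
  Ds <- apply(D, 1, sort)  # column j = sorted distances from point j
  f2 <- unlist(lapply(k_neighbors, function(k) {
    v <- colMeans(Ds[2:(k + 1), , drop = FALSE])
    s <- summarize_stats(v)[1:3]
    setNames(s, paste0("density_nn", k, "_", names(s)))
  }))
  c(f1, f2)
}

#' The 48-feature nuclear-architecture vector
#'
#' Concatenates the Voronoi (12), Delaunay (8), MST (4) and density (24)
#' features in a fixed, documented order (see
#' [architecture_feature_names()]). Invariant to the input ordering of the
#' centroids.
#'
#' @param V `centroid_set` or n x 2 matrix with at least 8 points.
#' @param bounds `c(height, width)` of the image rectangle.
#' @return Named numeric vector of length 48.
#' @export
architecture_vector <- function(V, bounds) {
  V <- as_centroids(V)
  vor <- voronoi_features(V, bounds)
  del <- delaunay_features(V)
  mst <- mst_features(del$graph)
  out <- c(vor$features, del$features, mst$features, density_features(V))
  stopifnot(length(out) == 48L)
  out
}

#' Names of the 48 architecture features, in order
#' @return Character vector of length 48.
#' @export
architecture_feature_names <- function() {
  stats4 <- c("mean", "std", "disorder", "min_max_ratio")
  stats3 <- c("mean", "std", "disorder")
  c(paste0("voronoi_", rep(c("area", "chord", "perimeter"), each = 4), "_", stats4),
    paste0("delaunay_", rep(c("area", "perimeter"), each = 4), "_", stats4),
    paste0("mst_branch_", stats4),
    paste0("density_r", rep(c(10, 20, 30, 40, 50), each = 3), "_", stats3),
    paste0("density_nn", rep(c(3, 5, 7), each = 3), "_", stats3))
}
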