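# Nuclear centroid detection: Otsu binarization of the hematoxylin channel,
# exact Euclidean distance transform relative to the 8-connected exterior
# boundary, and marker-based watershed flooding of the distance map from its
# regional maxima. Centroids are the geometric centers of the resulting
# segments.

#' Binarize a hematoxylin channel with Otsu's method
#'
#' The threshold maximizes the between-class variance on a 256-bin histogram;
#' the foreground `N` is the stain-dense (high) side. The boundary set `B`
#' is the 8-connected exterior border of `N` (background pixels adjacent to
#' foreground), so `N` and `B` are disjoint.
#'
#' @param channel Single-channel numeric matrix (e.g. from
#'   [hematoxylin_channel()]).
#' @return An object of class `nuclear_mask`: list with logical matrices
#'   `mask` (N) and `boundary` (B), and the `threshold` on the channel scale.
#' @export
binarize_otsu <- function(channel) {
  rng <- range(channel)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    stopf("degenerate input: channel is constant, no Otsu threshold exists")
  scaled <- (channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  mask <- scaled > thr
  boundary <- local_extreme(mask * 1, 1L, pmax) > 0 & !mask
  structure(list(mask = mask, boundary = boundary,
                 threshold = rng[1] + thr * diff(rng)),
            class = "nuclear_mask")
}

#' Euclidean distance transform of a nuclear mask
#'
#' For each foreground pixel, the exact Euclidean distance to the nearest
#' boundary pixel (equivalently, the nearest background pixel); zero on the
#' background.
#'
#' @param mask A `nuclear_mask` from [binarize_otsu()], or a logical matrix.
#' @return Numeric matrix of distances (a `DistanceMap`).
#' @export
distance_transform <- function(mask) {
  m <- if (inherits(mask, "nuclear_mask")) mask$mask else mask
  if (!any(m)) {
    warning("empty foreground: distance map is identically zero")
    return(matrix(0, nrow(m), ncol(m)))
  }
  d <- EBImage::distmap(m * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(m), ncol(m))
}

# Regional maxima of d on the mask: pixels not exceeded in their 8-neighbor-
# hood; equal-valued plateaus collapse to a single marker at the plateau
# pixel of (row, col)-lexicographic centroid.
find_markers <- function(dmap, mask, min_distance = 5) {
  is_max <- mask & dmap > 0 & (dmap >= local_extreme(dmap, 1L, pmax) - 1e-9)
  if (!any(is_max)) return(matrix(integer(0), 0, 2))
  lab <- EBImage::bwlabel(is_max * 1)
  n <- max(lab)
  pts <- matrix(0, n, 2)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  for (i in seq_len(n)) {
    p <- idx[labs == i, , drop = FALSE]
    ctr <- colMeans(p)
    # snap the marker to the plateau member nearest the plateau centroid
    j <- which.min((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    pts[i, ] <- p[j, ]
  }
  # merge markers closer than min_distance (single linkage); the merged
  # marker sits at the member with the largest distance value
  if (nrow(pts) > 1L && min_distance > 0) {
    dd <- as.matrix(stats::dist(pts))
    grp <- seq_len(nrow(pts))
    find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
    for (i in seq_len(nrow(pts) - 1L)) for (j in (i + 1L):nrow(pts))
      if (dd[i, j] < min_distance) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
      }
    roots <- vapply(seq_len(nrow(pts)), find, 1L)
    keep <- lapply(unique(roots), function(g) {
      mem <- which(roots == g)
      mem[which.max(dmap[cbind(pts[mem, 1], pts[mem, 2])])]
    })
    pts <- pts[unlist(keep), , drop = FALSE]
  }
  pts
}

#' Watershed segmentation of the distance map
#'
#' Regional maxima of the distance map (8-connected; plateaus collapse to a
#' single marker, markers closer than `min_distance` merge) seed a flood of
#' the negated distance map restricted to the foreground. Segments smaller
#' than `min_area` pixels are discarded; centroids are the per-segment
#' geometric centers.
#'
#' @param dist Distance map from [distance_transform()].
#' @param mask `nuclear_mask` or logical matrix.
#' @param min_distance Minimum marker separation in pixels (default 5).
#' @param min_area Minimum segment area in pixels (default 30).
#' @return An object of class `centroid_set`: list with `centroids`
#'   (n x 2 matrix of (row, col), subpixel) and `labels` (integer matrix of
#'   per-pixel segment ids, 0 = background).
#' @export
watershed_centroids <- function(dist, mask, min_distance = 5, min_area = 30) {
  m <- if (inherits(mask, "nuclear_mask")) mask$mask else mask
  if (!any(m)) stopf("mask is empty")
  markers <- find_markers(dist, m, min_distance)
  if (nrow(markers) == 0L) {
    warning("no local maxima found; returning empty centroid set")
    return(structure(list(centroids = matrix(numeric(0), 0, 2),
                          labels = matrix(0L, nrow(m), ncol(m))),
                     class = "centroid_set"))
  }
  mk <- cbind(markers, seq_len(nrow(markers)))
  labels <- watershed_flood_cpp(dist, m, mk)
  # size filter + sequential relabel + centroids
  tab <- tabulate(labels[labels > 0], nbins = nrow(markers))
  keep <- which(tab >= min_area)
  remap <- integer(nrow(markers))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- remap[labels[pos]]
  cents <- matrix(numeric(0), 0, 2)
  if (length(keep)) {
    idx <- which(labels > 0, arr.ind = TRUE)
    l <- labels[labels > 0]
    cents <- cbind(tapply(idx[, 1], l, mean), tapply(idx[, 2], l, mean))
    dimnames(cents) <- NULL
  }
  structure(list(centroids = cents, labels = labels), class = "centroid_set")
}

#' Detect nuclear centroids in an RGB tissue image
#'
#' Full pipeline: color deconvolution, hematoxylin channel, Otsu
#' binarization, Euclidean distance transform, marker-based watershed.
#' Deterministic for fixed inputs. A (near-)stain-free image yields an
#' empty centroid set with a warning.
#'
#' @param image h x w x 3 RGB intensity array (0-255).
#' @param sm A [stain_matrix()].
#' @param min_distance,min_area Watershed parameters, see
#'   [watershed_centroids()].
#' @return A `centroid_set`.
#' @export
detect_nuclei <- function(image, sm = default_stain_matrix(),
                          min_distance = 5, min_area = 30) {
  od <- to_optical_density(image, I0 = as_stain_matrix(sm)$I0)
  h <- hematoxylin_channel(deconvolve(od, sm))
  if (diff(range(h)) < 0.05) {
    warning("degenerate input: hematoxylin channel is nearly constant")
    return(structure(list(centroids = matrix(numeric(0), 0, 2),
                          labels = matrix(0L, nrow(h), ncol(h))),
                     class = "centroid_set"))
  }
  nm <- binarize_otsu(h)
  d <- distance_transform(nm)
  watershed_centroids(d, nm, min_distance = min_distance, min_area = min_area)
}

#' Match detected centroids to ground truth
#'
#' Greedy bipartite matching by increasing distance: each detected centroid
#' may match at most one true centroid within `max_dist` pixels.
#'
#' @param detected,truth n x 2 matrices of (row, col) coordinates.
#' @param max_dist Match radius in pixels (default 3).
#' @return List with `n_matched`, `sensitivity` (matched / truth) and
#'   `spurious_rate` (unmatched detections / detections).
#' @export
match_centroids <- function(detected, truth, max_dist = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(n_matched = 0L, sensitivity = 0, spurious_rate = if (nd) 1 else 0))
  D <- outer(detected[, 1], truth[, 1], "-")^2 + outer(detected[, 2], truth[, 2], "-")^2
  D <- sqrt(D)
  ord <- order(D)
  used_d <- logical(nd); used_t <- logical(nt); matched <- 0L
  for (k in ord) {
    if (D[k] > max_dist) break
    i <- (k - 1L) %% nd + 1L; j <- (k - 1L) %/% nd + 1L
    if (used_d[i] || used_t[j]) next
    used_d[i] <- used_t[j] <- TRUE
    matched <- matched + 1L
  }
  list(n_matched = matched,
       sensitivity = matched / nt,
       spurious_rate = (nd - matched) / nd)
}
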