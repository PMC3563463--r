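# Independent oracles used by the tests. These deliberately avoid the code
# paths they check (brute-force enumeration, closed forms, direct counting).

# Minimum spanning weight by exhaustive enumeration of all (n-1)-edge
# subsets of the given edge list, keeping those that span and connect.
brute_min_spanning_weight <- function(edges, weights, n) {
  m <- nrow(edges)
  stopifnot(m >= n - 1)
  best <- Inf
  combos <- combn(m, n - 1)
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }  # cycle: n-1 edges cannot span
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(weights[sel]))
  }
  best
}

# Delaunay edges by the brute-force circumcircle test on all triples
# (general-position point sets only).
brute_delaunay_edges <- function(V) {
  n <- nrow(V)
  edges <- matrix(integer(0), 0, 2)
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    p <- V[tri[1], ]; q <- V[tri[2], ]; r <- V[tri[3], ]
    # circumcenter via perpendicular bisectors
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    ux <- ((sum(p^2)) * (q[2] - r[2]) + (sum(q^2)) * (r[2] - p[2]) +
           (sum(r^2)) * (p[2] - q[2])) / d
    uy <- ((sum(p^2)) * (r[1] - q[1]) + (sum(q^2)) * (p[1] - r[1]) +
           (sum(r^2)) * (q[1] - p[1])) / d
    rad2 <- sum((p - c(ux, uy))^2)
    others <- setdiff(seq_len(n), tri)
    inside <- any(vapply(others, function(o)
      sum((V[o, ] - c(ux, uy))^2) < rad2 - 1e-9, TRUE))
    if (!inside)
      edges <- rbind(edges, t(combn(sort(tri), 2)))
  }
  unique(edges)
}

# Reference GLCM feature computation for a single pixel's full window,
# written directly from the formula sheet over a dense 256x256 matrix.
ref_glcm_pixel <- function(plane, r, c, window, offsets) {
  half <- window %/% 2
  r0 <- max(1, r - half); r1 <- min(nrow(plane), r + half)
  c0 <- max(1, c - half); c1 <- min(ncol(plane), c + half)
  P <- matrix(0, 256, 256)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (cc in c0:c1) for (rr in r0:r1) {
      rr2 <- rr + dr; cc2 <- cc + dc
      if (rr2 < r0 || rr2 > r1 || cc2 < c0 || cc2 > c1) next
      a <- plane[rr, cc] + 1; b <- plane[rr2, cc2] + 1
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P <- P / sum(P)
  i <- row(P) - 1; j <- col(P) - 1
  px <- rowSums(P)
  mu <- sum(i * P); sigma2 <- sum((i - mu)^2 * P)
  nz <- P > 0
  ent <- -sum(P[nz] * log(P[nz]))
  psum <- tapply(as.numeric(P), as.numeric(i + j), sum)
  pdiff <- tapply(as.numeric(P), as.numeric(abs(i - j)), sum)
  ks <- as.numeric(names(psum)); kd <- as.numeric(names(pdiff))
  sa <- sum(ks * psum)
  da <- sum(kd * pdiff)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  pxi <- px[i + 1]; pxj <- px[j + 1]
  hxy1 <- -sum(P[nz] * log(pxi[nz] * pxj[nz]))
  hxy2 <- -sum(outer(px, px)[outer(px, px) > 0] *
               log(outer(px, px)[outer(px, px) > 0]))
  c(autocorrelation = sum(i * j * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sigma2 > 0) sum((i - mu) * (j - mu) * P) / sigma2 else 1,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = ent,
    homogeneity = sum(P / (1 + (i - j)^2)),
    max_probability = max(P),
    variance = sum((i - mu)^2 * P),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = -sum(psum[psum > 0] * log(psum[psum > 0])),
    difference_variance = sum((kd - da)^2 * pdiff),
    difference_entropy = -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0])),
    imc1 = if (hx > 0) (ent - hxy1) / hx else 0,
    imc2 = sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0)),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_norm = sum(P / (1 + abs(i - j) / 256)),
    inverse_difference_moment_norm = sum(P / (1 + (i - j)^2 / 256^2)))
}

# A disc mask centered at (r0, c0).
disc_mask <- function(nr, nc, r0, c0, radius) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) (r - r0)^2 + (c - c0)^2 <= radius^2)
}

# Small ROI helper: a fast, fixed-size ROI for a given spec label.
quick_roi <- function(label = "G4", seed = 1, size = 96) {
  generate_roi(default_class_specs()[[label]], size, size, seed = seed)
}
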