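test_that("summary statistics follow the disorder and ratio conventions", {
  s <- summarize_stats(c(5, 5, 5))
  expect_equal(unname(s), c(5, 0, 0, 1))
  # values {1, 3}: mean 2, population std 1, disorder 1/3, ratio 1/3
  s2 <- summarize_stats(c(1, 3))
  expect_equal(unname(s2), c(2, 1, 1 / 3, 1 / 3))
  # A = B gives disorder 1/2
  v <- c(0, 2)  # mean 1, population std 1
  expect_equal(summarize_stats(v)[["disorder"]], 0.5)
  expect_equal(summarize_stats(c(0, 0))[["min_max_ratio"]], 1)
  expect_error(summarize_stats(numeric(0)), "empty")
})

test_that("four corner points in a square image give four congruent cells", {
  # square of points centered in the [0.5, 40.5]^2 pixel rectangle
  V <- rbind(c(10.5, 10.5), c(10.5, 30.5), c(30.5, 10.5), c(30.5, 30.5))
  vf <- voronoi_features(V, bounds = c(40, 40))
  f <- vf$features
  expect_length(f, 12L)
  expect_equal(f[["voronoi_area_mean"]], 40 * 40 / 4)
  expect_equal(f[["voronoi_area_std"]], 0)
  expect_equal(f[["voronoi_area_disorder"]], 0)
  expect_equal(f[["voronoi_area_min_max_ratio"]], 1)
  expect_error(voronoi_features(V[1:2, ], c(40, 40)), "degenerate")
  expect_error(voronoi_features(rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)),
                                c(40, 40)), "collinear")
})

test_that("Voronoi cell areas always sum to the image area", {
  for (s in 1:5) {
    set.seed(s)
    V <- cbind(runif(20, 1, 60), runif(20, 1, 80))
    vf <- voronoi_features(V, bounds = c(60, 80))
    areas <- vapply(vf$tessellation, `[[`, 0, "area")
    expect_equal(sum(areas), 60 * 80, tolerance = 1e-6)
    expect_length(vf$tessellation, 20L)
  }
})

test_that("a 3-4-5 right triangle yields the closed-form Delaunay features", {
  V <- rbind(c(0, 0), c(3, 0), c(0, 4))  # legs 3 and 4, hypotenuse 5
  df <- delaunay_features(V)
  expect_length(df$features, 8L)
  expect_equal(df$features[["delaunay_area_mean"]], 6)
  expect_equal(df$features[["delaunay_perimeter_mean"]], 12)
  expect_equal(df$features[["delaunay_area_std"]], 0)
  expect_equal(nrow(df$graph$edges), 3L)
})

test_that("Delaunay edges match the brute-force circumcircle oracle", {
  for (s in 1:10) {
    set.seed(s)
    V <- cbind(runif(8, 0, 50), runif(8, 0, 50))
    df <- delaunay_features(V)
    ref <- brute_delaunay_edges(V)
    got <- df$graph$edges[order(df$graph$edges[, 1], df$graph$edges[, 2]), ]
    ref <- ref[order(ref[, 1], ref[, 2]), ]
    expect_equal(unname(got), unname(ref))
  }
})

test_that("Voronoi/Delaunay duality holds for interior edges", {
  set.seed(42)
  V <- cbind(runif(15, 20, 80), runif(15, 20, 80))
  vf <- voronoi_features(V, bounds = c(100, 100))
  df <- delaunay_features(V)
  touches_border <- function(p)
    any(p$row < 0.5 + 1e-6 | p$row > 100.5 - 1e-6 |
        p$col < 0.5 + 1e-6 | p$col > 100.5 - 1e-6)
  shares_boundary <- function(a, b) {
    pa <- vf$tessellation[[a]]; pb <- vf$tessellation[[b]]
    shared <- 0
    for (i in seq_along(pa$row)) for (j in seq_along(pb$row))
      if (abs(pa$row[i] - pb$row[j]) < 1e-6 &&
          abs(pa$col[i] - pb$col[j]) < 1e-6) shared <- shared + 1
    shared >= 2
  }
  checked <- 0
  for (k in seq_len(nrow(df$graph$edges))) {
    a <- df$graph$edges[k, 1]; b <- df$graph$edges[k, 2]
    if (touches_border(vf$tessellation[[a]]) ||
        touches_border(vf$tessellation[[b]])) next  # clipped cells exempt
    expect_true(shares_boundary(a, b))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("MST equals the exhaustive spanning-tree minimum on small sets", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:8, 1)
    V <- cbind(runif(n, 0, 40), runif(n, 0, 40))
    df <- delaunay_features(V)
    mf <- mst_features(df$graph)
    expect_length(mf$features, 4L)
    expect_equal(sum(mf$graph$weights),
                 brute_min_spanning_weight(df$graph$edges, df$graph$weights, n))
    # MST edges are a subset of the Delaunay edges
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(key(mf$graph$edges) %in% key(df$graph$edges)))
  }
})

test_that("equally spaced near-collinear points give a chain MST", {
  V <- cbind(10 + (0:4) * 7, 10 + c(0, 0.3, -0.2, 0.25, -0.1))
  mf <- mst_features(delaunay_features(V)$graph)
  expect_equal(mf$features[["mst_branch_mean"]], 7, tolerance = 0.01)
  expect_lt(mf$features[["mst_branch_std"]], 0.1)
  expect_gt(mf$features[["mst_branch_min_max_ratio"]], 0.98)
})

test_that("neighbor counting kernel matches direct enumeration", {
  # 3 collinear points spaced 5 px: middle sees 2 within radius 10, ends 1
  V <- rbind(c(10, 10), c(10, 15), c(10, 20))
  D <- as.matrix(dist(V))
  counts <- histocascade:::neighbor_counts(D, 10)
  expect_equal(as.numeric(counts), c(1, 2, 1) + c(1, 0, 1))
  # <= radius inclusion: a point exactly at distance 10 counts
  V2 <- rbind(c(0, 0), c(0, 10))
  expect_equal(as.numeric(histocascade:::neighbor_counts(as.matrix(dist(V2)), 10)),
               c(1, 1))
})

test_that("regular grid density features match grid geometry", {
  V <- as.matrix(expand.grid(row = (0:4) * 20 + 5, col = (0:4) * 20 + 5))
  f <- density_features(V)
  expect_length(f, 24L)
  # interior points have 4 neighbors at distance exactly 20
  Ds <- as.matrix(dist(V))
  nn3 <- mean(apply(Ds, 1, function(d) mean(sort(d)[2:4])))
  expect_equal(f[["density_nn3_mean"]], nn3)
  # interior point: its 3 nearest neighbors all sit at the grid spacing
  expect_equal(mean(sort(Ds[13, ])[2:4]), 20)
  expect_error(density_features(V[1:5, ]), "at least 8")
})

test_that("the 48-feature vector is ordered, named, and input-order invariant", {
  set.seed(3)
  V <- cbind(runif(25, 5, 90), runif(25, 5, 90))
  f <- architecture_vector(V, c(96, 96))
  expect_length(f, 48L)
  expect_identical(names(f), architecture_feature_names())
  perm <- V[sample(nrow(V)), ]
  expect_equal(architecture_vector(perm, c(96, 96)), f)
  # translation invariance away from borders (density + graphs; Voronoi
  # cells of interior points are unaffected by a small shift)
  V2 <- V + 2
  f2 <- architecture_vector(V2, c(100, 100))
  expect_equal(f2[grep("^(mst|density|delaunay)", names(f2))],
               f[grep("^(mst|density|delaunay)", names(f))], tolerance = 1e-8)
})

test_that("duplicate centroids are deduplicated with a warning", {
  V <- rbind(c(10, 10), c(10, 10), c(20, 30), c(40, 15), c(30, 40),
             c(50, 50), c(60, 20), c(70, 70), c(15, 60))
  expect_warning(f <- architecture_vector(V, c(80, 80)), "duplicate")
  expect_length(f, 48L)
})
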