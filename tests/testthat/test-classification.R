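# Small separable feature clouds standing in for the seven classes.
make_clusters <- function(n_per_class, sep = 6, sd = 1, seed = 1,
                          classes = c("G3", "G4", "G5", "BE", "BS", "AT", "PIN")) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep, sep, sep, 2 * sep, 0,
                      0, 2 * sep, 2 * sep, 2 * sep), ncol = 2, byrow = TRUE)
  x <- NULL; y <- character(0)
  for (i in seq_along(classes)) {
    x <- rbind(x, cbind(rnorm(n_per_class, centers[i, 1], sd),
                        rnorm(n_per_class, centers[i, 2], sd)))
    y <- c(y, rep(classes[i], n_per_class))
  }
  list(x = data.frame(f1 = x[, 1], f2 = x[, 2]), y = y)
}

test_that("Eq.-style metrics follow the contingency arithmetic", {
  expect_equal(unname(evaluate_counts(1, 1, 0, 0)), c(1, 1, 1))
  m <- evaluate_counts(3, 10, 1, 2)
  expect_equal(m[["ACC"]], 13 / 16)
  expect_equal(m[["PPV"]], 0.75)
  expect_equal(m[["NPV"]], 10 / 12)
  m0 <- evaluate_counts(0, 5, 0, 2)
  expect_true(is.na(m0[["PPV"]]))
  expect_equal(m0[["NPV"]], 5 / 7)
  expect_error(evaluate_counts(0, 0, 0, 0), "zero")
})

test_that("ACC is invariant and PPV/NPV swap under group relabeling", {
  tp <- 7; tn <- 11; fp <- 3; fn <- 2
  m <- evaluate_counts(tp, tn, fp, fn)
  sw <- evaluate_counts(tn, tp, fn, fp)  # positive and negative exchanged
  expect_equal(m[["ACC"]], sw[["ACC"]])
  expect_equal(m[["PPV"]], sw[["NPV"]])
  expect_equal(m[["NPV"]], sw[["PPV"]])
})

test_that("binary trees separate separable data and are deterministic", {
  d <- make_clusters(20, seed = 2)
  fit <- train_binary_tree(d$x, d$y, c("G3", "G4", "G5"),
                           c("BE", "BS", "AT", "PIN"), seed = 1)
  pred <- predict(fit, d$x, type = "class")
  truth <- ifelse(d$y %in% c("G3", "G4", "G5"), "pos", "neg")
  expect_equal(mean(pred == truth), 1)
  fit2 <- train_binary_tree(d$x, d$y, c("G3", "G4", "G5"),
                            c("BE", "BS", "AT", "PIN"), seed = 1)
  expect_identical(predict(fit2, d$x, type = "class"), pred)
  expect_error(train_binary_tree(d$x, d$y, "G3", "nonexistent"), "training error")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  accs <- vapply(1:50, function(s) {
    set.seed(s)
    x <- data.frame(f1 = rnorm(80), f2 = rnorm(80))
    y <- rep(c("A", "B"), 40)[sample(80)]
    fit <- train_binary_tree(x[1:40, ], y[1:40], "A", "B")
    mean((predict(fit, x[41:80, ], type = "class") == "pos") == (y[41:80] == "A"))
  }, 0)
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("the default cascade encodes six binary divisions over 7 leaves", {
  cas <- default_cascade()
  expect_equal(histocascade:::count_nodes(cas), 6L)
  expect_setequal(histocascade:::cascade_leaves(cas),
                  c("G3", "G4", "G5", "BE", "BS", "AT", "PIN"))
  expect_setequal(cas$left_group, c("G3", "G4", "G5"))
  expect_setequal(cas$right_group, c("BE", "BS", "AT", "PIN"))
})

test_that("cascade routing confines predictions to ancestor groups", {
  d <- make_clusters(15, seed = 3)
  cas <- fit_cascade(d$x, d$y, seed = 4)
  pred <- predict_cascade(cas, d$x)
  # separable clusters: perfect routing through all six nodes
  expect_equal(pred, d$y)
  # root forced to cancer: all predictions stay in the cancer subtree
  forced <- predict_cascade(cas$left, d$x)  # left subtree only
  expect_true(all(forced %in% c("G3", "G4", "G5")))
})

test_that("untrained cascades refuse to predict", {
  expect_error(predict_cascade(default_cascade(), data.frame(f1 = 1, f2 = 2)),
               "untrained")
})

test_that("OSC separates well-separated clusters; OVA partitions counts", {
  d <- make_clusters(24, seed = 5)
  hold <- make_clusters(12, seed = 6)
  osc <- fit_osc(d$x, d$y)
  expect_gt(mean(predict_osc(osc, hold$x) == hold$y), 0.95)
  ova <- fit_ova(d$x, d$y)
  dec <- predict_ova(ova, hold$x)
  for (cl in colnames(dec)) {
    cnt <- histocascade:::binary_counts(dec[, cl], hold$y == cl)
    expect_equal(sum(cnt), nrow(hold$x))
  }
  fused <- predict_ova(ova, hold$x, fuse = TRUE)$fused
  expect_gt(mean(fused == hold$y), 0.9)
})

test_that("an oracle feature drives every strategy to PPV 1", {
  d <- make_clusters(10, seed = 8)
  d$x$oracle <- as.numeric(factor(d$y))  # class id leaked as a feature
  cas <- fit_cascade(d$x, d$y)
  expect_equal(predict_cascade(cas, d$x), d$y)
  expect_equal(predict_osc(fit_osc(d$x, d$y), d$x), d$y)
  dec <- predict_ova(fit_ova(d$x, d$y), d$x)
  for (cl in colnames(dec))
    expect_equal(unname(histocascade:::binary_counts(dec[, cl], d$y == cl)[["fp"]]), 0L)
})

test_that("run_experiment aggregates 60 fold evaluations with conservation", {
  d <- make_clusters(9, seed = 9)
  rep <- run_experiment(d$x, d$y, n_trials = 2, n_folds = 3, seed = 7)
  expect_s3_class(rep, "strategy_report")
  expect_setequal(unique(rep$strategy), c("CAS", "OSC", "OVA"))
  expect_equal(nrow(rep), 3 * 7 * 3)  # strategies x classes x metrics
  expect_true(all(rep$mean >= 0 & rep$mean <= 1))
  expect_true(all(rep$stderr >= 0))
  expect_true(all(rep$n_evals + rep$n_undefined == 2 * 3))
  # class G3 reduced to 2 samples: fewer than the 3 folds
  keep <- c(1:2, 10:63)
  expect_error(run_experiment(d$x[keep, ], d$y[keep], n_trials = 1), "at least")
})

test_that("stratified folds keep every class in every training fold", {
  y <- rep(c("A", "B", "C"), c(6, 9, 12))
  fold <- histocascade:::stratified_folds(y, 3, seed = 1)
  for (f in 1:3) for (cl in c("A", "B", "C"))
    expect_gt(sum(y[fold != f] == cl), 0)
  expect_equal(as.numeric(table(fold[y == "B"])), c(3, 3, 3))
})

test_that("cascade YAML round trip preserves the structure", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    name = "root", left = list("A", "B"), right = list("C"),
    left_child = list(name = "ab", left = list("A"), right = list("B"))), tmp)
  cas <- read_cascade(tmp)
  expect_equal(cas$name, "root")
  expect_equal(cas$left$name, "ab")
  expect_setequal(histocascade:::cascade_leaves(cas), c("A", "B", "C"))
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "x", left = list("A"), right = list("A")), bad)
  expect_error(read_cascade(bad), "overlap")
})
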