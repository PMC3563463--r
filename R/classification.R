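# Multi-class strategies over entropy decision trees: the cascaded
# classifier (CAS) routes a sample through six independently trained binary
# nodes (cancer/non-cancer, then G3+G4 vs G5 and confounder vs normal, then
# singletons), one-shot classification (OSC) fits a single 7-leaf tree, and
# one-versus-all (OVA) evaluates seven independent target-vs-rest binary
# tasks. Performance is reported per class as ACC, PPV and NPV from
# TP/TN/FP/FN counts.

#' Default cascade structure
#'
#' The class-group hierarchy: \{G3,G4,G5\} vs \{BE,BS,AT,PIN\} at the root,
#' then \{G3,G4\} vs \{G5\} and \{AT,PIN\} vs \{BE,BS\}, then singleton
#' leaves — six binary divisions in total.
#'
#' @return A `cascade_node` tree (nested lists with `name`, `left_group`,
#'   `right_group`, and optional `left`/`right` children).
#' @export
default_cascade <- function() {
  node <- function(name, left_group, right_group, left = NULL, right = NULL) {
    structure(list(name = name, left_group = left_group,
                   right_group = right_group, left = left, right = right,
                   model = NULL),
              class = "cascade_node")
  }
  node("cancer_vs_noncancer",
       left_group = c("G3", "G4", "G5"),
       right_group = c("BE", "BS", "AT", "PIN"),
       left = node("g34_vs_g5", c("G3", "G4"), "G5",
                   left = node("g3_vs_g4", "G3", "G4")),
       right = node("confounder_vs_normal", c("AT", "PIN"), c("BE", "BS"),
                    left = node("at_vs_pin", "AT", "PIN"),
                    right = node("be_vs_bs", "BE", "BS")))
}

#' Read a cascade structure from YAML
#'
#' Each node is a mapping with `name`, `left`/`right` label lists, and
#' optional nested `left_child` / `right_child` nodes.
#'
#' @param path YAML file path.
#' @return A `cascade_node` tree.
#' @export
read_cascade <- function(path) {
  build <- function(x) {
    structure(list(name = x$name,
                   left_group = as.character(unlist(x$left)),
                   right_group = as.character(unlist(x$right)),
                   left = if (!is.null(x$left_child)) build(x$left_child),
                   right = if (!is.null(x$right_child)) build(x$right_child),
                   model = NULL),
              class = "cascade_node")
  }
  validate_cascade(build(yaml::read_yaml(path)))
}

cascade_leaves <- function(node) {
  if (is.null(node)) return(character(0))
  left <- if (is.null(node$left)) node$left_group else cascade_leaves(node$left)
  right <- if (is.null(node$right)) node$right_group else cascade_leaves(node$right)
  c(left, right)
}

count_nodes <- function(node) {
  if (is.null(node)) return(0L)
  1L + count_nodes(node$left) + count_nodes(node$right)
}

validate_cascade <- function(node) {
  check <- function(n) {
    if (is.null(n)) return(invisible())
    if (length(intersect(n$left_group, n$right_group)))
      stopf("cascade node '%s' has overlapping groups", n$name)
    if (is.null(n$left) && length(n$left_group) > 1L)
      stopf("cascade node '%s': left group has no child but is not a singleton", n$name)
    if (is.null(n$right) && length(n$right_group) > 1L)
      stopf("cascade node '%s': right group has no child but is not a singleton", n$name)
    check(n$left); check(n$right)
  }
  check(node)
  node
}

#' Train a binary entropy decision tree
#'
#' Relabels the samples into positive/negative groups and fits a CART-style
#' tree with entropy (information) splits, no cost-complexity pruning
#' (`cp = 0`) and a minimum leaf size of 2 — the open stand-in for the
#' C5.0 learner.
#'
#' @param features Data frame or matrix of feature columns.
#' @param labels Class labels per row.
#' @param positive_group,negative_group Character vectors of class labels.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   fixed for contract consistency).
#' @param ... Passed to [rpart::rpart.control()].
#' @return Fitted `rpart` object predicting `"pos"`/`"neg"`.
#' @export
train_binary_tree <- function(features, labels, positive_group,
                              negative_group, seed = 1L, ...) {
  sel <- labels %in% c(positive_group, negative_group)
  x <- as.data.frame(features)[sel, , drop = FALSE]
  y <- factor(ifelse(labels[sel] %in% positive_group, "pos", "neg"),
              levels = c("neg", "pos"))
  if (length(unique(y)) < 2L)
    stopf("training error: a class group is absent from the training data")
  d <- cbind(x, .y = y)
  with_seed(seed,
    rpart::rpart(.y ~ ., data = d, method = "class",
                 parms = list(split = "information"),
                 control = rpart::rpart.control(cp = 0, minbucket = 2,
                                                minsplit = 4, xval = 0, ...)))
}

#' Fit all six cascade node classifiers
#'
#' @param cascade A `cascade_node` tree (default [default_cascade()]).
#' @inheritParams train_binary_tree
#' @return The cascade with a trained model at every node.
#' @export
fit_cascade <- function(features, labels, cascade = default_cascade(),
                        seed = 1L) {
  fit <- function(node) {
    if (is.null(node)) return(NULL)
    node$model <- train_binary_tree(features, labels,
                                    node$left_group, node$right_group, seed)
    # exact [[ ]] indexing: `$left <- NULL` would drop the element and let
    # `$left` partial-match `left_group`
    if (!is.null(node[["left"]])) node[["left"]] <- fit(node[["left"]])
    if (!is.null(node[["right"]])) node[["right"]] <- fit(node[["right"]])
    node
  }
  fit(validate_cascade(cascade))
}

#' Predict class labels by routing through the cascade
#'
#' Each sample descends from the root: the node classifier chooses the left
#' or right class group, and the walk continues until a singleton leaf.
#'
#' @param cascade Trained cascade from [fit_cascade()].
#' @param features Data frame/matrix of samples to classify.
#' @return Character vector of predicted class labels.
#' @export
predict_cascade <- function(cascade, features) {
  x <- as.data.frame(features)
  out <- character(nrow(x))
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (is.null(node[["model"]])) stopf("cascade node '%s' is untrained", node$name)
    p <- predict(node[["model"]], x[idx, , drop = FALSE], type = "class")
    go_left <- p == "pos"
    if (is.null(node[["left"]])) out[idx[go_left]] <<- node$left_group
    else route(node[["left"]], idx[go_left])
    if (is.null(node[["right"]])) out[idx[!go_left]] <<- node$right_group
    else route(node[["right"]], idx[!go_left])
  }
  route(cascade, seq_len(nrow(x)))
  out
}

#' Fit / predict the one-shot (OSC) multi-class tree
#'
#' A single entropy decision tree whose leaves carry all seven class labels.
#'
#' @inheritParams train_binary_tree
#' @return Fitted `rpart` object.
#' @export
fit_osc <- function(features, labels, seed = 1L) {
  d <- cbind(as.data.frame(features), .y = factor(labels))
  with_seed(seed,
    rpart::rpart(.y ~ ., data = d, method = "class",
                 parms = list(split = "information"),
                 control = rpart::rpart.control(cp = 0, minbucket = 2,
                                                minsplit = 4, xval = 0)))
}

#' @rdname fit_osc
#' @param model Fitted OSC tree.
#' @export
predict_osc <- function(model, features) {
  as.character(predict(model, as.data.frame(features), type = "class"))
}

#' Fit the one-versus-all (OVA) classifiers
#'
#' One binary tree per class, target vs all remaining classes. Each task is
#' scored independently (the paper's convention: errors in one class do not
#' affect the others); [predict_ova()] returns the per-class binary
#' decisions, with an optional fused argmax label.
#'
#' @inheritParams train_binary_tree
#' @param classes Class labels to build targets for (default: all present).
#' @return Named list of fitted binary trees.
#' @export
fit_ova <- function(features, labels, classes = sort(unique(labels)),
                    seed = 1L) {
  setNames(lapply(classes, function(cl)
    train_binary_tree(features, labels, cl, setdiff(classes, cl), seed)),
    classes)
}

#' @rdname fit_ova
#' @param models List from [fit_ova()].
#' @param fuse Also return a fused 7-way label by maximum posterior.
#' @export
predict_ova <- function(models, features, fuse = FALSE) {
  x <- as.data.frame(features)
  dec <- vapply(models, function(m)
    predict(m, x, type = "class") == "pos", logical(nrow(x)))
  dec <- matrix(dec, nrow = nrow(x),
                dimnames = list(NULL, names(models)))
  if (!fuse) return(dec)
  prob <- vapply(models, function(m)
    predict(m, x, type = "prob")[, "pos"], numeric(nrow(x)))
  list(decisions = dec,
       fused = names(models)[max.col(matrix(prob, nrow = nrow(x)),
                                     ties.method = "first")])
}

#' Per-class performance from contingency counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`.
#' An undefined ratio (zero denominator) is reported as `NA` and excluded
#' from trial averaging.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Named numeric vector `c(ACC, PPV, NPV)`.
#' @export
evaluate_counts <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total == 0) stopf("all counts are zero")
  c(ACC = (tp + tn) / total,
    PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

binary_counts <- function(pred_pos, true_pos) {
  c(tp = sum(pred_pos & true_pos), tn = sum(!pred_pos & !true_pos),
    fp = sum(pred_pos & !true_pos), fn = sum(!pred_pos & true_pos))
}

stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      if (length(idx) < n_folds)
        stopf("class '%s' has fewer samples than folds", cl)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Compare the CAS, OSC and OVA strategies by repeated cross-validation
#'
#' Stratified `n_folds`-fold cross-validation repeated `n_trials` times
#' (folds reshuffled per trial with seed `seed + trial`). Every strategy is
#' scored per class from TP/TN/FP/FN on each test fold; per-class ACC, PPV
#' and NPV are averaged over the `n_trials * n_folds` fold evaluations with
#' their standard error (undefined metrics excluded and counted).
#'
#' @param features Data frame/matrix of feature columns (no label column).
#' @param labels Class label per row (at least `n_folds` samples per class).
#' @param strategies Subset of `c("CAS", "OSC", "OVA")`.
#' @param n_trials,n_folds Cross-validation design (defaults 20 and 3).
#' @param seed Master seed; trial `t` uses `seed + t`.
#' @param cascade Cascade structure for the CAS strategy.
#' @return A `strategy_report` data frame: strategy, class, metric, mean,
#'   stderr, n_evals, n_undefined.
#' @export
run_experiment <- function(features, labels,
                           strategies = c("CAS", "OSC", "OVA"),
                           n_trials = 20, n_folds = 3, seed = 1L,
                           cascade = default_cascade()) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  features <- as.data.frame(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (min(table(labels)) < n_folds)
    stopf("every class needs at least %d samples", n_folds)
  vals <- list()  # vals[[strategy]][[class]][[metric]] = numeric vector
  add <- function(strategy, class, v) {
    key <- paste(strategy, class, sep = ".")
    vals[[key]] <<- rbind(vals[[key]], v)
  }
  for (t in seq_len(n_trials)) {
    fold <- stratified_folds(labels, n_folds, seed = as.integer(seed) + t)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      xtr <- features[tr, , drop = FALSE]; ytr <- labels[tr]
      xte <- features[te, , drop = FALSE]; yte <- labels[te]
      fit_seed <- as.integer(seed) + t * 101L + f
      if ("CAS" %in% strategies) {
        pred <- predict_cascade(fit_cascade(xtr, ytr, cascade, fit_seed), xte)
        for (cl in classes)
          add("CAS", cl, do.call(evaluate_counts,
                                 as.list(binary_counts(pred == cl, yte == cl))))
      }
      if ("OSC" %in% strategies) {
        pred <- predict_osc(fit_osc(xtr, ytr, fit_seed), xte)
        for (cl in classes)
          add("OSC", cl, do.call(evaluate_counts,
                                 as.list(binary_counts(pred == cl, yte == cl))))
      }
      if ("OVA" %in% strategies) {
        dec <- predict_ova(fit_ova(xtr, ytr, classes, fit_seed), xte)
        for (cl in classes)
          add("OVA", cl, do.call(evaluate_counts,
                                 as.list(binary_counts(dec[, cl], yte == cl))))
      }
    }
  }
  rows <- list()
  for (key in names(vals)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    m <- vals[[key]]
    for (metric in colnames(m)) {
      v <- m[, metric]
      ok <- !is.na(v)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = parts[1], class = parts[2], metric = metric,
        mean = mean(v[ok]),
        stderr = if (sum(ok) > 1) sd(v[ok]) / sqrt(sum(ok)) else 0,
        n_evals = sum(ok), n_undefined = sum(!ok),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("strategy_report", "data.frame")
  report
}

#' Write a strategy report to CSV and JSON
#'
#' @param report A `strategy_report` from [run_experiment()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "report.csv"); js <- file.path(dir, "report.json")
  write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, js, dataframe = "rows", digits = NA)
  invisible(c(csv = csv, json = js))
}
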