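# AdaBoost feature ranking: discrete AdaBoost over single-feature decision
# stumps. At each iteration the stump (feature, threshold, polarity) with
# the lowest weighted error is selected, weighted by
# alpha = 0.5 ln((1 - eps)/eps), and the sample weights are re-focused on
# misclassified samples. Per-feature alphas are accumulated (a feature may
# be selected more than once) and summed across trials for the final
# ranking.

# Best stump for one feature under sample weights w; y in {-1, +1}.
# Returns list(err, threshold, polarity) with predictions
# sign(polarity * (x - threshold)) (ties at the threshold go positive).
best_stump <- function(x, y, w) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
  # candidate thresholds below the smallest value and between distinct values
  pos_w <- sum(ws[ys > 0])
  # err(t) for polarity +1 (predict +1 when x > t): start with t = -Inf
  # cumulative: moving threshold past sample i flips its prediction to -1
  cum <- cumsum(ifelse(ys > 0, ws, -ws))
  err_pos_inf <- sum(ws[ys < 0])               # t = -Inf, all predicted +1
  errs <- err_pos_inf + cum                    # threshold after sample i
  # only thresholds between distinct consecutive values are realizable
  distinct <- c(xs[-1] != xs[-length(xs)], TRUE)
  cand_err <- c(err_pos_inf, errs[distinct])
  cand_thr <- c(xs[1] - 1, c((xs[-length(xs)] + xs[-1]) / 2, xs[length(xs)] + 1)[distinct])
  best <- which.min(cand_err)
  worst <- which.max(cand_err)
  if (cand_err[best] <= 1 - cand_err[worst]) {
    list(err = cand_err[best], threshold = cand_thr[best], polarity = 1)
  } else {
    list(err = 1 - cand_err[worst], threshold = cand_thr[worst], polarity = -1)
  }
}

stump_predict <- function(x, threshold, polarity) {
  ifelse(polarity * (x - threshold) > 0, 1, -1)
}

#' Rank features by AdaBoost with decision stumps
#'
#' Runs `T` boosting iterations on a binary task. Iteration `t` selects the
#' single-feature threshold stump with the lowest weighted error `eps_t`
#' (both polarities searched), assigns it
#' `alpha_t = 0.5 ln((1 - eps_t)/eps_t)` (`eps` clamped to
#' `[1e-10, 0.5 - 1e-10]`), and updates the sample weights multiplicatively
#' with renormalization. Cumulative per-feature weights (summed over
#' repeated selections) are returned sorted non-increasingly, ties broken
#' lexicographically by feature name.
#'
#' @param features Matrix or data frame of numeric features.
#' @param labels Binary labels (two distinct values).
#' @param T Number of boosting iterations (default 10).
#' @param seed Integer seed (used only to break exact stump-error ties
#'   reproducibly; the algorithm is otherwise deterministic).
#' @return Data frame with columns `feature`, `weight`, `rank`, plus
#'   attribute `selections` (the per-iteration trace).
#' @export
adaboost_rank <- function(features, labels, T = 10, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  lev <- unique(labels)
  if (length(lev) != 2L) stopf("adaboost_rank needs exactly two classes (got %d)", length(lev))
  if (T < 1) stopf("T must be >= 1")
  y <- ifelse(labels == lev[1], 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  acc <- setNames(numeric(ncol(x)), colnames(x))
  trace <- vector("list", T)
  for (t in seq_len(T)) {
    stumps <- lapply(seq_len(ncol(x)), function(j) best_stump(x[, j], y, w))
    errs <- vapply(stumps, `[[`, 0, "err")
    j <- which.min(errs)  # first minimum: deterministic tie-break by column
    st <- stumps[[j]]
    eps <- min(max(st$err, 1e-10), 0.5 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    pred <- stump_predict(x[, j], st$threshold, st$polarity)
    w <- w * exp(-alpha * y * pred)
    w <- w / sum(w)
    acc[j] <- acc[j] + alpha
    trace[[t]] <- list(iteration = t, feature = colnames(x)[j],
                       error = st$err, alpha = alpha,
                       threshold = st$threshold, polarity = st$polarity,
                       weight_sum = sum(w))
  }
  sel <- acc[acc > 0]
  ord <- order(-sel, names(sel))
  out <- data.frame(feature = names(sel)[ord], weight = unname(sel[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "selections") <- trace
  out
}

#' Combine rankings across trials
#'
#' Sums cumulative per-feature weights over trials and re-ranks (ties broken
#' lexicographically by feature name).
#'
#' @param per_trial_rankings List of data frames from [adaboost_rank()].
#' @return Data frame with `feature`, `weight`, `rank`.
#' @export
rank_across_trials <- function(per_trial_rankings) {
  if (length(per_trial_rankings) == 0L) stopf("need at least one trial")
  all <- do.call(rbind, lapply(per_trial_rankings,
                               function(r) r[, c("feature", "weight")]))
  agg <- tapply(all$weight, all$feature, sum)
  ord <- order(-agg, names(agg))
  data.frame(feature = names(agg)[ord], weight = unname(agg[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
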