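#' Random-forest Gini importance of genes for a binary subtype
#'
#' Grows a classification forest and reports each gene's mean decrease in
#' Gini impurity (MDG) together with the cohort mean importance. A larger
#' MDG corresponds to a larger reduction of node impurity at splits on that
#' gene, i.e. greater importance for separating the two classes.
#'
#' @param X samples x genes numeric matrix (no missing values).
#' @param y binary labels (factor or coercible), both classes present.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed for the forest (mandatory: importance is stochastic).
#' @return data.frame `gene`, `mdg` plus attribute `mean_mdg`.
#' @export
gini_importance <- function(X, y, n_trees = 500, seed) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (anyNA(X)) stop("X must not contain missing values")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rf <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                   ntree = n_trees, importance = FALSE)
  mdg <- rf$importance[, "MeanDecreaseGini"]
  out <- data.frame(gene = names(mdg), mdg = unname(mdg),
                    stringsAsFactors = FALSE)
  attr(out, "mean_mdg") <- mean(out$mdg)
  out
}

#' Select genes with above-mean importance
#'
#' Keeps the genes whose mean decrease in Gini strictly exceeds the mean MDG
#' over all scored genes, preserving input order. With all importances
#' equal, nothing is selected.
#'
#' @param fi data.frame from [gini_importance()] (needs >= 2 rows).
#' @return Character vector of selected gene names.
#' @export
select_features <- function(fi) {
  if (nrow(fi) < 2) stop("feature selection needs >= 2 scored genes")
  mu <- attr(fi, "mean_mdg")
  if (is.null(mu)) mu <- mean(fi$mdg)
  fi$gene[fi$mdg > mu]
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half.
#'
#' @param scores numeric vector.
#' @param labels binary labels; the second factor level is the positive class.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must be binary")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate a forest classifier on selected genes
#'
#' Trains a random forest on the selected genes and evaluates it with
#' stratified k-fold cross-validation (default) or a stratified holdout.
#' Accuracy is reported with an exact Clopper-Pearson binomial 95% CI on
#' the pooled out-of-fold predictions; AUC uses the rank (Mann-Whitney)
#' formulation on the pooled out-of-fold class probabilities.
#'
#' @param X samples x genes numeric matrix.
#' @param y binary labels; second factor level is the positive class.
#' @param scheme `"k-fold"` (default) or `"holdout"`.
#' @param k number of folds (k-fold scheme).
#' @param holdout_frac test fraction (holdout scheme).
#' @param n_trees trees per forest.
#' @param seed RNG seed (mandatory).
#' @return List of class `classifier_report`: `selected` (genes used),
#'   `accuracy`, `accuracy_ci`, `auc`, `roc` (data.frame of fpr/tpr),
#'   `confusion`, `scores`, `labels`, `seed`, `scheme`.
#' @export
train_eval <- function(X, y, scheme = c("k-fold", "holdout"), k = 5,
                       holdout_frac = 0.3, n_trees = 500, seed) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("a seed is required")
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  X <- as.data.frame(X)
  n <- nrow(X)
  set.seed(seed)
  pos_level <- levels(y)[2]

  stratified_folds <- function(y, k) {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  }

  if (scheme == "k-fold") {
    fold <- stratified_folds(y, k)
    prob <- numeric(n); pred <- character(n)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2)
        stop("degenerate training split: a fold lost one class")
      rf <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                       ntree = n_trees)
      prob[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE],
                                  type = "prob")[, pos_level]
      pred[!tr] <- as.character(stats::predict(rf, X[!tr, , drop = FALSE]))
    }
    eval_idx <- seq_len(n)
  } else {
    test <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, max(1L, round(holdout_frac * length(idx))))
    }))
    tr <- setdiff(seq_len(n), test)
    if (nlevels(droplevels(y[tr])) < 2) stop("degenerate training split")
    rf <- randomForest::randomForest(x = X[tr, , drop = FALSE], y = y[tr],
                                     ntree = n_trees)
    prob <- pred <- rep(NA, n)
    prob[test] <- stats::predict(rf, X[test, , drop = FALSE],
                                 type = "prob")[, pos_level]
    pred[test] <- as.character(stats::predict(rf, X[test, , drop = FALSE]))
    eval_idx <- test
  }

  truth <- y[eval_idx]
  phat <- prob[eval_idx]
  yhat <- factor(pred[eval_idx], levels = levels(y))
  n_correct <- sum(yhat == truth)
  bt <- stats::binom.test(n_correct, length(eval_idx))
  structure(list(
    selected = colnames(X),
    accuracy = n_correct / length(eval_idx),
    accuracy_ci = unname(bt$conf.int),
    auc = rank_auc(phat, truth),
    roc = roc_points(phat, truth),
    confusion = table(predicted = yhat, truth = truth),
    scores = phat, labels = truth,
    seed = seed,
    scheme = if (scheme == "k-fold") sprintf("stratified %d-fold CV", k)
             else sprintf("stratified holdout (%.0f%%)", 100 * holdout_frac)
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s, genes: %s\n", x$scheme,
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f), AUC %.4f\n",
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2], x$auc))
  invisible(x)
}

#' ROC curve points
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels; second factor level is positive.
#' @return data.frame `threshold`, `fpr`, `tpr`, sorted by threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- factor(labels)
  pos <- labels == levels(labels)[2]
  thr <- c(-Inf, sort(unique(scores)), Inf)
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] > t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  )
}

#' Optimal cutpoint by the Youden index
#'
#' Scans the midpoints between consecutive distinct observed scores and
#' returns the cutpoint maximizing sensitivity + specificity - 1. The
#' direction is chosen from the data: positives may lie above (`">"`) or
#' below (`"<"`) the cutpoint, whichever yields the larger Youden index, so
#' flipping the class labels returns the same cutpoint with sensitivity and
#' specificity swapped. Ties are broken toward the lower cutpoint.
#'
#' @param scores numeric vector (must vary).
#' @param labels binary labels; second factor level is the positive class.
#' @return List with `value`, `criterion`, `direction`, `youden`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cutpoint <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must be binary")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("scores are constant; no cutpoint exists")
  pos <- labels == levels(labels)[2]
  candidates <- (u[-1] + u[-length(u)]) / 2
  # with positives above the cut: J_>(c); with positives below: J_<(c) = -J_>(c)
  j_gt <- vapply(candidates, function(cut) {
    mean(scores[pos] > cut) + mean(scores[!pos] <= cut) - 1
  }, numeric(1))
  best <- which.max(abs(j_gt))  # first (lowest) maximiser on ties
  cut <- candidates[best]
  direction <- if (j_gt[best] >= 0) ">" else "<"
  sens <- if (direction == ">") mean(scores[pos] > cut) else mean(scores[pos] <= cut)
  spec <- if (direction == ">") mean(scores[!pos] <= cut) else mean(scores[!pos] > cut)
  list(value = cut, criterion = "youden", direction = direction,
       youden = abs(j_gt[best]), sensitivity = sens, specificity = spec)
}
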