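make_separating_data <- function(n = 400, p = 10, effect = 3, seed = 7,
                                 informative = 1) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), length.out = n))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  X[y == "pos", seq_len(informative)] <-
    X[y == "pos", seq_len(informative)] + effect
  list(X = X, y = y)
}

test_that("a perfectly separating gene gets the top Gini importance", {
  d <- make_separating_data(n = 400, effect = 3, seed = 7)
  fi <- gini_importance(d$X, d$y, n_trees = 500, seed = 7)
  expect_equal(fi$gene[which.max(fi$mdg)], "g1")
  expect_true(all(fi$mdg >= 0))
  expect_equal(attr(fi, "mean_mdg"), mean(fi$mdg))
})

test_that("permuted labels yield no outstanding importance", {
  set.seed(19)
  X <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  y <- factor(rep(c("a", "b"), length.out = 150))
  flat <- vapply(1:50, function(i) {
    fi <- gini_importance(X, sample(y), n_trees = 200, seed = 1000 + i)
    max(fi$mdg) <= 3 * median(fi$mdg)
  }, logical(1))
  expect_gte(mean(flat), 0.95)
})

test_that("duplicated feature columns share their importance", {
  d <- make_separating_data(n = 400, effect = 3, seed = 21)
  X <- cbind(d$X, g1_copy = d$X[, "g1"])
  fi <- gini_importance(X, d$y, n_trees = 500, seed = 21)
  m1 <- fi$mdg[fi$gene == "g1"]
  m2 <- fi$mdg[fi$gene == "g1_copy"]
  expect_lt(abs(m1 - m2) / max(m1, m2), 0.25)
})

test_that("feature selection keeps genes strictly above the mean importance", {
  # the five-gene selection pattern: listed importances with cohort mean 177.8
  fi <- data.frame(
    gene = c("STAT1", "CDK1", "JUN", "IRF1", "ABL1",
             "AR", "PRKCB", "RELA", "SUMO1", "HDAC1"),
    mdg = c(283.5, 236.8, 228.5, 215.4, 180.7,
            150.0, 140.0, 130.0, 120.0, 93.1)
  )
  expect_equal(mean(fi$mdg), 177.8)
  expect_identical(select_features(fi),
                   c("STAT1", "CDK1", "JUN", "IRF1", "ABL1"))

  # all equal -> nothing strictly above the mean
  flat <- data.frame(gene = letters[1:4], mdg = rep(5, 4))
  expect_length(select_features(flat), 0)

  # one dominant importance -> exactly that gene
  dom <- data.frame(gene = c("a", "b", "c"), mdg = c(100, 1, 1))
  expect_identical(select_features(dom), "a")

  expect_error(select_features(data.frame(gene = "a", mdg = 1)), ">= 2")
})

test_that("rank AUC equals the brute-force pairwise probability", {
  set.seed(25)
  scores <- rnorm(60)
  labels <- factor(rep(c("neg", "pos"), each = 30))
  pos <- scores[labels == "pos"]; neg <- scores[labels == "neg"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(rank_auc(scores, labels), mean(pairs))

  # invariance under strictly monotone transforms of the scores
  expect_equal(rank_auc(exp(scores), labels), rank_auc(scores, labels))
  expect_equal(rank_auc(2 * scores + 1, labels), rank_auc(scores, labels))
})

test_that("cross-validated forest is perfect on separable classes, chance on noise", {
  d <- make_separating_data(n = 120, p = 4, effect = 8, seed = 29)
  rep_ <- train_eval(d$X, d$y, k = 5, n_trees = 200, seed = 29)
  expect_equal(rep_$accuracy, 1.0)
  expect_equal(rep_$auc, 1.0)
  expect_true(rep_$accuracy >= rep_$accuracy_ci[1] &&
                rep_$accuracy <= rep_$accuracy_ci[2])

  set.seed(11)
  Xn <- matrix(rnorm(600 * 5), 600, 5, dimnames = list(NULL, paste0("g", 1:5)))
  yn <- factor(rep(c("a", "b"), each = 300))
  rep_n <- train_eval(Xn, yn, k = 5, n_trees = 200, seed = 11)
  expect_gte(rep_n$auc, 0.42)
  expect_lte(rep_n$auc, 0.58)
})

test_that("the holdout scheme evaluates only held-out samples", {
  d <- make_separating_data(n = 200, p = 4, effect = 4, seed = 31)
  rep_ <- train_eval(d$X, d$y, scheme = "holdout", holdout_frac = 0.3,
                     n_trees = 200, seed = 31)
  expect_equal(length(rep_$scores), 60)
  expect_gte(rep_$auc, 0.9)
})

test_that("Youden cutpoint: separable groups, direction and tie handling", {
  cut <- youden_cutpoint(c(0.1, 0.2, 0.8, 0.9),
                         factor(c("n", "n", "p", "p"), levels = c("n", "p")))
  expect_equal(cut$value, 0.5)   # lowest midpoint achieving the maximum
  expect_equal(cut$direction, ">")
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  # flipped labels: same cutpoint, sensitivity and specificity swap roles
  flip <- youden_cutpoint(c(0.1, 0.2, 0.8, 0.9),
                          factor(c("p", "p", "n", "n"), levels = c("n", "p")))
  expect_equal(flip$value, cut$value)
  expect_equal(flip$direction, "<")
  expect_equal(flip$sensitivity, cut$specificity)
  expect_equal(flip$specificity, cut$sensitivity)

  expect_error(youden_cutpoint(rep(1, 4), factor(c("n", "n", "p", "p"))),
               "constant")
})

test_that("Youden cutpoint recovers the Gaussian intersection point", {
  set.seed(3)
  scores <- c(rnorm(2000, 0.3, 0.05), rnorm(2000, 0.6, 0.05))
  labels <- factor(rep(c("n", "p"), each = 2000), levels = c("n", "p"))
  cut <- youden_cutpoint(scores, labels)
  expect_equal(cut$value, 0.45, tolerance = 0.02 / 0.45)
  expect_equal(cut$direction, ">")
})

test_that("ROC points step from (1,1) to (0,0) and match pROC's AUC", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- rnorm(80)
  labels <- factor(rep(c("n", "p"), each = 40), levels = c("n", "p"))
  roc <- roc_points(scores, labels)
  expect_equal(roc$fpr[1], 1); expect_equal(roc$tpr[1], 1)
  expect_equal(roc$fpr[nrow(roc)], 0); expect_equal(roc$tpr[nrow(roc)], 0)
  expect_true(all(diff(roc$fpr) <= 0) && all(diff(roc$tpr) <= 0))
  ext <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rank_auc(scores, labels), ext)
})
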