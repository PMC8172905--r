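test_that("kernel CDF statistic is monotone within a gene and handles constants", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                9, 1, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "flat", "mix"), c("s1", "s2", "s3")))
  expect_message(z <- kernel_expression_statistic(m), "constant genes")
  expect_true(all(diff(z["up", ]) > 0))
  expect_equal(unname(z["flat", ]), rep(0.5, 3))
  expect_identical(order(z["mix", ]), order(m["mix", ]))
  expect_true(all(z > 0 & z < 1))
  expect_error(kernel_expression_statistic(m[, 1:2]), "at least 3 samples")
})

test_that("kernel CDF statistic is invariant to shifting one gene's row", {
  set.seed(4)
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  z1 <- kernel_expression_statistic(m)
  m2 <- m
  m2[7, ] <- m2[7, ] + 100
  expect_equal(kernel_expression_statistic(m2), z1)
})

test_that("a set loaded at the top of a sample's ranking maximises the walk score", {
  # the kernel statistic is per-gene, so a set can only occupy the top of
  # every sample's ranking by construction of the statistic matrix itself
  set.seed(8)
  p <- 60; n <- 20; k <- 5
  z_top <- matrix(runif(p * n, 0, 0.8), p, n,
                  dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  z_top[1:k, ] <- runif(k * n, 0.9, 1)
  top_set <- paste0("g", 1:k)
  es_top <- gsva_score(z_top, top_set)
  expect_true(all(es_top > 0))
  ok <- vapply(1:200, function(i) {
    rnd <- sample(rownames(z_top), k)
    all(gsva_score(z_top, rnd) <= es_top + 1e-12)
  }, logical(1))
  expect_true(all(ok))
  # the same genes placed at the bottom of the ranking score negative
  z_bot <- z_top
  z_bot[1:k, ] <- runif(k * n, 0, 0.05)
  expect_true(all(gsva_score(z_bot, top_set) < 0))
})

test_that("tau = 0 reduces to the unweighted KS statistic (independent oracle)", {
  set.seed(12)
  p <- 40; n <- 8
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  z <- kernel_expression_statistic(m)
  members <- paste0("g", c(3, 11, 19, 27, 35))
  in_set <- rownames(z) %in% members
  es <- gsva_score(z, members, tau = 0)
  oracle <- apply(z, 2, unweighted_ks_es, in_set = in_set)
  expect_equal(es, oracle)
})

test_that("a singleton set follows the two-level closed form", {
  set.seed(14)
  p <- 25; n <- 6
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  z <- kernel_expression_statistic(m)
  g <- "g10"
  es <- suppressWarnings(gsva_score(z, g))
  # with one member at position k of the descending ordering:
  # es = 1 - 2 (k - 1) / (p - 1)
  k_pos <- apply(z, 2, function(col) which(order(col, decreasing = TRUE) == which(rownames(z) == g)))
  expect_equal(unname(es), unname(1 - 2 * (k_pos - 1) / (p - 1)))
})

test_that("es ignores relabelling of genes outside the set", {
  set.seed(15)
  m <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  z <- kernel_expression_statistic(m)
  members <- paste0("g", 1:4)
  es1 <- gsva_score(z, members)
  z2 <- z
  rownames(z2)[5:30] <- paste0("h", 5:30)
  expect_equal(unname(gsva_score(z2, members)), unname(es1))
})

test_that("z-scoring centres the cohort and the call respects the threshold", {
  set.seed(20)
  es <- setNames(rnorm(100), paste0("s", 1:100))
  res <- z_and_call(es)
  expect_equal(mean(res$z), 0)
  expect_equal(sqrt(mean(res$z^2)), 1)   # population sd
  expect_identical(res$enriched, res$z > 0.35)

  # a single extreme sample is the only call in a large cohort
  es2 <- setNames(c(rnorm(99, sd = 0.05), 5), paste0("s", 1:100))
  res2 <- z_and_call(es2)
  expect_identical(which(res2$enriched), 100L)

  # fraction enriched is monotone non-increasing in the threshold
  fr <- vapply(c(-1, 0, 0.32, 0.35, 1, 2),
               function(t) mean(z_and_call(es, t)$enriched), numeric(1))
  expect_true(all(diff(fr) <= 0))
  # the published alternative threshold changes calls consistently
  expect_gte(sum(z_and_call(es, 0.32)$enriched), sum(z_and_call(es, 0.35)$enriched))

  expect_error(z_and_call(setNames(rep(1, 5), paste0("s", 1:5))), "zero variance")
  expect_error(z_and_call(setNames(1, "s1")), "at least 2")
})

test_that("absent set genes are dropped with a warning; empty intersections error", {
  set.seed(21)
  m <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:5)))
  z <- kernel_expression_statistic(m)
  expect_warning(gsva_score(z, c("g1", "g2", "ABSENT")), "dropped 1")
  expect_error(gsva_score(z, c("NOPE1", "NOPE2")), "no gene of the set")
})
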