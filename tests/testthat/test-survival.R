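test_that("product-limit estimator matches closed forms and a hand-computed table", {
  # three events, no censoring: survival steps 2/3, 1/3, 0
  km <- km_fit(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # all censored: flat at 1
  km2 <- km_fit(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)))
  expect_true(all(km2$surv == 1))
  expect_true(all(km2$n_event == 0))

  # mixed six-record set against the hand-computed product limit:
  # t=1 (6 at risk, 1 event)          -> 5/6
  # t=2 (censored, no step)           -> 5/6
  # t=3 (4 at risk, 1 event)          -> 5/6 * 3/4 = 5/8
  # t=4 (3 at risk, 1 event, 1 cens)  -> 5/8 * 2/3 = 5/12
  # t=5 (1 at risk, 1 event)          -> 0
  km3 <- km_fit(data.frame(time = c(1, 2, 3, 4, 4, 5),
                           event = c(1, 0, 1, 1, 0, 1)))
  expect_equal(km3$time, 1:5)
  expect_equal(km3$surv, c(5 / 6, 5 / 6, 5 / 8, 5 / 12, 0))
  expect_equal(km3$n_risk, c(6, 5, 4, 3, 1))

  expect_error(km_fit(data.frame(time = c(-1, 2), event = c(1, 1))),
               "negative")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(41)
  times <- round(rexp(40, 0.2), 2)
  km <- km_fit(data.frame(time = times, event = 1))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank: identical groups score zero, labels are exchangeable", {
  d <- data.frame(time = c(1, 2, 3, 1, 2, 3), event = 1,
                  group = rep(c("a", "b"), each = 3))
  out <- logrank_test(d)
  expect_equal(out$chisq, 0)
  expect_equal(out$p, 1)

  set.seed(43)
  d2 <- sim_survival(100, hr = 3, seed = 43)
  p1 <- logrank_test(d2)$p
  d2$group <- ifelse(d2$group == "high", "low", "high")
  expect_equal(logrank_test(d2)$p, p1)
})

test_that("log-rank p-values are uniform under label permutation", {
  d <- sim_survival(60, hr = 1, seed = 47)
  set.seed(47)
  ps <- replicate(500, {
    d$group <- sample(d$group)
    logrank_test(d)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("log-rank detects a strong separation", {
  set.seed(49)
  d <- data.frame(time = c(rexp(200, 1), rexp(200, 4)),
                  event = 1,
                  group = rep(c("slow", "fast"), each = 200))
  expect_lt(logrank_test(d)$p, 1e-6)
})

test_that("Cox estimate: CI coverage under the null and scale equivariance", {
  hits <- vapply(1:50, function(i) {
    d <- sim_survival(500, hr = 1, seed = 100 + i)
    ci <- cox_univariate(d, d$x)$ci
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  d <- sim_survival(300, hr = 2, seed = 51)
  f1 <- cox_univariate(d, d$x)
  f2 <- cox_univariate(d, 10 * d$x)
  expect_equal(f2$log_hr, f1$log_hr / 10, tolerance = 1e-6)
  expect_false(f1$flagged)
})

test_that("Cox recovers a true hazard ratio of 2", {
  d <- sim_survival(500, hr = 2, seed = 5)
  fit <- cox_univariate(d, d$x)
  expect_gte(fit$hr, 1.6)
  expect_lte(fit$hr, 2.5)
  expect_true(fit$ci[1] < fit$hr & fit$hr < fit$ci[2])
})

test_that("Cox agrees with the log-rank decision for moderate two-group effects", {
  agree <- vapply(1:40, function(i) {
    d <- sim_survival(200, hr = 1.8, seed = 200 + i)
    pc <- cox_univariate(d, d$x)$p
    pl <- logrank_test(d)$p
    (pc < 0.05) == (pl < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("survival cutpoint recovers a planted change-point at 0.46", {
  set.seed(9)
  n <- 600
  scores <- runif(n, -0.2, 1.1)
  hazard <- ifelse(scores < 0.46, 0.3, 0.1)   # hazard x3 below the cut
  d <- data.frame(time = rexp(n, hazard), event = 1)
  cut <- surv_cutpoint(d, scores)
  expect_equal(cut$value, 0.46, tolerance = 0.05 / 0.46)
  expect_gte(cut$n_low, 60)
  expect_gte(cut$n_high, 60)
})

test_that("independent scores give weak optimal splits that do not replicate", {
  notsig <- vapply(1:20, function(i) {
    set.seed(300 + i)
    n <- 150
    d <- data.frame(time = rexp(n, 0.1), event = 1)
    scores <- runif(n)
    cut <- surv_cutpoint(d, scores)
    # apply the selected cutpoint to an independent replicate
    d2 <- data.frame(time = rexp(n, 0.1), event = 1,
                     group = ifelse(runif(n) > cut$value, "high", "low"))
    logrank_test(d2)$p >= 0.05
  }, logical(1))
  expect_gte(mean(notsig), 0.9)
})

test_that("minprop = 0.5 with even n admits only the median split", {
  set.seed(53)
  n <- 20
  scores <- seq_len(n) / n
  d <- data.frame(time = rexp(n, 0.2), event = 1)
  cut <- surv_cutpoint(d, scores, minprop = 0.5)
  expect_equal(cut$n_low, 10)
  expect_equal(cut$n_high, 10)
  expect_equal(cut$value, mean(scores[10:11]))
})
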