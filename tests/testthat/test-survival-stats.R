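test_that("presence stratification is boundary-inclusive at 15%", {
  expect_equal(stratify_presence(c(0.15, 0.149, 0)),
               c("present", "absent", "absent"))
})

test_that("tertile stratification reproduces the expected group shapes", {
  t9 <- stratify_tertiles(1:9)
  expect_equal(which(t9 == "low"), 1:3)
  expect_equal(which(t9 == "mid"), 4:6)
  expect_equal(which(t9 == "high"), 7:9)
  t89 <- stratify_tertiles(seq_len(89))
  expect_equal(as.vector(table(t89)), c(30L, 30L, 29L))
  # boundary ties go to the lower group
  tt <- stratify_tertiles(c(1, 1, 1, 1, 5, 9, 9, 9, 9))
  expect_equal(sum(tt == "low"), 4)
  expect_error(stratify_tertiles(rep(2, 5)), "degenerate")
})

test_that("KM product-limit matches hand computation", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(km$surv, c(3 / 4, 1 / 2))
  allc <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(allc), 0) # S stays at 1 throughout
  single <- km_curve(5, 1)
  expect_equal(single$surv, 0)
  expect_error(km_curve(-1, 1), "negative")
})

test_that("log-rank matches survival::survdiff on random data", {
  skip_if_not_installed("survival")
  set.seed(61)
  for (r in 1:50) {
    n <- sample(20:60, 1)
    times <- rexp(n, 0.05) + 0.01
    events <- rbinom(n, 1, 0.7)
    groups <- sample(1:sample(2:3, 1), n, replace = TRUE)
    if (length(unique(groups)) < 2 || sum(events) == 0) next
    ours <- logrank_test(times, events, groups)
    ref <- survival::survdiff(survival::Surv(times, events) ~ groups)
    expect_equal(ours$statistic, ref$chisq, tolerance = 1e-6)
    expect_equal(unname(ours$observed), unname(ref$obs), tolerance = 1e-9)
    expect_equal(unname(ours$expected), unname(ref$exp), tolerance = 1e-9)
  }
})

test_that("KM matches survival::survfit on random data", {
  skip_if_not_installed("survival")
  set.seed(62)
  for (r in 1:10) {
    n <- 40
    times <- round(rexp(n, 0.05), 2) + 0.01
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) next
    km <- km_curve(times, events)
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    ref_surv <- summary(sf, times = km$time)$surv
    expect_equal(km$surv, ref_surv, tolerance = 1e-9)
  }
})

test_that("log-rank trivia: identical groups, unit weights, errors", {
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 0, 1, 1, 0, 1)
  dup <- logrank_test(rep(times, 2), rep(events, 2),
                      rep(c("a", "b"), each = 6))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1)
  g <- rep(c("a", "b"), 3)
  unw <- logrank_test(times, events, g)
  w1 <- logrank_test(times, events, g, weights = rep(1, 6))
  expect_equal(unw$statistic, w1$statistic, tolerance = 1e-12)
  expect_equal(w1$weighting, "weighted")
  expect_error(logrank_test(times, events, rep("a", 6)), "two groups")
})

test_that("log-rank p agrees with a permutation-null oracle on a toy", {
  times <- c(2, 4, 5, 7, 9, 12)
  events <- c(1, 1, 0, 1, 1, 0)
  groups <- c("a", "a", "a", "b", "b", "b")
  obs <- logrank_test(times, events, groups)$statistic
  # exact permutation null over all 20 label assignments
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    logrank_test(times, events, g)$statistic
  })
  p_perm <- mean(stats >= obs - 1e-12)
  p_asym <- logrank_test(times, events, groups)$p
  expect_lt(abs(p_perm - p_asym), 0.25) # small-n agreement in kind
  expect_gte(p_perm, 0)
})

test_that("IPW weights follow the stratum cross-tab reciprocals", {
  # single stratum: all weights 1 after normalisation
  w1 <- ipw_weights(rep(c("a", "b"), 5), rep("s1", 10))
  expect_equal(w1, rep(1, 10))
  # 0.8/0.2 stratum: raw weights 1.25 and 5 before normalisation
  groups <- c(rep("a", 8), rep("b", 2))
  tab <- table(rep("s1", 10), groups)
  raw <- 1 / (tab / sum(tab))[1, ]
  expect_equal(unname(raw), c(1.25, 5))
  # group absent from a stratum: smoothed, finite
  g2 <- c("a", "a", "b", "a", "a")
  s2 <- c("x", "x", "x", "y", "y")
  w2 <- ipw_weights(g2, s2)
  expect_true(all(is.finite(w2) & w2 > 0))
})

test_that("IPW with uninformative covariates equals the unweighted test", {
  set.seed(67)
  times <- rexp(40, 0.05); events <- rbinom(40, 1, 0.8)
  groups <- rep(c("a", "b"), 20)
  w <- ipw_weights(groups, rep("only", 40))
  a <- logrank_test(times, events, groups)
  b <- logrank_test(times, events, groups, weights = w)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the two-sided binomial test equals full enumeration", {
  expect_equal(binomial_enrichment_test(10, 10, 1), 1)
  k <- 8; n <- 10; p0 <- 0.16
  probs <- dbinom(0:n, n, p0)
  oracle <- sum(probs[probs <= dbinom(k, n, p0) * (1 + 1e-7)])
  expect_equal(binomial_enrichment_test(k, n, p0), oracle,
               tolerance = 1e-12)
  expect_gte(binomial_enrichment_test(16, 100, 0.16), 0.9)
  expect_error(binomial_enrichment_test(11, 10, 0.5), "invalid")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 6, 5, 9)
  res <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(2, 5)), "constant")
})
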