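test_that("pooled median is the plain KM median of the concatenated sample", {
  expect_equal(pooled_median(toy_groups()), 2)
  g2 <- grouped_surv(list(surv_sample(c(1, 2), c(1, 1), "A"),
                          surv_sample(c(3, 4), c(1, 1), "B")))
  expect_equal(pooled_median(g2), 2)
  # pooling identical copies leaves the median unchanged
  s <- surv_sample(c(2, 5, 7, 11), c(1, 1, 0, 1))
  g3 <- grouped_surv(list(s, s, s))
  expect_equal(pooled_median(g3), km_median(km_fit(s)))
  # undefined pooled median is a typed degenerate-data error
  gc <- grouped_surv(list(surv_sample(1:3, c(0, 0, 0), "A"),
                          surv_sample(1:3, c(0, 0, 0), "B")))
  expect_error(pooled_median(gc), class = "survmedian_degenerate")
  expect_error(pooled_median(gc), regexp = "pooled median")
})

test_that("group survival probability at the pooled median (eta)", {
  expect_equal(eta(surv_sample(1:4, rep(1, 4)), 2), 0.5)
  expect_equal(eta(surv_sample(1:4, rep(1, 4)), 0.2), 1)
  expect_equal(eta(surv_sample(1:3, c(0, 1, 1)), 2), 0.5)
})

test_that("composite variance combines Greenwood and the local correction", {
  # theta_i = 2, closest other uncensored time 1 (tie vs 3 broken low):
  # 0.0625 + (0.5 - 0.75)^2 / 2
  expect_equal(variance_eta(surv_sample(1:4, rep(1, 4)), 2), 0.09375)
  # full hand computation on three events: 2/27 + 1/18 = 7/54
  expect_equal(variance_eta(surv_sample(1:3, rep(1, 3)), 2), 7 / 54,
               tolerance = 1e-12)
  # a single uncensored time: correction term unavailable, Greenwood only
  s <- surv_sample(c(2, 3, 5), c(1, 0, 0))
  curve <- km_fit(s)
  expect_equal(variance_eta(s, 4), greenwood_variance_at(curve, 4))
  # all censored: both components vanish -> degenerate variance error
  expect_error(variance_eta(surv_sample(1:3, c(0, 0, 0)), 2),
               class = "survmedian_degenerate")
})

test_that("statistic is zero (p = 1) when all groups are identical", {
  res <- surv_median_test(toy_groups())
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  expect_equal(unname(res$parameter), 1L)
  expect_equal(unname(res$etas), c(0.5, 0.5))
  expect_equal(unname(res$variances), c(0.09375, 0.09375))
})

test_that("Cochran form matches hand arithmetic and the chi-square tail", {
  # eta = (0.6, 0.4), sigma^2 = (0.01, 0.01): C = 2, df = 1
  C <- survmedian:::cochran_stat(c(0.6, 0.4), c(0.01, 0.01))
  expect_equal(C, 2)
  expect_equal(pchisq(C, 1, lower.tail = FALSE), 0.15729921,
               tolerance = 1e-7)
})

test_that("degrees of freedom are K - 1 and weights normalize", {
  set.seed(7)
  g <- grouped_surv(lapply(1:4, function(i) rand_sample(30, 0.1, i)))
  res <- surv_median_test(g)
  expect_equal(unname(res$parameter), 3L)
  h <- res$weights / sum(res$weights)
  expect_equal(sum(h), 1)
  expect_true(all(res$variances > 0))
  expect_gte(unname(res$statistic), 0)
})

test_that("Cochran form equals the computational identity on fuzzed inputs", {
  set.seed(88)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    etas <- runif(K)
    vars <- runif(K, 0.001, 0.2)
    w <- 1 / vars
    C1 <- survmedian:::cochran_stat(etas, vars)
    C2 <- sum(w * etas^2) - sum(w * etas)^2 / sum(w)
    expect_equal(C1, C2, tolerance = 1e-10)
    expect_gte(C1, -1e-12)
    if (max(etas) - min(etas) > 1e-8) expect_gt(C1, 0)
  }
  # C = 0 iff all etas equal
  expect_equal(survmedian:::cochran_stat(rep(0.37, 4), runif(4, 0.01, 1)), 0)
})

test_that("shrinking any single variance never decreases the statistic", {
  set.seed(99)
  for (i in 1:30) {
    K <- sample(2:5, 1)
    etas <- runif(K)
    vars <- runif(K, 0.01, 0.2)
    C0 <- survmedian:::cochran_stat(etas, vars)
    j <- sample(K, 1)
    vars2 <- vars
    vars2[j] <- vars[j] * runif(1, 0.1, 0.999)
    expect_gte(survmedian:::cochran_stat(etas, vars2), C0 - 1e-12)
  }
})

test_that("composite statistic is invariant under positive affine time transforms", {
  set.seed(55)
  for (i in 1:10) {
    g <- grouped_surv(lapply(1:3, function(i) rand_sample(25, 0.2, i)))
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    g2 <- grouped_surv(lapply(g, function(s)
      surv_sample(a * s$times + b, s$events, s$label)))
    r1 <- surv_median_test(g); r2 <- surv_median_test(g2)
    expect_equal(unname(r2$statistic), unname(r1$statistic),
                 tolerance = 1e-10)
    expect_equal(r2$p.value, r1$p.value, tolerance = 1e-10)
  }
})

test_that("greenwood variant is invariant under any increasing transform", {
  set.seed(56)
  trans <- function(t) t^3 + 2 * t
  for (i in 1:10) {
    g <- grouped_surv(lapply(1:3, function(i) rand_sample(25, 0.2, i)))
    g2 <- grouped_surv(lapply(g, function(s)
      surv_sample(trans(s$times), s$events, s$label)))
    r1 <- greenwood_median_test(g); r2 <- greenwood_median_test(g2)
    expect_equal(unname(r2$statistic), unname(r1$statistic),
                 tolerance = 1e-10)
  }
})

test_that("greenwood-only statistic dominates the composite statistic", {
  set.seed(57)
  for (i in 1:20) {
    g <- grouped_surv(lapply(1:4, function(i) rand_sample(20, 0.25, i)))
    rc <- surv_median_test(g)
    rg <- greenwood_median_test(g)
    expect_true(all(rg$variances <= rc$variances + 1e-15))
    expect_gte(unname(rg$statistic), unname(rc$statistic) - 1e-12)
    expect_lte(rg$p.value, rc$p.value + 1e-12)
  }
})

test_that("degenerate groups raise typed errors identifying the group", {
  g <- grouped_surv(list(surv_sample(1:4, rep(1, 4), "ok"),
                         surv_sample(1:4, rep(0, 4), "allcens")))
  expect_error(surv_median_test(g), class = "survmedian_degenerate")
  expect_error(surv_median_test(g), regexp = "allcens")
  expect_error(grouped_surv(list(surv_sample(1:4, rep(1, 4)))),
               class = "survmedian_invalid_input")
})

test_that("correction_dropped flags groups without a usable correction term", {
  g <- grouped_surv(list(
    surv_sample(c(2, 3, 5), c(1, 0, 0), "one_event"),
    surv_sample(1:6, rep(1, 6), "full")))
  res <- surv_median_test(g)
  expect_true(res$correction_dropped["one_event"])
  expect_false(res$correction_dropped["full"])
})
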