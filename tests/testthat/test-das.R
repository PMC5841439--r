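test_that("pooled PSI is the depth-weighted inclusion fraction", {
  expect_equal(estimate_psi(c(30, 15), c(10, 5)), 0.75)
  expect_equal(estimate_psi(c(12, 7), c(0, 0)), 1.0)
  expect_error(estimate_psi(c(0, 0), c(0, 0)), "undefined")
})

test_that("pooled PSI is nearly unbiased under the generating model", {
  set.seed(101)
  p <- 0.4; theta <- 20
  est <- replicate(500, {
    tot <- rep(200L, 3L)
    k <- rbinom(3L, tot, rbeta(3L, p * theta, (1 - p) * theta))
    estimate_psi(k, tot - k)
  })
  expect_lt(abs(mean(est) - p), 0.02)
})

test_that("beta-binomial fits satisfy symmetry and one-sample identities", {
  # identical groups: group estimates equal the pooled estimate
  f <- fit_beta_binomial(c(10, 12, 10, 12), c(5, 6, 5, 6),
                         groups = c("a", "a", "b", "b"))
  expect_equal(unname(f$p["a"]), unname(f$p["b"]), tolerance = 1e-4)
  f0 <- fit_beta_binomial(c(10, 12, 10, 12), c(5, 6, 5, 6), model = "null")
  expect_equal(unname(f$p["a"]), unname(f0$p), tolerance = 1e-4)
  # one sample per group: MLE matches the binomial proportion
  f1 <- fit_beta_binomial(c(8, 2), c(2, 8), groups = c("a", "b"))
  expect_equal(unname(f1$p), c(0.8, 0.2), tolerance = 1e-3)
})

test_that("free fits match a dense grid-search oracle", {
  # the spec's frozen two-group instance, then random small instances
  k <- c(9, 8, 3, 2); n <- rep(10, 4); g <- c("a", "a", "b", "b")
  fit <- fit_beta_binomial(k, n - k, groups = g)
  oracle <- grid_oracle_loglik(k, n, g)
  expect_lt(abs(fit$logLik - oracle$logLik), 1e-3)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:30, 4L, replace = TRUE)
    k <- rbinom(4L, n, runif(1, 0.2, 0.8))
    fit <- fit_beta_binomial(k, n - k, model = "null")
    oracle <- grid_oracle_loglik(k, n)
    expect_gte(fit$logLik, oracle$logLik - 1e-3)
    expect_lt(abs(fit$logLik - oracle$logLik), 1e-3)
  }
})

test_that("the LRT behaves at the null case and has df = groups - 1", {
  r <- lrt_event(c(10, 11, 10, 11), c(10, 9, 10, 9),
                 c("a", "a", "b", "b"))
  expect_lt(r$stat, 1e-4)
  expect_gt(r$p_value, 0.99)
  expect_equal(r$df, 1L)
  # alternative likelihood never below the null
  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:200, 6L, replace = TRUE)
    k <- rbinom(6L, n, runif(1, 0.1, 0.9))
    r <- lrt_event(k, n - k, rep(c("a", "b"), each = 3L), theta_fix = 10)
    expect_gte(r$fit_alt$logLik, r$fit_null$logLik - 1e-8)
    expect_gte(r$stat, 0)
  }
})

test_that("label swap negates dPSI and preserves the p-value", {
  cfg <- sim_config(seed = 31)
  ev <- data.frame(event_id = sprintf("E%03d", 1:40))
  sim <- simulate_counts(cfg, ev)
  d1 <- das_test(sim$counts, "case", "control")
  d2 <- das_test(sim$counts, "control", "case")
  m <- match(d1$event_id, d2$event_id)
  expect_equal(d1$delta_psi, -d2$delta_psi[m])
  expect_equal(d1$p, d2$p[m], tolerance = 1e-6)
})

test_that("BH adjustment reproduces the hand-applied step-up formula", {
  # ordered p (0.01, 0.02, 0.03, 0.04), m = 4: q_i = min_j>=i p_j * 4/j = 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(5)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q <= 1) && all(q >= p))
  # NA entries excluded from m and returned as NA
  q2 <- bh_adjust(c(0.01, NA, 0.02, 0.03, 0.04))
  expect_true(is.na(q2[2]))
  expect_equal(q2[-2], rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance needs both strict thresholds", {
  rec <- structure(
    data.frame(event_id = c("e1", "e2", "e3", "e4"),
               delta_psi = c(0.04, 0.30, 0.30, 0.05),
               q = c(0.001, 0.04, 0.2, 0.01)),
    class = c("das", "data.frame"))
  out <- call_das(rec, 0.05, 0.05)
  expect_equal(out$records$significant, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("the coverage filter excludes thin events and reports them", {
  counts <- data.frame(
    event_id = rep(c("e1", "e2"), each = 4L),
    sample_id = rep(c("c1", "c2", "n1", "n2"), 2L),
    group = rep(c("case", "case", "control", "control"), 2L),
    n_inc = c(20L, 25L, 10L, 12L, 1L, 2L, 0L, 1L),
    n_exc = c(10L, 15L, 20L, 18L, 1L, 0L, 1L, 0L))
  d <- das_test(counts, "case", "control", min_coverage = 10)
  expect_equal(d$event_id, "e1")
  expect_equal(attr(d, "n_low_coverage"), 1L)
})
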