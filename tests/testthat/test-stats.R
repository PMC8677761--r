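test_that("equal-probability goodness of fit matches the closed form", {
  g <- chisq_gof(c(51, 26, 22, 21))
  expect_equal(g$statistic, 20.067, tolerance = 5e-4)
  expect_equal(g$df, 3)
  expect_equal(chisq_gof(c(30, 30))$statistic, 0)
  expect_equal(chisq_gof(c(10, 0))$statistic, 10)   # (5^2 + 5^2)/5
  expect_error(chisq_gof(c(5)), "at least 2")
  expect_error(chisq_gof(c(0, 0)), "positive")
  expect_error(chisq_gof(c(3, 4), expected_probs = c(0.6, 0.6)), "sum to 1")
  expect_error(chisq_gof(c(3, 4), expected_probs = c(1, 0)), "zero expected")
})

test_that("the continuity-corrected 2x2 statistic matches its construction", {
  x <- chisq_2x2_corrected(matrix(c(162, 1, 648, 809), 2))
  expect_equal(x$statistic, 174.63, tolerance = 5e-3)
  expect_equal(chisq_2x2_corrected(matrix(50, 2, 2))$statistic, 0)
  expect_error(chisq_2x2_corrected(matrix(c(0, 0, 3, 4), 2)), "zero margin")

  # the correction never exceeds the uncorrected statistic
  withr::with_seed(101, {
    for (i in 1:50) {
      m <- matrix(rpois(4, 20) + 1, 2)
      corr <- chisq_2x2_corrected(m)$statistic
      uncorr <- suppressWarnings(
        stats::chisq.test(m, correct = FALSE)$statistic)
      expect_lte(corr, unname(uncorr) + 1e-12)
    }
  })
})

test_that("Fisher's exact test agrees with exhaustive enumeration", {
  expect_equal(fisher_exact(matrix(c(77, 73, 43, 47), 2)), 0.689,
               tolerance = 5e-4)
  expect_equal(fisher_exact(matrix(c(0, 0, 10, 10), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2)),
               fisher_oracle(3, 1, 1, 3), tolerance = 1e-12)
  withr::with_seed(111, {
    for (i in 1:200) {
      m <- matrix(rpois(4, 6), 2)
      expect_equal(fisher_exact(m),
                   fisher_oracle(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), ">= 0")
})

test_that("BH adjustment is a capped, monotone, idempotent step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(121, {
    p <- runif(30)
  })
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # closed-form step-up oracle: running minimum of p_(i) * m / i from the
  # largest p down, capped at 1
  o_sorted <- order(p)
  m <- length(p)
  oracle <- pmin(rev(cummin(rev(sort(p) * m / seq_len(m)))), 1)
  expect_equal(adj[o_sorted], oracle)
  # sorted outputs are monotone non-decreasing
  expect_true(all(diff(adj[o_sorted]) >= 0))
  o <- sample(30)
  expect_equal(bh_adjust(p[o]), adj[o])               # order-equivariant
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the run report assembles per-period tables and scenario counts", {
  cfg <- mixed_config(seed = 17, n_events = 2,
                      participation = c(PRE = 0.8, PEAK = 0.8,
                                        WANING = 0.8, LATE = 0.8))
  sim <- simulate_swarm(cfg, duration_s = 120)
  an <- analyze_swarm(sim)
  inter <- sampled_interactions(an, times = c(30, 60, 90))
  rep <- build_report(an, interactions = inter)
  expect_s3_class(rep, "swarm_report")
  # four period rows per sex
  ps <- rep$tables$period_summary
  expect_equal(nrow(ps), 8L)
  expect_equal(sort(unique(ps$sex)), c("female", "male"))
  # conservation: scenario counts sum to the number of sampled points
  expect_equal(sum(rep$tables$scenario_counts$n), 3L)

  # event-free run: every sampled point falls in the > 50 Hz scenario
  sim0 <- simulate_swarm(mixed_config(seed = 18, n_events = 0),
                         duration_s = 60)
  an0 <- analyze_swarm(sim0)
  inter0 <- sampled_interactions(an0, times = c(20, 40))
  expect_true(all(inter0$scenario == "NONE_GT50"))

  out <- withr::local_tempdir()
  build_report(an, interactions = inter, out_dir = out)
  expect_true(file.exists(file.path(out, "period_summary.csv")))
  expect_true(file.exists(file.path(out, "summary.txt")))
})

test_that("pairwise post-hoc comparisons are BH-adjusted", {
  ph <- posthoc_pairwise_gof(c(a = 51, b = 26, c = 22, d = 21))
  expect_equal(nrow(ph), 6L)
  expect_true(all(ph$p_adj >= ph$p_raw))
  # the dominant scenario differs from each of the others
  expect_true(all(ph$p_adj[ph$a == "a"] < 0.05))
})
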