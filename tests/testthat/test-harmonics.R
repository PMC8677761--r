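test_that("harmonic overtones and ratio differences follow the arithmetic", {
  expect_equal(harmonic(900, 2), 1800)
  expect_equal(harmonic(600, 3), 1800)
  expect_equal(harmonic(550, 1), 550)
  expect_error(harmonic(-5, 2), "positive")
  expect_error(harmonic(550, 0), "integer")

  expect_equal(ratio_difference(900, 600, "M2F3"), 0)
  expect_equal(ratio_difference(850, 550, "M2F3"), 50)
  expect_equal(ratio_difference(850, 550, "M1F2"), 250)
})

test_that("difference categories are half-open and partition [0, Inf)", {
  expect_equal(as.character(classify_difference(3)), "LT5")
  expect_equal(as.character(classify_difference(15)), "LT20")
  expect_equal(as.character(classify_difference(50)), "GT50")   # boundary
  expect_equal(as.character(classify_difference(5)), "LT10")    # strict < 5
  expect_error(classify_difference(-1), "non-negative")

  withr::with_seed(77, {
    d <- c(runif(500, 0, 120), 0, 5, 10, 20, 50, 4.999, 49.999)
  })
  cats <- classify_difference(d)
  expect_false(anyNA(cats))                 # total on [0, Inf)
  # membership agrees with direct interval arithmetic
  expected <- ifelse(d < 5, "LT5", ifelse(d < 10, "LT10",
               ifelse(d < 20, "LT20", ifelse(d < 50, "LT50", "GT50"))))
  expect_equal(as.character(cats), expected)
})

test_that("best_outcome minimises over the four ratios", {
  expect_equal(as.character(best_outcome(900, 600)$ratio), "M2F3")
  expect_equal(best_outcome(900, 600)$diff, 0)
  expect_equal(as.character(best_outcome(900, 600)$category), "LT5")

  bo <- best_outcome(903.47, 600)
  expect_equal(as.character(bo$ratio), "M2F3")
  expect_equal(bo$diff, 6.94, tolerance = 1e-9)
  expect_equal(as.character(bo$category), "LT10")

  expect_equal(as.character(best_outcome(850, 425)$ratio), "M1F2")
  expect_equal(best_outcome(850, 425)$diff, 0)

  # minimality against every individual ratio
  withr::with_seed(78, {
    m <- runif(200, 700, 1100); f <- runif(200, 400, 700)
  })
  bos <- best_outcome(m, f)
  for (r in harmonic_ratios()$ratio)
    expect_true(all(bos$diff <= ratio_difference(m, f, r) + 1e-12))
  # homogeneity: scaling both fundamentals scales every difference
  k <- 1.37
  for (r in harmonic_ratios()$ratio)
    expect_equal(ratio_difference(k * m, k * f, r),
                 k * ratio_difference(m, f, r), tolerance = 1e-9)
})

test_that("mixed scenarios depend only on GT50-vs-not of each phase", {
  expect_equal(as.character(scenario_mixed("LT5", "LT20")), "S1_BOTH")
  expect_equal(as.character(scenario_mixed("LT50", "GT50")),
               "S2_EARLY_ONLY")
  expect_equal(as.character(scenario_mixed("GT50", "LT10")),
               "S3_LATE_ONLY")
  expect_equal(as.character(scenario_mixed("GT50", "GT50")), "NONE_GT50")
  # absent interactions count as > 50 Hz
  expect_equal(as.character(scenario_mixed(NA, NA)), "NONE_GT50")
  # invariance under category refinement
  fine <- c("LT5", "LT10", "LT20", "LT50")
  for (a in fine) for (b in fine)
    expect_equal(as.character(scenario_mixed(a, b)), "S1_BOTH")
})

test_that("playback outcomes form the 4-bit achievement lattice", {
  all_gt <- scenario_playback("GT50", "GT50", "GT50", "GT50")
  expect_equal(all_gt$signature, "0000")

  modal <- scenario_playback("LT5", "GT50", "GT50", "LT5")
  expect_equal(modal$signature, "1001")

  # boundary sensitivity: 850/550 before and 900/600 during at M2:F3 both
  # give exactly 50 Hz, which the strict bins place in GT50
  b <- classify_difference(ratio_difference(850, 550, "M2F3"))
  d <- classify_difference(ratio_difference(900, 600, "M2F3") + 50)
  expect_equal(scenario_playback(b, "GT50", "GT50", d)$signature, "0000")
})

test_that("phase outcomes collapse three points by minimum difference", {
  # mixed mode: any ratio may serve at each point
  po <- phase_outcome(c(900, 880, 910), c(600, 590, 605))
  expect_equal(po$diff, 0)
  expect_equal(as.character(po$category), "LT5")
  # playback mode: fixed ratio against the played tone
  pp <- phase_outcome(c(903, 905, 901), female_hz = 600)
  expect_equal(pp$diff, 2)
  expect_equal(as.character(pp$category), "LT5")
  # no usable points: > 50 Hz outcome
  expect_equal(as.character(phase_outcome(c(NA, NA, NA))$category), "GT50")
})
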