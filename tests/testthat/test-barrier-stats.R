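test_that("two-tailed exact test matches the enumeration oracle and fisher.test", {
  # the perfect-cosegregation geometry: only the observed table is as extreme
  expect_equal(exact_test_2x2(6, 0, 0, 9), 1 / 5005)
  expect_equal(exact_test_2x2(5, 5, 5, 5), 1)
  # fully crossed table: both extreme tables counted
  expect_equal(exact_test_2x2(0, 50, 50, 0), 2 / choose(100, 50))

  # exhaustive against the brute-force oracle for all tables with N <= 16
  worst <- 0
  for (N in 1:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      worst <- max(worst, abs(exact_test_2x2(a, b, cc, d) -
                                oracle_fisher_p(a, b, cc, d)))
    }
  }
  expect_lt(worst, 1e-12)

  # random larger tables against stats::fisher.test as an independent check
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 10, 40), 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(exact_test_2x2(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-7)
  }

  expect_error(exact_test_2x2(0, 0, 0, 0), "empty")
  expect_error(exact_test_2x2(1.5, 2, 3, 4), "integers")
})

test_that("p-values under a simulated null are conservative (stochastically >= uniform)", {
  set.seed(7)
  p <- replicate(500, {
    y1 <- rbinom(1, 60, 0.4)
    y2 <- rbinom(1, 60, 0.4)
    exact_test_2x2(y1, 60 - y1, y2, 60 - y2)
  })
  expect_true(all(p > 0 & p <= 1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 500))
  }
})

test_that("barrier strength is the test/control odds ratio with zero-cell correction", {
  expect_equal(as.numeric(barrier_strength(c(40, 60), c(40, 60))), 1)
  expect_equal(as.numeric(barrier_strength(c(99, 1), c(50, 50))), 99)
  bs0 <- barrier_strength(c(100, 0), c(50, 50))
  expect_equal(as.numeric(bs0), (100.5 / 0.5) / (50.5 / 50.5))
  expect_true(attr(bs0, "corrected"))
  expect_false(attr(barrier_strength(c(10, 10), c(10, 10)), "corrected"))

  # scale invariance and transposition symmetry
  expect_equal(as.numeric(barrier_strength(c(90, 10), c(30, 70))),
               as.numeric(barrier_strength(c(900, 100), c(300, 700))))
  set.seed(3)
  for (i in 1:20) {
    t <- rpois(2, 30) + 1
    ctl <- rpois(2, 30) + 1
    expect_equal(as.numeric(barrier_strength(t, ctl)),
                 1 / as.numeric(barrier_strength(ctl, t)))
  }
  expect_error(barrier_strength(c(0, 0), c(0, 0)), "empty")
})

test_that("ear classification uses the printed tier thresholds and direction", {
  # geometry reproducing the (6,0,0,9) p-value: 2e-4 falls in the partial tier
  cls <- classify_ear(c(6, 0), c(0, 9))
  expect_equal(cls$p_value, 1 / 5005)
  expect_equal(cls$tier, "partial")
  # overwhelming rejection of tcb1 pollen: strong
  expect_equal(classify_ear(c(200, 0), c(80, 120))$tier, "strong")
  # identical ears: none
  expect_equal(classify_ear(c(50, 50), c(50, 50))$tier, "none")
  # significance in the wrong direction (more tcb1 kernels on test) is never a barrier
  expect_equal(classify_ear(c(0, 200), c(120, 80))$tier, "none")

  # tier boundaries are exactly 1e-4 and 1e-2: scan tables across the range
  set.seed(9)
  for (i in 1:200) {
    t <- c(rbinom(1, 80, runif(1, 0.3, 1)), 0)
    t[2] <- 80 - t[1]
    ctl <- c(rbinom(1, 80, 0.4), 0)
    ctl[2] <- 80 - ctl[1]
    cls <- classify_ear(t, ctl)
    dir <- t[2] / 80 < ctl[2] / 80
    want <- if (dir && cls$p_value < 1e-4) "strong"
            else if (dir && cls$p_value < 0.01) "partial" else "none"
    expect_identical(cls$tier, want)
  }
})

test_that("cosegregation counts concordance and scores the exact table", {
  marker <- rep(c(TRUE, FALSE), c(6, 9))
  pheno <- rep(c(TRUE, FALSE), c(6, 9))
  res <- cosegregation(marker, pheno)
  expect_equal(res$n_concordant, 15)
  expect_equal(res$n_discordant, 0)
  expect_equal(res$p_value, 1 / 5005)

  # fully discordant lists still partition the sample
  res2 <- cosegregation(marker, !pheno)
  expect_equal(res2$n_concordant, 0)
  expect_equal(res2$n_discordant, 15)
  expect_equal(res2$p_value, oracle_fisher_p(0, 6, 9, 0))

  set.seed(12)
  for (i in 1:20) {
    m <- runif(15) < 0.5
    ph <- runif(15) < 0.5
    r <- cosegregation(m, ph)
    expect_equal(r$n_concordant + r$n_discordant, 15)
  }
  expect_error(cosegregation(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("screen outlier flagging uses the Bonferroni-corrected binomial tail", {
  ears <- data.frame(
    ear_id = c("hit", "null", "expectation"),
    n_sugary = c(11L, 1L, 9L),
    n_total = c(45L, 45L, 300L)
  )
  out <- flag_screen_outliers(ears, null_fraction = 0.03, alpha = 0.05)
  # 11/45 sugary against a 3% null is astronomically unlikely
  expect_true(out$flagged[1])
  expect_lt(out$p_value[1], 1e-7)
  # an ear at (or near) the null expectation is never flagged
  expect_false(out$flagged[2])
  expect_false(out$flagged[3])
  expect_equal(out$p_value,
               pbinom(ears$n_sugary - 1, ears$n_total, 0.03, lower.tail = FALSE))
  expect_error(flag_screen_outliers(ears, null_fraction = 0), "\\(0, 1\\)")
})

test_that("screen flagging finds planted knockouts with controlled false flags", {
  scr <- simulate_open_pollinated_screen(
    n_plants = 2000, kernels_per_ear = 300, r = 0.06, leak = 0,
    knockout_fraction = 0.01, seed = 77
  )
  out <- flag_screen_outliers(scr, null_fraction = 0.03, alpha = 0.05)
  ko <- !out$barrier
  expect_gt(sum(ko), 0)
  expect_equal(mean(out$flagged[ko]), 1)          # sensitivity ~ 1
  expect_lte(sum(out$flagged[!ko]), 1)            # family-wise false flags
})
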