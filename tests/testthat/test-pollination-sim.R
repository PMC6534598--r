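test_that("mixed pollination is deterministic under a fixed seed", {
  args <- list(plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(),
               donor_tester_yellow(), n_kernels = 500L, seed = 99L)
  a <- do.call(simulate_mixed_pollination, args)
  b <- do.call(simulate_mixed_pollination, args)
  expect_identical(a, b)
  c <- do.call(simulate_mixed_pollination, modifyList(args, list(seed = 100L)))
  expect_false(identical(a$n_purple, c$n_purple))
})

test_that("neutral ear reproduces the 60:40 acceptance bias on an equal mix", {
  ears <- simulate_mixed_pollination(
    plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(),
    donor_tester_yellow(), mix_weight = 0.5, n_kernels = 10000L,
    leak = 0.03, seed = 2024L
  )
  neutral <- ears[ears$receiver_class == "neutral", ]
  frac_tcb1 <- neutral$n_purple / neutral$n_total
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(frac_tcb1 - 0.6), 3 * se)
})

test_that("a barrier female with leak 0 excludes all tcb1-donor kernels", {
  ears <- simulate_mixed_pollination(
    plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(),
    donor_tester_yellow(), n_kernels = 2000L, leak = 0, seed = 5L
  )
  expect_equal(ears$n_purple[ears$receiver_class == "test"], 0)
  expect_equal(ears$n_purple[ears$receiver_class == "tester"], 0)
  expect_gt(ears$n_purple[ears$receiver_class == "neutral"], 0)
  expect_equal(ears$n_total, rep(2000L, 3))
  expect_equal(ears$n_purple + ears$n_yellow, ears$n_total)

  # 50:50 {tcb1}/{Tcb1-m} mix on a barrier female at leak 0: every kernel
  # is Tcb1-m-sired, matching the closed-form acceptance rule
  male_only <- plant_genotype("Tcb1-m", "Tcb1-m")
  ears_m <- simulate_mixed_pollination(
    plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(), male_only,
    n_kernels = 2000L, leak = 0, seed = 6L
  )
  test_m <- ears_m[ears_m$receiver_class == "test", ]
  expect_equal(test_m$n_sired_donorB, 2000L)
  expect_equal(test_m$n_purple, 0L)
})

test_that("donors with identical colour markers are an unscoreable design", {
  expect_error(
    simulate_mixed_pollination(plant_genotype("Tcb1-s", "Tcb1-s"),
                               donor_tcb1_purple(), donor_tcb1_purple()),
    "unscoreable"
  )
})

test_that("a knockout female is indistinguishable from the neutral ear", {
  # with no barrier on the test ear, test vs neutral p-values are null-like
  set.seed(31)
  seeds <- sample.int(1e6, 300)
  p <- vapply(seeds, function(s) {
    ears <- simulate_mixed_pollination(
      plant_genotype("Tcb1-m", "tcb1"), donor_tcb1_purple(),
      donor_tester_yellow(), n_kernels = 150L, leak = 0.03, seed = s
    )
    test <- ears[ears$receiver_class == "test", ]
    neutral <- ears[ears$receiver_class == "neutral", ]
    exact_test_2x2(test$n_yellow, test$n_purple,
                   neutral$n_yellow, neutral$n_purple)
  }, numeric(1))
  for (alpha in c(0.05, 0.1)) {
    expect_lte(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 300))
  }
  expect_gt(mean(p), 0.4)  # discrete and conservative, mean well above 0
})

test_that("simulated sired fractions converge to the closed-form expectations", {
  # Tcb1-s test ear with leak: expected tcb1-sired fraction is
  # bias_t*leak / (bias_t*leak + bias_s) on an equal mix
  leak <- 0.1
  expected <- 0.6 * leak / (0.6 * leak + 0.4)
  ears <- simulate_mixed_pollination(
    plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(),
    donor_tester_yellow(), n_kernels = 20000L, leak = leak, seed = 8L
  )
  test <- ears[ears$receiver_class == "test", ]
  obs <- test$n_purple / test$n_total
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("open-pollinated screen matches the r/2 and 1/4 expectations", {
  scr <- simulate_open_pollinated_screen(
    n_plants = 300, kernels_per_ear = 400, r = 0.06, leak = 0, seed = 17
  )
  expect_true(all(scr$barrier))
  n <- 300 * 400
  se <- sqrt(0.03 * 0.97 / n)
  expect_lt(abs(mean(scr$sugary_fraction) - 0.03), 3 * se)

  ko <- simulate_open_pollinated_screen(
    n_plants = 300, kernels_per_ear = 400, r = 0.06, leak = 0,
    knockout_fraction = 1, seed = 18
  )
  se_ko <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(ko$sugary_fraction) - 0.25), 3 * se_ko)

  # a knockout ear's sugary count behaves like Binomial(45, 1/4)
  sector <- simulate_open_pollinated_screen(
    n_plants = 2000, kernels_per_ear = 45, r = 0.06, leak = 0,
    knockout_fraction = 1, seed = 19
  )
  expect_lt(abs(mean(sector$n_sugary) - 45 * 0.25),
            3 * sqrt(45 * 0.25 * 0.75 / 2000))
  expect_lt(abs(var(sector$n_sugary) - 45 * 0.25 * 0.75),
            0.15 * 45 * 0.25 * 0.75)
})

test_that("reversion experiment plants ground truth and recovers it", {
  res <- simulate_reversion_experiment(n_females = 36, reversion_prob = 0.18,
                                       n_kernels = 300, seed = 41)
  expect_equal(nrow(res), 36L)
  # reverted females carry above-threshold expression and a partial leak
  expect_true(all(res$expression[res$reverted] >= 0.1))
  expect_true(all(res$leak[res$reverted] >= 0.05 &
                    res$leak[res$reverted] <= 0.35))
  # classification recovers the planted reversion status
  detected <- res$tier != "none"
  expect_equal(mean(detected[res$reverted]), 1)
  expect_gte(mean(!detected[!res$reverted]), 0.9)

  # edge cases: no reversion -> no barrier calls beyond type-I error;
  # certain reversion with strong barrier -> all strong
  none <- simulate_reversion_experiment(n_females = 24, reversion_prob = 0,
                                        n_kernels = 300, seed = 42)
  expect_lte(sum(none$tier != "none"), 1)
  all_strong <- simulate_reversion_experiment(
    n_females = 12, reversion_prob = 1, partial_leak_band = c(0, 0),
    n_kernels = 300, seed = 43
  )
  expect_true(all(all_strong$tier == "strong"))
})

test_that("binomial expectation of reverted females matches the draw", {
  # ~18% of 36 females -> about 6.5 expected; check the seeded draw is
  # within 3 binomial SD and the pipeline count agrees with truth
  res <- simulate_reversion_experiment(n_females = 36, reversion_prob = 0.18,
                                       seed = 4)
  expect_lt(abs(sum(res$reverted) - 36 * 0.18),
            3 * sqrt(36 * 0.18 * 0.82) + 1)
  expect_equal(sum(res$tier != "none"), sum(res$reverted))
})

test_that("leak and bias are recovered from simulated neutral + test ears", {
  true_leak <- 0.05
  ears <- simulate_mixed_pollination(
    plant_genotype("Tcb1-s", "Tcb1-s"), donor_tcb1_purple(),
    donor_tester_yellow(), n_kernels = 20000L, leak = true_leak, seed = 60L
  )
  test <- ears[ears$receiver_class == "test", ]
  neutral <- ears[ears$receiver_class == "neutral", ]
  bias_hat <- estimate_acceptance_bias(neutral$n_purple, neutral$n_yellow)
  expect_lt(abs(bias_hat[["tcb1"]] - 0.6), 3 * sqrt(0.6 * 0.4 / 20000))
  leak_hat <- estimate_leak(test, neutral)
  # binomial error on the test-ear tcb1-sired odds dominates; at n = 20,000
  # the estimate sits well within 0.01 of the generating leak
  expect_lt(abs(leak_hat - true_leak), 0.01)
})
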