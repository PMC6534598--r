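test_that("relative expression is 2^(delta Ct) and shift-invariant", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(19, 20), 2)
  expect_equal(relative_expression(20 - log2(400), 20), 400)
  # additive shifts common to both genes cancel exactly
  set.seed(6)
  for (i in 1:20) {
    tgt <- runif(1, 15, 30)
    ref <- runif(1, 15, 30)
    shift <- runif(1, -5, 5)
    expect_equal(relative_expression(tgt + shift, ref + shift),
                 relative_expression(tgt, ref))
  }
  expect_error(relative_expression(NA, 20), "finite")
  expect_error(relative_expression(Inf, 20), "finite")
})

test_that("line summaries average technical then biological replicates", {
  ct <- ct_table_from_bio_levels("lineA", c(1, 2, 3))
  s <- summarize_expression(ct)
  expect_equal(s$relative_expression, 2)
  expect_equal(s$sem, sd(1:3) / sqrt(3), tolerance = 1e-10)
  expect_equal(s$n_biological, 3L)

  # identical biological means give SEM 0
  s0 <- summarize_expression(ct_table_from_bio_levels("lineB", c(2, 2, 2)))
  expect_equal(s0$sem, 0)

  # technical-first averaging: outlier technical reps within a biological
  # replicate are averaged on the Ct scale before the fold change is taken
  ct2 <- ct_table_from_bio_levels("lineC", c(4, 4))
  ct2$ct[ct2$gene == "target" & ct2$biological_rep == 1] <- c(17, 18, 19)
  s2 <- summarize_expression(ct2)
  expect_equal(s2$relative_expression, mean(c(2^(20 - 18), 4)))

  # missing reference rows are an error
  bad <- ct[ct$gene == "target", ]
  expect_error(summarize_expression(bad), "reference")
  one_bio <- ct[ct$biological_rep == 1, ]
  expect_error(summarize_expression(one_bio), "biological")
})

test_that("SEM estimator is unbiased over many simulated lines", {
  set.seed(123)
  sigma <- 0.3
  n_lines <- 400
  sems <- vapply(seq_len(n_lines), function(i) {
    bio <- 2^rnorm(3, 0, sigma)  # log-normal biological variation
    summarize_expression(ct_table_from_bio_levels(paste0("L", i), bio))$sem
  }, numeric(1))
  # mean SEM should approximate sd(bio)/sqrt(3) of the generating law
  truth <- mean(replicate(2000, sd(2^rnorm(3, 0, sigma)) / sqrt(3)))
  expect_lt(abs(mean(sems) - truth) / truth, 0.1)
})

test_that("planted fold changes are recovered from synthetic Ct tables", {
  tmp <- tempfile("qpcrfix")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  fx <- make_qpcr_fixture(tmp, seed = 3, sigma = 0)
  s <- summarize_expression(fx$data)
  truth <- unlist(fx$truth$expression)
  expect_equal(s$relative_expression[match(names(truth), s$line_name)],
               unname(truth), tolerance = 1e-12)
  # the 400-fold revertant-vs-standard contrast is exact at sigma = 0
  rel <- s$relative_expression[s$line_name == "mop1_revertant"] /
    s$relative_expression[s$line_name == "W22"]
  expect_equal(rel, 400)

  # with noise, recovery is within noise-propagated bounds
  fx2 <- make_qpcr_fixture(tmp, seed = 4, sigma = 0.2)
  s2 <- summarize_expression(fx2$data)
  for (ln in names(truth)) {
    est <- s2$relative_expression[s2$line_name == ln]
    expect_lt(abs(log2(est) - log2(truth[[ln]])), 4 * 0.2)
  }
})

test_that("expression-barrier association detects monotone and threshold structure", {
  lines <- sprintf("L%d", 1:6)
  summaries <- data.frame(line_name = lines,
                          relative_expression = c(0.01, 0.05, 0.2, 0.4, 0.8, 1.5))
  # perfectly monotone barrier strengths
  mono <- data.frame(line_name = lines,
                     barrier_strength = c(1.0, 1.1, 3, 8, 20, 33))
  res <- expression_barrier_association(summaries, mono)
  expect_equal(res$rho, 1)
  expect_true(res$threshold_consistent)
  # reversed pairing
  rev <- data.frame(line_name = lines,
                    barrier_strength = rev(mono$barrier_strength))
  expect_equal(expression_barrier_association(summaries, rev)$rho, -1)
  # a below-threshold line with a large barrier strength breaks the
  # threshold signature
  broken <- mono
  broken$barrier_strength[1] <- 10
  expect_false(expression_barrier_association(summaries, broken)$threshold_consistent)
  # unpaired lines are an error
  expect_error(
    expression_barrier_association(summaries, mono[-1, ]), "unpaired"
  )
})

test_that("threshold model data yield a positive association with correct flags", {
  set.seed(55)
  n <- 20
  expr <- 10^runif(n, -2, 0.5)
  bs <- ifelse(expr < 0.1, exp(rnorm(n, 0, 0.1)),
               1 + expr * exp(rnorm(n, 2, 0.3)))
  summaries <- data.frame(line_name = sprintf("P%02d", 1:n),
                          relative_expression = expr)
  strengths <- data.frame(line_name = sprintf("P%02d", 1:n),
                          barrier_strength = bs)
  res <- expression_barrier_association(summaries, strengths)
  expect_gt(res$rho, 0.5)
  expect_true(res$threshold_consistent)
  expect_identical(res$table$below_threshold, expr < 0.1)
})
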