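test_that("proportion perturbation flips entries by +/-e and renormalizes", {
  p <- c(0.5, 0.5)
  expect_identical(perturb_proportions(p, 0), p)
  allowed <- list(c(0.5, 0.5),
                  c(0.55, 0.45) / 1.0,
                  c(0.45, 0.55) / 1.0)
  set.seed(13)
  for (i in 1:20) {
    q <- perturb_proportions(p, 0.1)
    expect_true(any(vapply(allowed, function(a) isTRUE(all.equal(q, a)),
                           logical(1))))
    expect_equal(sum(q), 1, tolerance = 1e-12)
  }
  set.seed(13)
  for (i in 1:10) {
    q <- perturb_proportions(default_base_proportions(), 0.2)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_true(all(q > 0))
  }
  expect_error(perturb_proportions(p, 1), "< 1")
  expect_error(perturb_proportions(p, -0.1), ">= 0")
})

test_that("replicate simulation draws the requested cells from one system", {
  ann <- simulate_replicate_pair(e = 0.05, seed = 3)
  ct <- build_count_table(ann)
  expect_equal(unname(colSums(ct)), c(5000, 3000))

  # e = 0: empirical proportions near the base within 3 multinomial SEs
  base <- default_base_proportions()
  ann0 <- simulate_replicate_pair(base, e = 0, n1 = 5000, n2 = 3000,
                                  seed = 17)
  pr <- to_proportions(build_count_table(ann0))
  for (cond in colnames(pr)) {
    n <- sum(build_count_table(ann0)[, cond])
    se <- sqrt(base * (1 - base) / n)
    expect_true(all(abs(pr[, cond] - base) <= 3.5 * se))
  }
  expect_identical(simulate_replicate_pair(e = 0.1, seed = 5),
                   simulate_replicate_pair(e = 0.1, seed = 5))
})

test_that("condition simulation plants exactly six changes at 4000/6000 cells", {
  sim <- simulate_control_condition(e = 0.1, seed = 21)
  expect_identical(sum(sim$truth), 6L)
  ct <- build_count_table(sim$annotations)
  expect_equal(unname(colSums(ct)[c("control", "condition")]),
               c(4000, 6000))

  # unit factors reduce to the replicate design: no changed populations
  same <- apply_change_factors(default_base_proportions(),
                               default_changed_populations()$populations,
                               rep(1, 6))
  expect_equal(same, default_base_proportions())
})

test_that("per-cluster Fisher p-values match hypergeometric enumeration", {
  counts <- matrix(c(6L, 4L, 2L, 8L), nrow = 2,
                   dimnames = list(c("X", "Y"), c("A", "B")))
  p <- fisher_per_cluster(counts, "A", "B")
  expect_equal(unname(p["X"]), 31372 / 184756, tolerance = 1e-10)
  expect_equal(unname(p["X"]), oracle_fisher_2x2(6, 4, 2, 8),
               tolerance = 1e-10)

  balanced <- matrix(c(5L, 5L, 5L, 5L), nrow = 2,
                     dimnames = list(c("X", "Y"), c("A", "B")))
  expect_equal(unname(fisher_per_cluster(balanced, "A", "B")), c(1, 1))

  swapped <- counts[, c("B", "A")]
  expect_equal(fisher_per_cluster(counts, "A", "B"),
               fisher_per_cluster(swapped, "B", "A"))
})

test_that("classification metrics count TP/FP/TN/FN correctly", {
  truth <- c(rep(TRUE, 6), rep(FALSE, 4))
  calls <- truth
  calls[7] <- TRUE
  m <- benchmark_metrics(calls, truth)
  expect_equal(unname(m), c(1, 0.75, 6 / 7))

  none <- benchmark_metrics(rep(FALSE, 10), truth)
  expect_equal(unname(none), c(0, 1, 1))

  perfect <- benchmark_metrics(truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1))

  expect_true(is.na(benchmark_metrics(rep(FALSE, 4),
                                      rep(FALSE, 4))["sensitivity"]))
  expect_error(benchmark_metrics(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("benchmark sweep emits a tidy table and is seed-reproducible", {
  res <- run_benchmark("replicate", error_rates = c(0.05, 0.1), reps = 3,
                       n1 = 400, n2 = 300, t = 100, seed = 33)
  expect_identical(names(res), c("design", "error_rate", "method",
                                 "sensitivity", "specificity", "precision"))
  expect_identical(nrow(res), 4L)
  expect_true(all(is.na(res$sensitivity)))
  expect_true(all(res$specificity >= 0 & res$specificity <= 1))
  expect_identical(res, run_benchmark("replicate",
                                      error_rates = c(0.05, 0.1), reps = 3,
                                      n1 = 400, n2 = 300, t = 100,
                                      seed = 33))

  cond <- run_benchmark("condition", error_rates = 0.05, reps = 2,
                        n1 = 400, n2 = 600, t = 100, seed = 34)
  expect_true(all(!is.na(cond$sensitivity)))
})
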