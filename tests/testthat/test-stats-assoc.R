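test_that("the proportion CI reproduces every printed interval at 3 dp", {
  cases <- list(list(57, 93, 0.512, 0.714),
                list(19, 93, 0.121, 0.288),
                list(16, 93, 0.094, 0.250),
                list(4, 93, 0.001, 0.085),
                list(2, 93, -0.009, 0.052))
  for (cs in cases) {
    ci <- proportion_ci(cs[[1]], cs[[2]])
    expect_equal(round_half_up(ci$lower, 3), cs[[3]])
    expect_equal(round_half_up(ci$upper, 3), cs[[4]])
  }
  ## degenerate zero-variance case is flagged, bounds collapse to the point
  ci0 <- proportion_ci(0, 93)
  expect_true(ci0$degenerate)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))
  expect_error(proportion_ci(3, 1), "n >= 2")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(-0.00853, 3), -0.009)
  expect_equal(round_half_up(0.0085, 3), 0.009)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
})

test_that("chi-square matches the hand formula and its invariances", {
  flat <- chi_square_test(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  m <- matrix(c(50, 7, 21, 15), 2)
  res <- chi_square_test(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - E)^2 / E))   # 10.55016...
  expect_equal(res$df, 1)
  expect_equal(res$expected, E)
  ## transposition invariance
  expect_equal(chi_square_test(t(m))$statistic, res$statistic)
  ## df for 2x3; p monotone decreasing in the statistic at fixed df
  expect_equal(chi_square_test(matrix(c(5, 6, 7, 8, 9, 10), 2))$df, 2)
  p_small <- 1 - stats::pchisq(1, df = 1)
  p_large <- 1 - stats::pchisq(5, df = 1)
  expect_true(p_large < p_small)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "marginals")
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 11, 9, 3), 2))$p_value,
               fisher_oracle(1, 9, 11, 3), tolerance = 1e-12)
  ## frozen from the enumeration oracle
  expect_equal(fisher_exact(matrix(c(1, 11, 9, 3), 2))$p_value,
               0.002759456, tolerance = 1e-6)
  ## extreme table: p is the point probability, at most 1
  ext <- fisher_exact(matrix(c(0, 5, 5, 0), 2))
  expect_equal(ext$p_value, fisher_oracle(0, 5, 5, 0), tolerance = 1e-12)
  expect_lte(ext$p_value, 1)
  ## zero row fixes the table completely
  expect_equal(fisher_exact(matrix(c(0, 3, 0, 4), nrow = 2,
                                   byrow = TRUE))$p_value, 1)
})

test_that("Fisher agrees with the enumeration oracle across random margins", {
  set.seed(5)
  for (i in 1:300) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    m <- matrix(c(a, c_, b, d), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p_value, fisher_oracle(a, b, c_, d),
                 tolerance = 1e-9)
  }
})

test_that("rank-sum test: exact enumeration, ties, and degenerate input", {
  expect_equal(suppressMessages(wilcoxon_rank_sum(c(1, 1, 1), c(1, 1)))$p_value, 1)
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)    # 2 of the 20 rank splits are as extreme
  expect_equal(res$p_value, ranksum_oracle(c(1, 2, 3), c(4, 5, 6)))
  ## the normal approximation tracks the exact law at n = 10
  x <- (1:10) + 0.1; y <- (4:13) + 0.25
  exact <- wilcoxon_rank_sum(x, y)
  approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = FALSE)$p.value)
  expect_true(exact$exact)
  expect_lt(abs(exact$p_value - approx), 0.01)
  ## ties force the tie-corrected approximation
  tied <- wilcoxon_rank_sum(c(1, 2, 2, 3), c(2, 4, 5))
  expect_false(tied$exact)
  expect_true(tied$U >= 0 && tied$U <= 12)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("the selection rule switches between chi-square and Fisher", {
  big <- matrix(c(30, 25, 20, 18), 2)        # all expected >= 5
  expect_equal(select_test(big)$test_used, "chi_square")
  small <- matrix(c(1, 3, 2, 1), 2)          # expected cells below 5
  expect_equal(select_test(small)$test_used, "fisher_exact")
})

test_that("the association screen reproduces the fixture's screen margins", {
  fx <- generate_study_fixture()
  scr <- association_screen(fx)
  egfr_sex <- scr$results[["EGFR.sex"]]$observed
  expect_equal(unname(rowSums(egfr_sex)), c(71, 22))   # female / male lesions
  expect_equal(sum(egfr_sex[, "mutated"]), 57)
  expect_true(all(c("EGFR.ctr_bin", "TP53.stage_group", "KRAS.pack_years_bin")
                  %in% names(scr$results)))
  expect_true(all(scr$table$p >= 0 & scr$table$p <= 1))
  ## EGFR-subtype screen margins: subtype-mutant + EGFR-wild lesions only
  sub <- egfr_subtype_screen(fx)
  expect_equal(unname(colSums(sub[["L858R"]]$observed)), c(31, 36))
  expect_equal(unname(colSums(sub[["19del"]]$observed)), c(18, 36))
})

test_that("screen skips absent genes and single-level covariates with notice", {
  clinical <- make_clinical(c("A", "B"), c(2, 2))
  calls <- make_calls(list("A", "T1", "EGFR", "L858R"))
  co <- attach_calls(clinical, calls)
  expect_message(association_screen(co, genes = "KRAS", covariates = "sex"),
                 "no mutant lesions")
  expect_message(association_screen(co, genes = "EGFR", covariates = "sex"),
                 "single observed level")
})
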