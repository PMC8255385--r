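# ANOVA, paired t / Cohen's d, Bonferroni, JZS Bayes factors.

random_cells <- function(n_subj, n_cond, n_num) {
  g <- expand.grid(participant = seq_len(n_subj),
                   condition = paste0("c", seq_len(n_cond)),
                   numerosity = seq_len(n_num))
  g$cv <- rnorm(nrow(g))
  g$mean_response <- rnorm(nrow(g))
  g
}

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  set.seed(79)
  for (i in 1:5) {
    cells <- random_cells(5, 3, 4)
    got <- rm_anova(cells, "cv", numerosities = 1:4)
    want <- ws_anova_oracle(data.frame(y = cells$cv,
                                       participant = cells$participant,
                                       condition = cells$condition,
                                       numerosity = cells$numerosity))
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
  }
})

test_that("rm_anova degrees of freedom match the reference design", {
  tab <- simulate_cohort(seed = 29)
  cells <- cell_summaries(filter_outliers(tab)$table)
  an <- rm_anova(cells, "cv")
  expect_equal(an$df1, c(2L, 6L, 12L))
  expect_equal(an$df2, c(26L, 78L, 156L))
})

test_that("a constant dv yields zero F for every effect", {
  cells <- random_cells(4, 3, 3)
  cells$cv <- 1
  an <- rm_anova(cells, "cv", numerosities = 1:3)
  expect_equal(an$F, c(0, 0, 0))
  expect_equal(an$p, c(1, 1, 1))
})

test_that("missing cells are reported by name", {
  cells <- random_cells(4, 3, 3)
  cells <- cells[!(cells$participant == 2 & cells$condition == "c1" &
                     cells$numerosity == 3), ]
  expect_error(rm_anova(cells, "cv", numerosities = 1:3),
               "participant 2, condition c1, numerosity 3")
})

test_that("partial eta squared follows F * df1 / (F * df1 + df2)", {
  expect_equal(round(partial_eta2(7.83, 2, 26), 2), 0.38)
  expect_equal(round(partial_eta2(445, 6, 78), 2), 0.97)
  expect_equal(partial_eta2(0, 2, 26), 0)
})

test_that("paired t and Cohen's d agree with hand computation", {
  x <- c(1, 2, 3, 4)
  res <- paired_t(x, rep(0, 4))
  expect_equal(res$t, 2.5 / (sd(x) / 2))
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$d, 1.936, tolerance = 1e-3)
  expect_equal(res$d, res$t / sqrt(4))

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "constant")
})

test_that("Bonferroni correction scales and caps", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("JZS Bayes factor matches the high-resolution quadrature oracle", {
  for (t in c(0, 0.5, 2, 4.1)) {
    for (n in c(5, 14, 84)) {
      expect_equal(log10_jzs_bf(t, n), simpson_log10_jzs(t, n),
                   tolerance = 1e-6)
    }
  }
})

test_that("JZS Bayes factor favours the null at t = 0 and grows with |t|", {
  expect_lt(log10_jzs_bf(0, 14), 0)
  expect_lt(log10_jzs_bf(0, 84), 0)
  grid <- log10_jzs_bf(seq(0, 6, by = 0.5), 14)
  expect_true(all(diff(grid) > 0))
  expect_equal(log10_jzs_bf(3, 20), log10_jzs_bf(-3, 20))
})
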