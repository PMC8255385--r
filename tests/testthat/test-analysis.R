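# Outlier filter, cell summaries (CV = SD/N), grouping advantage.

make_cell_table <- function(responses, rts = NULL, participant = 1,
                            condition = "unstructured", numerosity = 9) {
  n <- length(responses)
  as_trial_table(data.frame(
    participant = participant, condition = condition, numerosity = numerosity,
    response = responses,
    rt_ms = if (is.null(rts)) rep(800, n) else rts))
}

test_that("3-SD filter removes exactly a constructed response-time outlier", {
  set.seed(73)
  rts <- rnorm(29, 800, 50)
  outlier_rt <- mean(rts) + 10 * sd(rts)
  tab <- make_cell_table(rep(9L, 30), c(rts, outlier_rt))
  res <- filter_outliers(tab)
  expect_equal(res$report$n_excluded, 1)
  expect_equal(res$table$excluded_reason[30], "rt_outlier")
  expect_true(all(res$table$excluded_reason[1:29] == ""))
  # direct verification of the rule on the full cell
  all_rt <- c(rts, outlier_rt)
  expect_true(abs(outlier_rt - mean(all_rt)) > 3 * sd(all_rt))
})

test_that("zero-variance cells and small cells are left intact", {
  res <- filter_outliers(make_cell_table(rep(7L, 20)))
  expect_equal(res$report$n_excluded, 0)
  expect_identical(res$table$excluded_reason, rep("", 20))

  small <- filter_outliers(make_cell_table(c(5L, 50L)))
  expect_equal(small$report$n_excluded, 0)
  expect_length(small$report$small_cells, 1)
})

test_that("an empty exclusion report round-trips to the identical table", {
  tab <- make_cell_table(c(8L, 9L, 9L, 10L))
  res <- filter_outliers(tab)
  expect_equal(res$report$n_excluded, 0)
  expect_identical(as.data.frame(res$table), as.data.frame(tab))
})

test_that("pre-flagged trials are ignored by the filter and the summaries", {
  tab <- simulate_cohort(cohort_design(n_participants = 2, trials_per_cell = 5),
                         seed = 3)
  res <- filter_outliers(tab)
  expect_true(all(res$table$excluded_reason[tab$excluded_reason == "no_clusters"]
                  == "no_clusters"))
  cells <- cell_summaries(res$table)
  expect_false(any(cells$condition == "isi_grouped" & cells$numerosity == 12))
})

test_that("cell summaries compute mean, sample SD, and CV = SD/N", {
  cells <- cell_summaries(make_cell_table(c(8L, 10L)))
  expect_equal(cells$mean_response, 9)
  expect_equal(cells$sd_response, sqrt(2))
  expect_equal(cells$cv, sqrt(2) / 9, tolerance = 1e-12)  # 0.15713

  same <- cell_summaries(make_cell_table(rep(9L, 3)))
  expect_equal(same$cv, 0)

  biased <- cell_summaries(make_cell_table(rep(10L, 5), numerosity = 9))
  expect_equal(biased$cv, 0)  # bias does not affect CV
})

test_that("grouping advantage implements (CVu - CVg)/CVu x 100", {
  expect_equal(grouping_advantage(0.12, 0.09), 25)
  expect_equal(grouping_advantage(0.37, 0.37), 0)
  expect_equal(grouping_advantage(0.10, 0.12), -20)
  expect_error(grouping_advantage(0, 0.1), "undefined")
})

test_that("advantage records join grouped cells to their baseline", {
  tab <- simulate_cohort(seed = 17)
  cells <- cell_summaries(filter_outliers(tab)$table)
  rec <- advantage_records(cells)
  expect_equal(nrow(rec), 14 * 7 * 2)
  expect_setequal(unique(rec$condition), c("freq_grouped", "isi_grouped"))
  i <- which(rec$participant == 3 & rec$numerosity == 6 &
               rec$condition == "isi_grouped")
  cvu <- cells$cv[cells$participant == 3 & cells$numerosity == 6 &
                    cells$condition == "unstructured"]
  cvg <- cells$cv[cells$participant == 3 & cells$numerosity == 6 &
                    cells$condition == "isi_grouped"]
  expect_equal(rec$advantage[i], (cvu - cvg) / cvu * 100)
})

test_that("trial tables round-trip through CSV with provenance headers", {
  tab <- simulate_cohort(cohort_design(n_participants = 2, trials_per_cell = 4),
                         seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tab, path, header = c("seed=5", "config_hash=abc"))
  back <- read_trials(path)
  expect_equal(as.data.frame(back)[, names(tab)[1:6]],
               as.data.frame(tab)[, 1:6], tolerance = 1e-9)
  expect_identical(back$excluded_reason, tab$excluded_reason)
})

test_that("import_trials maps external column names onto the native schema", {
  ext <- data.frame(subj = c(1, 1, 2, 2), cond = "baseline", nset = 7,
                    resp = c(6, 8, 7, 7), RT = c(700, 900, 800, 850))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ext, path, row.names = FALSE)
  tab <- import_trials(path,
                       mapping = c(participant = "subj", condition = "cond",
                                   numerosity = "nset", response = "resp",
                                   rt_ms = "RT"),
                       condition_levels = c(baseline = "unstructured"))
  expect_s3_class(tab, "trial_table")
  expect_true(all(tab$condition == "unstructured"))
  expect_error(import_trials(path, mapping = c(participant = "nope",
                                               condition = "cond",
                                               numerosity = "nset",
                                               response = "resp",
                                               rt_ms = "RT")),
               "nope")
})
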