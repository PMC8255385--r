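# Tone-sequence scheduling: ISI arithmetic, jitter, cluster patterns, grids.

test_that("nominal ISI solves the duration identity and matches the printed table", {
  n <- 5:12
  g <- nominal_isi(n)
  expect_equal(50 * n + (n - 1) * g, rep(1400, 8))
  expect_equal(nominal_isi(5), 287.5)
  expect_equal(nominal_isi(6), 220)
  expect_equal(nominal_isi(10), 100)
  tab <- isi_table()
  expect_equal(tab$isi_display_ms, c(287, 220, 175, 142, 118, 100, 85, 72))
  expect_error(nominal_isi(4), "5\\.\\.12")
  expect_error(nominal_isi(13), "5\\.\\.12")
})

test_that("unstructured sequences sit on the jittered grid", {
  set.seed(11)
  g7 <- nominal_isi(7)
  grid7 <- (0:6) * (50 + g7)
  for (i in 1:25) {
    s <- unstructured_sequence(7)
    expect_identical(s$numerosity, 7L)
    expect_equal(s$onset_ms[1], 0)
    expect_equal(s$onset_ms[7] + 50, 1400)
    # internal tones deviate from the grid by exactly 10% of the nominal ISI
    dev <- s$onset_ms - grid7
    expect_equal(abs(dev[2:6]), rep(0.1 * g7, 5))
    expect_equal(dev[c(1, 7)], c(0, 0))
    expect_length(unique(s$frequency_hz), 1L)
    expect_true(s$frequency_hz[1] %in% c(400, 700, 1000))
  }
  # zero jitter degenerates to the regular sequence
  s0 <- unstructured_sequence(7, jitter = 0)
  expect_equal(s0$onset_ms, grid7)
})

test_that("jitter signs are fair: mean internal onset equals the grid position", {
  set.seed(23)
  g <- nominal_isi(6)
  grid <- (0:5) * (50 + g)
  onsets <- replicate(4000, unstructured_sequence(6, frequency = 400)$onset_ms)
  expect_equal(rowMeans(onsets), grid, tolerance = 0.02)
})

test_that("cluster pattern lists are exactly the defined partitions", {
  expect_setequal(lapply(cluster_patterns(9, "freq_grouped"), identity),
                  list(c(4, 3, 2), c(3, 3, 3)))
  expect_setequal(cluster_patterns(8, "isi_grouped"),
                  list(c(4, 4), c(2, 2, 2, 2)))
  expect_setequal(cluster_patterns(7, "freq_grouped"),
                  list(c(3, 2, 2), c(2, 2, 3), c(3, 4)))
  expect_equal(cluster_patterns(11, "isi_grouped"), list(c(5, 6)))
  expect_equal(cluster_patterns(12, "freq_grouped"), list(c(4, 4, 4)))
  expect_length(cluster_patterns(12, "isi_grouped"), 0)
  for (n in 5:12) {
    for (cond in c("freq_grouped", "isi_grouped")) {
      for (p in cluster_patterns(n, cond)) expect_equal(sum(p), n)
    }
  }
})

test_that("frequency-grouped sequences respect pattern and adjacency rules", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    s <- frequency_grouped_sequence(n)
    pats <- cluster_patterns(n, "freq_grouped")
    expect_true(any(vapply(pats, identical, logical(1), y = s$pattern)))
    # one frequency per group, adjacent groups differ
    runs <- rle(s$frequency_hz)
    expect_equal(runs$lengths, as.integer(s$pattern))
    expect_true(all(diff(runs$values) != 0))
    # change-points between adjacent tones = number of groups - 1
    expect_equal(sum(diff(s$frequency_hz) != 0), length(s$pattern) - 1L)
  }
})

test_that("numerosity-6 frequency configurations come from the fixed set", {
  set.seed(37)
  cfgs <- replicate(60, frequency_grouped_sequence(6)$frequency_hz,
                    simplify = FALSE)
  allowed <- groupitizr:::.N6_FREQ_CONFIGS
  for (cf in cfgs) {
    expect_true(any(vapply(allowed, identical, logical(1), y = cf)))
  }
})

test_that("ISI-grouped sequences occupy a 12-slot grid with separated groups", {
  set.seed(41)
  spacing <- (1400 - 50) / 11
  for (i in 1:50) {
    n <- sample(5:11, 1)
    s <- isi_grouped_sequence(n)
    pats <- cluster_patterns(n, "isi_grouped")
    expect_true(any(vapply(pats, identical, logical(1), y = s$pattern)))
    slots <- round(s$onset_ms / spacing)
    expect_equal(s$onset_ms, slots * spacing)           # on the grid
    expect_equal(slots[1], 0)
    expect_equal(slots[n], 11)
    # groups are consecutive runs separated by >= 1 empty slot
    gap_at <- which(diff(s$group_index) != 0)
    expect_true(all(diff(slots)[gap_at] >= 2))
    expect_true(all(diff(slots)[-gap_at] == 1))
    expect_length(unique(s$frequency_hz), 1L)
  }
})

test_that("the full 12-tone ISI sequence equals the unjittered regular grid", {
  s12 <- isi_grouped_sequence(12, frequency = 700)
  u12 <- unstructured_sequence(12, jitter = 0, frequency = 700)
  expect_equal(s12$onset_ms, u12$onset_ms)
  expect_null(s12$pattern)
  expect_true(all(s12$group_index == -1L))
})

test_that("duration conservation holds across conditions and seeds", {
  set.seed(43)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    cond <- sample(c("unstructured", "freq_grouped", "isi_grouped"), 1)
    s <- generate_sequence(cond, n)
    expect_equal(s$onset_ms[1], 0)
    expect_equal(s$onset_ms[n] + s$duration_ms[n], 1400)
    expect_true(all(diff(s$onset_ms) >= s$duration_ms[-n]))
  }
})
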