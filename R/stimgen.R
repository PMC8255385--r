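# Tone-sequence scheduling for the three experimental conditions.
#
# Timing convention used throughout: a sequence spans first-tone onset (0 ms)
# to last-tone offset (1400 ms); the ISI is the silent offset-to-onset gap
# between consecutive tones. This is the unique convention that reproduces
# the regular-pattern ISI table exactly (e.g. (1400 - 6*50)/5 = 220 ms for
# N = 6).

.TONE_MS <- 50
.TOTAL_MS <- 1400
.FREQS_HZ <- c(400, 700, 1000)
.N_SLOTS <- 12L

.CONDITIONS <- c("unstructured", "freq_grouped", "isi_grouped")

.check_numerosity <- function(numerosity) {
  if (length(numerosity) != 1L || is.na(numerosity) ||
      numerosity != as.integer(numerosity) ||
      numerosity < 5 || numerosity > 12) {
    stop("`numerosity` must be a single integer in 5..12, got: ",
         deparse(numerosity), call. = FALSE)
  }
  as.integer(numerosity)
}

#' Nominal inter-stimulus interval of a regular tone sequence
#'
#' For a sequence of `numerosity` 50-ms tones spanning exactly 1400 ms from
#' first onset to last offset, the silent gap g between consecutive tones
#' satisfies `50 * N + (N - 1) * g = 1400`, i.e. `g = (1400 - 50 N)/(N - 1)`.
#' Values are returned exactly (fractional ms); use `isi_table()` for the
#' truncated display convention.
#'
#' @param numerosity integer vector with values in 5..12.
#' @return Numeric vector of offset-to-onset gaps in ms.
#' @examples
#' nominal_isi(6)   # 220
#' nominal_isi(5)   # 287.5
#' @export
nominal_isi <- function(numerosity) {
  vapply(numerosity, function(n) {
    n <- .check_numerosity(n)
    (.TOTAL_MS - .TONE_MS * n) / (n - 1)
  }, numeric(1))
}

#' Regular-pattern ISI table
#'
#' One row per numerosity 5..12 with the exact gap and its display value
#' (fractional milliseconds truncated).
#'
#' @return A data.frame with columns `numerosity`, `isi_ms`, `isi_display_ms`.
#' @export
isi_table <- function() {
  n <- 5:12
  g <- nominal_isi(n)
  data.frame(numerosity = n, isi_ms = g, isi_display_ms = trunc(g))
}

## Cluster patterns, verbatim per-numerosity lists for each grouped condition.
.FREQ_PATTERNS <- list(
  `5`  = list(c(2, 3), c(3, 2)),
  `6`  = list(c(3, 3), c(2, 2, 2)),
  `7`  = list(c(3, 2, 2), c(2, 2, 3), c(3, 4)),
  `8`  = list(c(4, 4), c(2, 2, 2, 2)),
  `9`  = list(c(4, 3, 2), c(3, 3, 3)),
  `10` = list(c(4, 4, 2), c(3, 4, 3)),
  `11` = list(c(4, 4, 3)),
  `12` = list(c(4, 4, 4))
)

.ISI_PATTERNS <- list(
  `5`  = list(c(2, 3), c(2, 1, 2)),
  `6`  = list(c(3, 3), c(2, 2, 2)),
  `7`  = list(c(2, 3, 2), c(3, 1, 3)),
  `8`  = list(c(4, 4), c(2, 2, 2, 2)),
  `9`  = list(c(2, 3, 4), c(3, 3, 3)),
  `10` = list(c(5, 5), c(4, 2, 4)),
  `11` = list(c(5, 6)),
  `12` = list()  # all 12 slots used; no clustering possible
)

# Six fixed frequency configurations for numerosity 6 (frequency condition);
# other numerosities draw group frequencies at run time.
.N6_FREQ_CONFIGS <- list(
  c(1000, 1000, 700, 700, 400, 400),
  c(1000, 1000, 400, 400, 700, 700),
  c(700, 700, 1000, 1000, 400, 400),
  c(700, 700, 700, 400, 400, 400),
  c(400, 400, 400, 1000, 1000, 1000),
  c(1000, 1000, 1000, 700, 700, 700)
)

#' Admissible cluster patterns for a numerosity and grouped condition
#'
#' Returns the fixed list of ordered group-size partitions used to cluster a
#' sequence (e.g. `c(4, 3, 2)` for nine tones in three groups). Numerosity 12
#' in the ISI-grouped condition admits no clustering (every slot of the
#' 12-slot grid is occupied) and returns an empty list.
#'
#' @param numerosity integer in 5..12.
#' @param condition `"freq_grouped"` or `"isi_grouped"`.
#' @return List of integer vectors, each summing to `numerosity`.
#' @examples
#' cluster_patterns(9, "freq_grouped")  # 4+3+2 and 3+3+3
#' cluster_patterns(12, "isi_grouped")  # empty
#' @export
cluster_patterns <- function(numerosity, condition = c("freq_grouped", "isi_grouped")) {
  numerosity <- .check_numerosity(numerosity)
  condition <- match.arg(condition)
  pats <- switch(condition,
    freq_grouped = .FREQ_PATTERNS,
    isi_grouped = .ISI_PATTERNS
  )[[as.character(numerosity)]]
  pats
}

.new_sequence <- function(condition, numerosity, onset, frequency, group_index,
                          pattern = NULL, duration = .TONE_MS) {
  stopifnot(length(onset) == numerosity, length(frequency) == numerosity,
            length(group_index) == numerosity)
  seq <- structure(
    list(condition = condition,
         numerosity = as.integer(numerosity),
         onset_ms = as.numeric(onset),
         duration_ms = rep(as.numeric(duration), numerosity),
         frequency_hz = as.numeric(frequency),
         group_index = as.integer(group_index),  # 0-based; -1 = ungrouped
         pattern = pattern,
         total_duration_ms = .TOTAL_MS),
    class = "stimulus_sequence"
  )
  validate_sequence(seq)
  seq
}

#' Validate a stimulus sequence
#'
#' Checks the structural invariants common to all three conditions: onsets
#' sorted and non-overlapping, first onset at 0 ms, last offset at 1400 ms,
#' frequencies drawn from \{400, 700, 1000\} Hz, and (for grouped sequences)
#' group sizes matching the cluster pattern.
#'
#' @param seq a `stimulus_sequence`.
#' @return `seq`, invisibly; errors describe the violated invariant.
#' @export
validate_sequence <- function(seq) {
  with(seq, {
    if (any(onset_ms < 0)) stop("negative onset")
    if (is.unsorted(onset_ms, strictly = TRUE)) stop("onsets not strictly increasing")
    if (any(diff(onset_ms) < duration_ms[-length(duration_ms)] - 1e-9)) {
      stop("overlapping tones")
    }
    if (abs(onset_ms[1]) > 1e-9) stop("first onset must be 0 ms")
    last_off <- onset_ms[numerosity] + duration_ms[numerosity]
    if (abs(last_off - total_duration_ms) > 1e-9) {
      stop("last offset must be ", total_duration_ms, " ms, got ", last_off)
    }
    if (!all(frequency_hz %in% .FREQS_HZ)) stop("frequency outside {400, 700, 1000} Hz")
    if (!is.null(pattern)) {
      if (sum(pattern) != numerosity) stop("pattern does not sum to numerosity")
      sizes <- as.integer(table(factor(group_index, levels = seq_along(pattern) - 1L)))
      if (!identical(sizes, as.integer(pattern))) stop("group sizes do not match pattern")
    }
  })
  invisible(seq)
}

#' Generate an unstructured tone sequence
#'
#' Tones are first placed on the regular grid (onset k*(50 + g) for the
#' nominal gap g), then every internal tone (neither first nor last) is
#' shifted by exactly `jitter * g` with an independent random sign, so each
#' shift lengthens one adjacent ISI and shortens the other. All tones share
#' one frequency drawn uniformly from 400/700/1000 Hz.
#'
#' @param numerosity integer in 5..12.
#' @param jitter fraction of the nominal ISI by which internal tones move
#'   (default 0.1; 0 gives the perfectly regular sequence).
#' @param frequency optional fixed frequency in Hz; drawn at random if `NULL`.
#' @return A `stimulus_sequence`.
#' @export
unstructured_sequence <- function(numerosity, jitter = 0.1, frequency = NULL) {
  numerosity <- .check_numerosity(numerosity)
  g <- nominal_isi(numerosity)
  onset <- (seq_len(numerosity) - 1) * (.TONE_MS + g)
  if (jitter > 0 && numerosity > 2) {
    internal <- 2:(numerosity - 1)
    onset[internal] <- onset[internal] +
      jitter * g * sample(c(-1, 1), length(internal), replace = TRUE)
  }
  if (is.null(frequency)) frequency <- sample(.FREQS_HZ, 1)
  .new_sequence("unstructured", numerosity, onset,
                rep(frequency, numerosity), rep(-1L, numerosity))
}

# Draw one frequency per group such that adjacent groups differ.
.draw_group_frequencies <- function(n_groups) {
  f <- numeric(n_groups)
  f[1] <- sample(.FREQS_HZ, 1)
  for (k in seq_len(n_groups)[-1]) {
    f[k] <- sample(setdiff(.FREQS_HZ, f[k - 1]), 1)
  }
  f
}

.config_pattern <- function(config) {
  # group sizes implied by a run-length frequency configuration
  rle(config)$lengths
}

#' Generate a frequency-grouped tone sequence
#'
#' Timing (including the 10% jitter) is identical to
#' [unstructured_sequence()]; grouping is carried by tone frequency. A
#' cluster pattern is drawn uniformly from [cluster_patterns()], tones within
#' a group share one frequency, and adjacent groups always differ. For
#' numerosity 6 the frequency configuration is drawn from the six fixed
#' configurations defined for that numerosity.
#'
#' @inheritParams unstructured_sequence
#' @return A `stimulus_sequence` with a `pattern` and per-tone `group_index`.
#' @export
frequency_grouped_sequence <- function(numerosity, jitter = 0.1) {
  numerosity <- .check_numerosity(numerosity)
  pats <- cluster_patterns(numerosity, "freq_grouped")
  pattern <- pats[[sample.int(length(pats), 1)]]
  group_index <- rep(seq_along(pattern) - 1L, pattern)
  if (numerosity == 6L) {
    matching <- Filter(function(cf) identical(as.integer(.config_pattern(cf)),
                                              as.integer(pattern)),
                       .N6_FREQ_CONFIGS)
    frequency <- matching[[sample.int(length(matching), 1)]]
  } else {
    frequency <- .draw_group_frequencies(length(pattern))[group_index + 1L]
  }
  timing <- unstructured_sequence(numerosity, jitter = jitter, frequency = 400)
  .new_sequence("freq_grouped", numerosity, timing$onset_ms, frequency,
                group_index, pattern = pattern)
}

#' Generate an ISI-grouped tone sequence
#'
#' The 1.4-s sequence is divided into 12 onset slots with spacing
#' `(1400 - 50)/11` ms, so that the full 12-slot sequence coincides with the
#' regular (unjittered) 12-tone grid and endpoints stay at 0/1400 ms. A
#' cluster pattern is drawn uniformly from [cluster_patterns()]; groups
#' occupy runs of consecutive slots separated by at least one empty slot,
#' empty slots distributed across the between-group gaps as evenly as
#' possible (ties broken at random). No temporal jitter is applied; all tones
#' share one frequency. Numerosity 12 fills every slot and is returned with
#' no pattern (ungrouped), to be flagged for exclusion downstream.
#'
#' @param numerosity integer in 5..12.
#' @param frequency optional fixed frequency in Hz; drawn at random if `NULL`.
#' @return A `stimulus_sequence`.
#' @export
isi_grouped_sequence <- function(numerosity, frequency = NULL) {
  numerosity <- .check_numerosity(numerosity)
  spacing <- (.TOTAL_MS - .TONE_MS) / (.N_SLOTS - 1)
  if (is.null(frequency)) frequency <- sample(.FREQS_HZ, 1)
  if (numerosity == .N_SLOTS) {
    onset <- (seq_len(.N_SLOTS) - 1) * spacing
    return(.new_sequence("isi_grouped", numerosity, onset,
                         rep(frequency, numerosity), rep(-1L, numerosity)))
  }
  pats <- cluster_patterns(numerosity, "isi_grouped")
  pattern <- pats[[sample.int(length(pats), 1)]]
  n_gaps <- length(pattern) - 1L
  n_empty <- .N_SLOTS - numerosity
  if (n_empty < n_gaps) {
    stop("pattern ", paste(pattern, collapse = "+"),
         " not placeable on ", .N_SLOTS, " slots with empty slots between groups")
  }
  gap <- rep(n_empty %/% n_gaps, n_gaps)
  extra <- n_empty %% n_gaps
  if (extra > 0) {
    idx <- if (n_gaps == 1L) 1L else sample.int(n_gaps, extra)
    gap[idx] <- gap[idx] + 1L
  }
  slots <- integer(0)
  pos <- 0L
  for (j in seq_along(pattern)) {
    slots <- c(slots, pos + seq_len(pattern[j]) - 1L)
    pos <- pos + pattern[j] + if (j <= n_gaps) gap[j] else 0L
  }
  onset <- slots * spacing
  group_index <- rep(seq_along(pattern) - 1L, pattern)
  .new_sequence("isi_grouped", numerosity, onset, rep(frequency, numerosity),
                group_index, pattern = pattern)
}

#' Generate one stimulus sequence for any condition
#'
#' @param condition one of `"unstructured"`, `"freq_grouped"`, `"isi_grouped"`.
#' @param numerosity integer in 5..12.
#' @param ... passed to the condition-specific generator.
#' @return A `stimulus_sequence`.
#' @export
generate_sequence <- function(condition = .CONDITIONS, numerosity, ...) {
  condition <- match.arg(condition)
  switch(condition,
    unstructured = unstructured_sequence(numerosity, ...),
    freq_grouped = frequency_grouped_sequence(numerosity, ...),
    isi_grouped = isi_grouped_sequence(numerosity, ...)
  )
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("stimulus_sequence: %s, numerosity %d%s\n", x$condition,
              x$numerosity,
              if (is.null(x$pattern)) "" else
                paste0(", pattern ", paste(x$pattern, collapse = "+"))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.stimulus_sequence <- function(x, ...) {
  data.frame(onset_ms = x$onset_ms, duration_ms = x$duration_ms,
             frequency_hz = x$frequency_hz, group_index = x$group_index)
}

#' @export
plot.stimulus_sequence <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, x$total_duration_ms),
                 ylim = range(.FREQS_HZ) + c(-100, 100),
                 xlab = "time (ms)", ylab = "frequency (Hz)",
                 main = sprintf("%s, N = %d", x$condition, x$numerosity), ...)
  cols <- c("grey30", "firebrick", "steelblue", "darkgreen")
  col <- ifelse(x$group_index < 0, cols[1], cols[(x$group_index %% 4) + 1])
  graphics::rect(x$onset_ms, x$frequency_hz - 25,
                 x$onset_ms + x$duration_ms, x$frequency_hz + 25,
                 col = col, border = NA)
  invisible(x)
}
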