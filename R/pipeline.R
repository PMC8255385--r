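# End-to-end analysis: outlier filter -> cell summaries -> ANOVAs ->
# post-hoc condition contrasts -> grouping advantage -> low/high range split.

#' Low/high numerosity split of the grouping advantage
#'
#' Advantage records (participant x numerosity x grouped condition) are
#' pooled within a low range and a high range of three numerosities each
#' (defaults 5:7 and 9:11; the numerosity straddling the midpoint is in
#' neither range, keeping the two pools the same size). Within each range a
#' one-sample t tests the pooled advantages against zero (default design: 14
#' participants x 3 numerosities x 2 grouped conditions = 84 records, df 83).
#' The ranges are then compared with a paired t, pairing records by
#' participant, grouped condition, and rank of numerosity within the range.
#'
#' @param cells a `cell_summary`.
#' @param low,high numerosities in the low and high range (equal lengths).
#' @param bf_scale Cauchy prior scale for the Bayes factors.
#' @return data.frame of class `range_split` with rows `low`, `high`, and
#'   `high_vs_low`; columns `range`, `n`, `mean_advantage`, `t`, `df`, `p`,
#'   `d`, `log10_bf`.
#' @export
range_split_advantage <- function(cells, low = 5:7, high = 9:11,
                                  bf_scale = sqrt(2) / 2) {
  stopifnot(length(low) == length(high))
  rec_l <- advantage_records(cells, numerosities = low)
  rec_h <- advantage_records(cells, numerosities = high)
  if (!nrow(rec_l) || !nrow(rec_h)) stop("empty numerosity range")
  row_for <- function(label, res, n) {
    data.frame(range = label, n = n, mean_advantage = res$mean %||% res$mean_diff,
               t = res$t, df = res$df, p = res$p, d = res$d,
               log10_bf = log10_jzs_bf(res$t, n, bf_scale))
  }
  out <- rbind(
    row_for("low", one_sample_t(rec_l$advantage), nrow(rec_l)),
    row_for("high", one_sample_t(rec_h$advantage), nrow(rec_h))
  )
  # pair the two pools record-by-record
  key <- function(rec, rng) {
    rec$rank <- match(rec$numerosity, sort(rng))
    rec[order(rec$condition, rec$participant, rec$rank), ]
  }
  rec_l <- key(rec_l, low)
  rec_h <- key(rec_h, high)
  if (nrow(rec_l) == nrow(rec_h)) {
    cmp <- paired_t(rec_h$advantage, rec_l$advantage)
    out <- rbind(out, row_for("high_vs_low", cmp, nrow(rec_l)))
  } else {
    warning("unequal record counts across ranges; between-range test skipped")
  }
  rownames(out) <- NULL
  class(out) <- c("range_split", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a trial table
#'
#' Stages, in order: 3-SD outlier exclusion; per-cell summaries with
#' CV = SD/N; repeated-measures ANOVAs on mean perceived numerosity and on CV
#' (condition x numerosity, both within participants); post-hoc paired
#' t-tests between conditions on per-participant CVs averaged over the
#' analysed numerosities, Bonferroni-corrected over the three contrasts, with
#' Cohen's d and log10 JZS Bayes factors; per-participant grouping-advantage
#' records and their means; and the low/high numerosity range split.
#'
#' @param table a `trial_table`.
#' @param numerosities numerosities analysed (default 5:11).
#' @param bf_scale Cauchy prior scale for Bayes factors (default sqrt(2)/2).
#' @return A list of class `groupitizing_report`.
#' @export
run_pipeline <- function(table, numerosities = 5:11, bf_scale = sqrt(2) / 2) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  filt <- stage("filter_outliers", filter_outliers(table))
  cells <- stage("cell_summaries", cell_summaries(filt$table))
  conditions <- sort(unique(as.character(cells$condition)))

  anova <- posthoc <- advantage <- ranges <- NULL
  if (length(conditions) >= 2) {
    anova <- list(
      mean_response = stage("rm_anova",
                            rm_anova(cells, "mean_response", numerosities)),
      cv = stage("rm_anova", rm_anova(cells, "cv", numerosities))
    )
    keep <- cells$numerosity %in% numerosities
    percv <- stats::aggregate(cv ~ participant + condition,
                              data = cells[keep, ], FUN = mean)
    pairs <- utils::combn(conditions, 2, simplify = FALSE)
    posthoc <- stage("posthoc", do.call(rbind, lapply(pairs, function(pr) {
      a <- percv$cv[percv$condition == pr[1]][order(percv$participant[percv$condition == pr[1]])]
      b <- percv$cv[percv$condition == pr[2]][order(percv$participant[percv$condition == pr[2]])]
      res <- paired_t(a, b)
      data.frame(contrast = paste(pr, collapse = " vs "), t = res$t,
                 df = res$df, p = res$p, d = res$d,
                 log10_bf = log10_jzs_bf(res$t, length(a), bf_scale))
    })))
    posthoc$p_bonf <- bonferroni(posthoc$p, m = max(3, nrow(posthoc)))
    if ("unstructured" %in% conditions && length(conditions) == 3) {
      rec <- stage("advantage", advantage_records(cells, numerosities))
      if (nrow(rec) > 0) {
        means <- stats::aggregate(advantage ~ condition, data = rec, FUN = mean)
        advantage <- list(records = rec, means = means,
                          n_undefined = attr(rec, "n_undefined"))
        ranges <- stage("range_split", range_split_advantage(cells,
                                                             bf_scale = bf_scale))
      } else {
        # e.g. a noise-free table: every baseline CV is 0, the index is
        # undefined everywhere
        advantage <- list(records = rec, means = NULL,
                          n_undefined = attr(rec, "n_undefined"))
        warning("grouping advantage undefined for every cell (baseline CV = 0)")
      }
    }
  } else {
    warning("fewer than two conditions present; condition contrasts skipped")
  }

  structure(list(exclusions = filt$report, cells = cells, anova = anova,
                 posthoc = posthoc, advantage = advantage,
                 range_split = ranges,
                 config = list(numerosities = numerosities,
                               bf_scale = bf_scale,
                               conditions = conditions,
                               seed = attr(table, "seed"))),
            class = "groupitizing_report")
}

#' Grand-mean coefficient of variation
#'
#' Mean CV over all cells of one condition (participants x numerosities),
#' the cohort-level precision index.
#'
#' @param report a `groupitizing_report` (or a `cell_summary`).
#' @param condition condition to average; `NULL` averages each condition.
#' @return Named numeric vector of grand-mean CVs.
#' @export
grand_mean_cv <- function(report, condition = NULL) {
  cells <- if (inherits(report, "groupitizing_report")) report$cells else report
  keep <- cells$numerosity %in%
    (if (inherits(report, "groupitizing_report"))
       report$config$numerosities else unique(cells$numerosity))
  cells <- cells[keep, ]
  out <- tapply(cells$cv, cells$condition, mean)
  if (!is.null(condition)) out <- out[condition]
  out
}

#' @export
print.groupitizing_report <- function(x, ...) {
  cat("Auditory groupitizing analysis\n")
  cat(sprintf("  %d cells, %d trials excluded by the 3-SD filter\n",
              nrow(x$cells), x$exclusions$n_excluded))
  gm <- grand_mean_cv(x)
  cat("  grand-mean CV: ",
      paste(sprintf("%s = %.3f", names(gm), gm), collapse = ", "), "\n", sep = "")
  if (!is.null(x$anova)) {
    print(x$anova$cv)
  }
  if (!is.null(x$posthoc)) {
    cat("Post-hoc paired t-tests on condition-mean CVs:\n")
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("  %-32s t(%d) = %.2f, p_bonf = %.3g, d = %.2f, log10 BF = %.2f\n",
                  x$posthoc$contrast[i], x$posthoc$df[i], x$posthoc$t[i],
                  x$posthoc$p_bonf[i], x$posthoc$d[i], x$posthoc$log10_bf[i]))
    }
  }
  if (!is.null(x$advantage) && !is.null(x$advantage$means)) {
    m <- x$advantage$means
    cat("Grouping advantage: ",
        paste(sprintf("%s = %.1f%%", m$condition, m$advantage), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$range_split)) {
    r <- x$range_split
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  range %-12s mean = %5.1f%%  t(%d) = %.2f, p = %.3g, d = %.2f, log10 BF = %.2f\n",
                  r$range[i], r$mean_advantage[i], r$df[i], r$t[i], r$p[i],
                  r$d[i], r$log10_bf[i]))
    }
  }
  invisible(x)
}

#' @export
summary.groupitizing_report <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.groupitizing_report <- function(x, ...) {
  cells <- x$cells[x$cells$numerosity %in% x$config$numerosities, ]
  m <- stats::aggregate(cv ~ condition + numerosity, data = cells, FUN = mean)
  conds <- sort(unique(m$condition))
  cols <- stats::setNames(c("grey20", "firebrick", "steelblue")[seq_along(conds)],
                          conds)
  graphics::plot(NULL, xlim = range(m$numerosity), ylim = c(0, max(m$cv) * 1.2),
                 xlab = "numerosity", ylab = "coefficient of variation", ...)
  for (cn in conds) {
    mm <- m[m$condition == cn, ]
    graphics::lines(mm$numerosity, mm$cv, col = cols[cn], type = "b", pch = 16)
  }
  graphics::legend("topright", legend = conds, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Write a report to disk
#'
#' Writes `report.json` (everything except the per-cell table) plus
#' `cells.csv` and `advantage.csv`.
#'
#' @param report a `groupitizing_report`.
#' @param dir output directory (created if needed).
#' @param header optional provenance strings prepended as `#` comments to the
#'   CSVs and stored under `$provenance` in the JSON.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, header = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  payload <- list(
    provenance = header,
    config = report$config,
    exclusions = report$exclusions,
    grand_mean_cv = as.list(grand_mean_cv(report)),
    anova = report$anova,
    posthoc = report$posthoc,
    advantage_means = report$advantage$means,
    range_split = report$range_split
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  csv_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  cells_path <- file.path(dir, "cells.csv")
  csv_with_header(as.data.frame(report$cells), cells_path)
  paths <- c(report = json_path, cells = cells_path)
  if (!is.null(report$advantage)) {
    adv_path <- file.path(dir, "advantage.csv")
    csv_with_header(report$advantage$records, adv_path)
    paths <- c(paths, advantage = adv_path)
  }
  invisible(paths)
}
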