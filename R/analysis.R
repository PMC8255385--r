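# Trial-table analysis: 3-SD outlier exclusion, per-cell coefficients of
# variation (CV = sigma / N), and the grouping-advantage index
# (CVu - CVg) / CVu * 100.

.TRIAL_COLS <- c("participant", "condition", "numerosity", "response", "rt_ms")

#' Coerce a data.frame to a trial table
#'
#' @param df data.frame with columns `participant`, `condition`,
#'   `numerosity`, `response`, `rt_ms`, and optionally `excluded_reason`.
#' @return The validated `trial_table`.
#' @export
as_trial_table <- function(df) {
  missing <- setdiff(.TRIAL_COLS, names(df))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(df$excluded_reason)) df$excluded_reason <- ""
  df$excluded_reason[is.na(df$excluded_reason)] <- ""
  if (any(df$response < 1)) stop("responses must be >= 1")
  if (!all(df$condition %in% .CONDITIONS)) {
    stop("unknown condition(s): ",
         paste(setdiff(unique(df$condition), .CONDITIONS), collapse = ", "))
  }
  if (!inherits(df, "trial_table")) class(df) <- c("trial_table", "data.frame")
  df
}

#' Read / write trial tables
#'
#' CSV schema: `participant,condition,numerosity,response,rt_ms,
#' excluded_reason`. Lines starting with `#` (provenance headers) are
#' ignored on read.
#'
#' @param path CSV file.
#' @return [read_trials()] returns a `trial_table`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such trial table: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_trial_table(df)
}

#' @rdname read_trials
#' @param table a `trial_table`.
#' @param header optional character vector written as leading `#` comment
#'   lines (seed, configuration hash).
#' @export
write_trials <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a trial table with external column names
#'
#' Adapter for deposited datasets whose column names differ from the native
#' schema: `mapping` names native columns and gives the source column for
#' each (e.g. `c(participant = "subj", response = "resp", ...)`).
#'
#' @param path CSV file.
#' @param mapping named character vector, native -> source column names.
#' @param condition_levels optional named character vector translating source
#'   condition labels to `unstructured` / `freq_grouped` / `isi_grouped`.
#' @return A `trial_table`.
#' @export
import_trials <- function(path, mapping, condition_levels = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(mapping, names(df))
  if (length(missing)) {
    stop("source file lacks mapped column(s): ", paste(missing, collapse = ", "))
  }
  out <- df[unname(mapping)]
  names(out) <- names(mapping)
  if (!is.null(condition_levels)) {
    out$condition <- unname(condition_levels[as.character(out$condition)])
  }
  as_trial_table(out)
}

.cell_key <- function(table) {
  interaction(table$participant, table$condition, table$numerosity, drop = TRUE)
}

#' 3-SD outlier exclusion
#'
#' Within each participant x condition x numerosity cell, a trial is excluded
#' when its response or its response time lies more than 3 cell SDs from the
#' cell mean (single pass; the mean and SD include the candidate trial).
#' Trials already flagged (e.g. ISI-grouped numerosity 12) are left alone and
#' not used to compute cell statistics. Cells with fewer than 3 usable trials
#' are kept unfiltered and listed in the report.
#'
#' @param table a `trial_table`.
#' @return A list with `table` (the input with `excluded_reason` filled in)
#'   and `report`: per-condition counts and fractions of newly excluded
#'   trials, plus any unfilterable small cells.
#' @export
filter_outliers <- function(table) {
  table <- as_trial_table(table)
  active <- which(table$excluded_reason == "")
  if (!length(active)) stop("no usable trials to filter")
  key <- .cell_key(table[active, , drop = FALSE])
  small_cells <- character(0)
  for (idx in split(active, key)) {
    if (length(idx) < 3) {
      small_cells <- c(small_cells, paste(table$participant[idx[1]],
                                          table$condition[idx[1]],
                                          table$numerosity[idx[1]], sep = "/"))
      next
    }
    r <- table$response[idx]
    rt <- table$rt_ms[idx]
    bad_r <- if (stats::sd(r) > 0) abs(r - mean(r)) > 3 * stats::sd(r) else FALSE
    bad_rt <- if (stats::sd(rt) > 0) abs(rt - mean(rt)) > 3 * stats::sd(rt) else FALSE
    table$excluded_reason[idx[bad_r]] <- "response_outlier"
    table$excluded_reason[idx[bad_rt & !bad_r]] <- "rt_outlier"
  }
  newly <- table$excluded_reason %in% c("response_outlier", "rt_outlier")
  eligible <- which(table$excluded_reason == "" | newly)
  rep_df <- do.call(rbind, lapply(split(eligible, table$condition[eligible]),
                                  function(i) {
    data.frame(condition = table$condition[i[1]], n_trials = length(i),
               n_excluded = sum(newly[i]),
               fraction_excluded = sum(newly[i]) / length(i))
  }))
  rownames(rep_df) <- NULL
  list(table = table,
       report = list(by_condition = rep_df,
                     n_excluded = sum(newly),
                     small_cells = small_cells))
}

#' Per-cell summaries and the coefficient of variation
#'
#' For every participant x condition x numerosity cell of the non-excluded
#' trials: trial count, mean perceived numerosity, sample SD of responses
#' (n - 1 denominator), and CV = SD / N.
#'
#' @param table a `trial_table` (normally after [filter_outliers()]).
#' @return data.frame of class `cell_summary` with columns `participant`,
#'   `condition`, `numerosity`, `n_trials`, `mean_response`, `sd_response`,
#'   `cv`.
#' @export
cell_summaries <- function(table) {
  table <- as_trial_table(table)
  keep <- table$excluded_reason == ""
  if (!any(keep)) stop("no non-excluded trials")
  df <- table[keep, , drop = FALSE]
  agg <- stats::aggregate(response ~ participant + condition + numerosity,
                          data = df, FUN = function(x) {
                            c(n = length(x), m = mean(x),
                              s = if (length(x) > 1) stats::sd(x) else 0)
                          })
  out <- data.frame(participant = agg$participant, condition = agg$condition,
                    numerosity = agg$numerosity,
                    n_trials = as.integer(agg$response[, "n"]),
                    mean_response = agg$response[, "m"],
                    sd_response = agg$response[, "s"])
  out$cv <- out$sd_response / out$numerosity
  out <- out[order(out$participant, out$condition, out$numerosity), ]
  rownames(out) <- NULL
  class(out) <- c("cell_summary", "data.frame")
  out
}

#' Grouping advantage
#'
#' Percent improvement in precision of a grouped condition over the
#' unstructured baseline: `(cv_u - cv_g) / cv_u * 100`. Positive values mean
#' grouping helped; the index is undefined when the baseline CV is zero.
#'
#' @param cv_u,cv_g coefficients of variation for the unstructured and
#'   grouped conditions (vectorised).
#' @return Numeric vector of advantages in percent.
#' @examples
#' grouping_advantage(0.12, 0.09)  # 25
#' @export
grouping_advantage <- function(cv_u, cv_g) {
  if (any(cv_u <= 0)) {
    stop("grouping advantage is undefined when the unstructured CV is 0")
  }
  (cv_u - cv_g) / cv_u * 100
}

#' Per-participant grouping-advantage records
#'
#' Joins each grouped-condition cell with the matching unstructured cell of
#' the same participant and numerosity and computes the advantage. Cells
#' whose baseline CV is zero are dropped (advantage undefined) and counted in
#' the `n_undefined` attribute.
#'
#' @param cells a `cell_summary`.
#' @param numerosities numerosities to keep (default 5:11).
#' @param grouped grouped conditions to index (default both).
#' @return data.frame with columns `participant`, `numerosity`, `condition`,
#'   `cv_u`, `cv_g`, `advantage`.
#' @export
advantage_records <- function(cells, numerosities = 5:11,
                              grouped = c("freq_grouped", "isi_grouped")) {
  cells <- cells[cells$numerosity %in% numerosities, , drop = FALSE]
  base <- cells[cells$condition == "unstructured",
                c("participant", "numerosity", "cv")]
  names(base)[3] <- "cv_u"
  grp <- cells[cells$condition %in% grouped,
               c("participant", "numerosity", "condition", "cv")]
  names(grp)[4] <- "cv_g"
  rec <- merge(grp, base, by = c("participant", "numerosity"))
  undef <- rec$cv_u <= 0
  rec <- rec[!undef, , drop = FALSE]
  rec$advantage <- grouping_advantage(rec$cv_u, rec$cv_g)
  rec <- rec[order(rec$condition, rec$participant, rec$numerosity),
             c("participant", "numerosity", "condition", "cv_u", "cv_g",
               "advantage")]
  rownames(rec) <- NULL
  attr(rec, "n_undefined") <- sum(undef)
  rec
}
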