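# Synthetic Weber-law observers: trial-level numerosity estimates with
# scalar variability (response SD proportional to numerosity, i.e. constant
# generative CV per condition) plus lognormal response times.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Observer parameters
#'
#' The generative model for one response is a rounded Gaussian,
#' `max(1, round(Normal(b_c * N, w_pc * N)))`, where `w_pc` is the
#' participant's Weber fraction in condition c: a condition-level fraction
#' `cv_by_condition[c]` scaled by a per-participant lognormal multiplier with
#' unit mean (so the cohort-average Weber fraction stays at its nominal
#' value). Response times are lognormal, with an optional contamination
#' fraction of slow outliers so the 3-SD response-time filter has something
#' to catch.
#'
#' @param cv_by_condition named generative coefficients of variation; the
#'   defaults (0.12 unstructured, 0.10 frequency-grouped, 0.09 ISI-grouped)
#'   are the cohort-average precisions the analysis is built around.
#' @param bias_by_condition multiplicative response bias per condition
#'   (default 1: accurate on average).
#' @param participant_spread SD, on the log scale, of the per-participant
#'   multiplier on the Weber fraction (default 0.25; 0 disables
#'   inter-individual variability).
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters (ms scale);
#'   defaults give a median of 800 ms.
#' @param rt_outlier_rate fraction of trials whose RT is multiplied by
#'   `rt_outlier_factor` (default 0.02, roughly the exclusion rate the 3-SD
#'   filter is expected to produce).
#' @param rt_outlier_factor slowdown factor for contaminated trials.
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(cv_by_condition = c(unstructured = 0.12,
                                                freq_grouped = 0.10,
                                                isi_grouped = 0.09),
                            bias_by_condition = c(unstructured = 1,
                                                  freq_grouped = 1,
                                                  isi_grouped = 1),
                            participant_spread = 0.25,
                            rt_meanlog = log(800), rt_sdlog = 0.4,
                            rt_outlier_rate = 0.02, rt_outlier_factor = 10) {
  if (any(cv_by_condition <= 0)) stop("all generative CVs must be > 0")
  if (any(bias_by_condition <= 0)) stop("all biases must be > 0")
  if (participant_spread < 0) stop("participant_spread must be >= 0")
  if (rt_outlier_rate < 0 || rt_outlier_rate > 1) {
    stop("rt_outlier_rate must be in [0, 1]")
  }
  structure(list(cv_by_condition = cv_by_condition,
                 bias_by_condition = bias_by_condition,
                 participant_spread = participant_spread,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_outlier_rate = rt_outlier_rate,
                 rt_outlier_factor = rt_outlier_factor),
            class = "observer_params")
}

#' Cohort design
#'
#' Defaults follow the reference design: 14 participants, three conditions,
#' numerosities 5..12, about 25 trials per cell.
#'
#' @param n_participants,numerosities,trials_per_cell,conditions design cells.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_participants = 14, numerosities = 5:12,
                          trials_per_cell = 25,
                          conditions = c("unstructured", "freq_grouped",
                                         "isi_grouped")) {
  stopifnot(n_participants >= 1, trials_per_cell >= 1,
            all(numerosities >= 1), all(conditions %in% .CONDITIONS))
  structure(list(n_participants = as.integer(n_participants),
                 numerosities = as.integer(numerosities),
                 trials_per_cell = as.integer(trials_per_cell),
                 conditions = conditions),
            class = "cohort_design")
}

#' Simulate numerosity estimates for one cell
#'
#' Draws `n` estimates from `Normal(bias * numerosity, w * numerosity)`,
#' rounds to the nearest integer, and floors at 1.
#'
#' @param numerosity true numerosity (>= 1).
#' @param w the observer's Weber fraction (generative CV, >= 0).
#' @param bias multiplicative bias (default 1).
#' @param n number of draws.
#' @return Integer vector of length `n`.
#' @export
simulate_response <- function(numerosity, w, bias = 1, n = 1) {
  stopifnot(numerosity >= 1, w >= 0, bias > 0)
  e <- stats::rnorm(n, mean = bias * numerosity, sd = w * numerosity)
  pmax(1L, as.integer(round(e)))
}

#' Simulate a full cohort
#'
#' One row per participant x condition x numerosity x trial. Each
#' participant's Weber-fraction multiplier is drawn once and shared across
#' conditions, so conditions differ only by the generative CV ratio.
#' ISI-grouped trials at numerosity 12 are generated (the design is balanced)
#' but flagged `excluded_reason = "no_clusters"` because that numerosity
#' offers no grouping cue.
#'
#' @param design a [cohort_design()].
#' @param params an [observer_params()].
#' @param seed optional integer; when given, the result is a pure function of
#'   `(design, params, seed)` and the caller's RNG state is untouched.
#' @return A data.frame of class `trial_table` with columns `participant`,
#'   `condition`, `numerosity`, `trial`, `response`, `rt_ms`,
#'   `excluded_reason`, and attribute `seed`.
#' @export
simulate_cohort <- function(design = cohort_design(), params = observer_params(),
                            seed = NULL) {
  .with_seed(seed, {
    mult <- stats::rlnorm(design$n_participants,
                          meanlog = -params$participant_spread^2 / 2,
                          sdlog = params$participant_spread)
    grid <- expand.grid(trial = seq_len(design$trials_per_cell),
                        numerosity = design$numerosities,
                        condition = design$conditions,
                        participant = seq_len(design$n_participants),
                        stringsAsFactors = FALSE)
    w <- params$cv_by_condition[grid$condition] * mult[grid$participant]
    b <- params$bias_by_condition[grid$condition]
    n <- nrow(grid)
    response <- pmax(1L, as.integer(round(stats::rnorm(
      n, mean = b * grid$numerosity, sd = w * grid$numerosity))))
    rt <- stats::rlnorm(n, params$rt_meanlog, params$rt_sdlog)
    slow <- stats::runif(n) < params$rt_outlier_rate
    rt[slow] <- rt[slow] * params$rt_outlier_factor
    excluded <- ifelse(grid$condition == "isi_grouped" & grid$numerosity == 12L,
                       "no_clusters", "")
    out <- data.frame(participant = grid$participant,
                      condition = grid$condition,
                      numerosity = grid$numerosity,
                      trial = grid$trial,
                      response = response,
                      rt_ms = rt,
                      excluded_reason = excluded,
                      stringsAsFactors = FALSE)
    out <- out[order(out$participant, out$condition, out$numerosity, out$trial), ]
    rownames(out) <- NULL
    class(out) <- c("trial_table", "data.frame")
    attr(out, "seed") <- seed
    out
  })
}
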