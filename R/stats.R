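# Inferential statistics: fully within-subject two-way ANOVA with partial
# eta squared, paired t-tests with Cohen's d, Bonferroni correction, and
# default (JZS) Bayes factors on the base-10 log scale.

#' Two-way fully within-subject repeated-measures ANOVA
#'
#' Fits `dv ~ condition * numerosity` with both factors within participants
#' (each effect tested against its own effect-by-participant interaction, the
#' standard univariate repeated-measures decomposition; no sphericity
#' correction). Effect size is partial eta squared,
#' `F * df1 / (F * df1 + df2)`.
#'
#' @param cells a `cell_summary` (one row per participant x condition x
#'   numerosity).
#' @param dv `"cv"` or `"mean_response"`.
#' @param numerosities levels to analyse (default 5:11; numerosity 12 offers
#'   no ISI grouping cue and is conventionally dropped).
#' @return data.frame of class `rm_anova` with columns `effect`, `df1`,
#'   `df2`, `F`, `p`, `partial_eta2`.
#' @export
rm_anova <- function(cells, dv = c("cv", "mean_response"), numerosities = 5:11) {
  dv <- match.arg(dv)
  d <- cells[cells$numerosity %in% numerosities, , drop = FALSE]
  d <- data.frame(y = d[[dv]],
                  participant = factor(d$participant),
                  condition = factor(d$condition),
                  numerosity = factor(d$numerosity))
  counts <- table(d$participant, d$condition, d$numerosity)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)[1, ]
    stop(sprintf("design not balanced: participant %s, condition %s, numerosity %s has %d rows",
                 dimnames(counts)[[1]][bad[1]], dimnames(counts)[[2]][bad[2]],
                 dimnames(counts)[[3]][bad[3]],
                 counts[bad[1], bad[2], bad[3]]))
  }
  if (stats::var(d$y) == 0) {
    out <- data.frame(
      effect = c("condition", "numerosity", "condition:numerosity"),
      df1 = c(nlevels(d$condition) - 1L, nlevels(d$numerosity) - 1L,
              (nlevels(d$condition) - 1L) * (nlevels(d$numerosity) - 1L)),
      df2 = c((nlevels(d$condition) - 1L) * (nlevels(d$participant) - 1L),
              (nlevels(d$numerosity) - 1L) * (nlevels(d$participant) - 1L),
              (nlevels(d$condition) - 1L) * (nlevels(d$numerosity) - 1L) *
                (nlevels(d$participant) - 1L)),
      F = 0, p = 1, partial_eta2 = 0)
    attr(out, "dv") <- dv
    class(out) <- c("rm_anova", "data.frame")
    return(out)
  }
  fit <- stats::aov(y ~ condition * numerosity +
                      Error(participant / (condition * numerosity)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    i <- match(effect, trimws(rownames(tab)))
    j <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = effect,
               df1 = as.integer(tab[i, "Df"]), df2 = as.integer(tab[j, "Df"]),
               F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  out <- rbind(
    grab("Error: participant:condition", "condition"),
    grab("Error: participant:numerosity", "numerosity"),
    grab("Error: participant:condition:numerosity", "condition:numerosity")
  )
  # A constant dv yields 0/0 mean squares; report F = 0 (no effect), p = 1.
  # A zero error term with a nonzero effect is a perfect effect: F = Inf.
  zero <- is.nan(out$F)
  out$F[zero] <- 0
  out$p[zero] <- 1
  out$partial_eta2 <- partial_eta2(out$F, out$df1, out$df2)
  perfect <- is.infinite(out$F)
  out$p[perfect] <- 0
  out$partial_eta2[perfect] <- 1
  rownames(out) <- NULL
  attr(out, "dv") <- dv
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Partial eta squared from an F statistic
#'
#' @param f F statistic; `df1`, `df2` its numerator and denominator degrees
#'   of freedom.
#' @return `F * df1 / (F * df1 + df2)`, in `[0, 1]`.
#' @examples
#' partial_eta2(7.83, 2, 26)  # 0.38
#' @export
partial_eta2 <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (dv: %s)\n", attr(x, "dv")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s F(%d, %d) = %.3g, p = %.3g, partial eta^2 = %.2f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$partial_eta2[i]))
  }
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Two-tailed paired t; Cohen's d is mean(x - y) / sd(x - y), identically
#' t / sqrt(n). Identical vectors return t = 0, d = 0; a nonzero constant
#' difference (zero variance) is an error.
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return list with `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1, d = 0, mean_diff = 0))
    stop("differences are a nonzero constant; t is undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
       p = tt$p.value, d = unname(tt$statistic) / sqrt(n),
       mean_diff = mean(d))
}

#' One-sample t-test against zero with Cohen's d
#'
#' @param x numeric vector, n >= 2.
#' @return list with `t`, `df`, `p`, `d`, `mean`.
#' @export
one_sample_t <- function(x) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) {
    if (all(x == 0)) return(list(t = 0, df = length(x) - 1L, p = 1, d = 0, mean = 0))
    stop("values are a nonzero constant; t is undefined")
  }
  tt <- stats::t.test(x)
  list(t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
       p = tt$p.value, d = mean(x) / stats::sd(x), mean = mean(x))
}

#' Bonferroni correction
#'
#' @param p p-values; `m` the number of comparisons in the family (defaults
#'   to `length(p)`, must be at least that).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

# Integrand of the JZS alternative marginal, already divided by the null
# likelihood so the integral is BF10 directly. Effect-size prior: Cauchy(0, r),
# written in its normal-by-inverse-gamma mixture form
# delta | g ~ N(0, g), g ~ InvGamma(1/2, r^2/2).
.jzs_integrand <- function(g, t, n, r) {
  nu <- n - 1
  lik_ratio <- (1 + n * g)^(-0.5) *
    ((1 + t^2 / ((1 + n * g) * nu)) / (1 + t^2 / nu))^(-(nu + 1) / 2)
  prior <- sqrt(r^2 / 2) / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
  lik_ratio * prior
}

#' Base-10 log of the JZS (default) Bayes factor for a t statistic
#'
#' Two-sided default Bayes factor for a one-sample (or paired) t-test, with a
#' Cauchy prior of scale `r` on the standardised effect size, computed by
#' adaptive quadrature of the marginal-likelihood ratio. Returns
#' log10(BF10): positive values favour the alternative.
#'
#' @param t t statistic(s).
#' @param n sample size (pairs for a paired test), n >= 2.
#' @param r Cauchy prior scale (default `sqrt(2)/2`, the conventional
#'   "medium" default).
#' @return log10 Bayes factor(s) in favour of the alternative.
#' @export
log10_jzs_bf <- function(t, n, r = sqrt(2) / 2) {
  stopifnot(n >= 2, all(is.finite(t)), r > 0)
  vapply(t, function(ti) {
    q <- tryCatch(
      stats::integrate(.jzs_integrand, 0, Inf, t = ti, n = n, r = r,
                       rel.tol = 1e-10, subdivisions = 500L),
      error = function(e) stop("JZS quadrature failed for t = ", ti,
                               ", n = ", n, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    if (q$message != "OK") {
      stop("JZS quadrature did not converge for t = ", ti, ", n = ", n,
           " (", q$message, ")")
    }
    log10(q$value)
  }, numeric(1))
}
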