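# Independent oracles used to cross-check the package's statistics.

# Brute-force sums-of-squares decomposition for a fully within-subject
# two-way design (one observation per subject x A x B cell), from the
# definitional formulas. Input: data.frame with y, participant, condition,
# numerosity (factors).
ws_anova_oracle <- function(d) {
  A <- factor(d$condition); B <- factor(d$numerosity); S <- factor(d$participant)
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  y <- array(NA_real_, dim = c(a, b, n))
  y[cbind(as.integer(A), as.integer(B), as.integer(S))] <- d$y
  stopifnot(!anyNA(y))
  m <- mean(y)
  ma <- apply(y, 1, mean); mb <- apply(y, 2, mean); ms <- apply(y, 3, mean)
  mab <- apply(y, c(1, 2), mean); mas <- apply(y, c(1, 3), mean)
  mbs <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((ma - m)^2)
  ss_b <- n * a * sum((mb - m)^2)
  ss_ab <- n * sum((mab - outer(ma, rep(1, b)) - outer(rep(1, a), mb) + m)^2)
  ss_as <- b * sum((mas - outer(ma, rep(1, n)) - outer(rep(1, a), ms) + m)^2)
  ss_bs <- a * sum((mbs - outer(mb, rep(1, n)) - outer(rep(1, b), ms) + m)^2)
  resid <- y
  for (i in 1:a) for (j in 1:b) for (k in 1:n) {
    resid[i, j, k] <- y[i, j, k] - mab[i, j] - mas[i, k] - mbs[j, k] +
      ma[i] + mb[j] + ms[k] - m
  }
  ss_abs <- sum(resid^2)
  f <- function(ss_eff, df_eff, ss_err, df_err) {
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  data.frame(
    effect = c("condition", "numerosity", "condition:numerosity"),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    F = c(f(ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
          f(ss_b, b - 1, ss_bs, (b - 1) * (n - 1)),
          f(ss_ab, (a - 1) * (b - 1), ss_abs, (a - 1) * (b - 1) * (n - 1)))
  )
}

# High-resolution composite-Simpson quadrature of the JZS marginal-likelihood
# ratio, written from the formula (Cauchy(0, r) prior on the standardised
# effect, normal-by-inverse-gamma mixture form), independently of the
# package's adaptive-quadrature implementation. Substitution g = u/(1 - u)
# maps (0, Inf) to (0, 1).
simpson_log10_jzs <- function(t, n, r = sqrt(2) / 2, npts = 200001) {
  nu <- n - 1
  f <- function(u) {
    g <- u / (1 - u)
    val <- (1 + n * g)^(-0.5) *
      ((1 + t^2 / ((1 + n * g) * nu)) / (1 + t^2 / nu))^(-(nu + 1) / 2) *
      sqrt(r^2 / 2) / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g)) /
      (1 - u)^2
    val[!is.finite(val)] <- 0
    val
  }
  u <- seq(0, 1 - 1e-9, length.out = npts)
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = npts)
  w[1] <- w[npts] <- 1
  log10(sum(w * f(u)) * h / 3)
}

# Cohort whose responses are exactly veridical (useful degenerate fixture).
veridical_cohort <- function(...) {
  simulate_cohort(cohort_design(...),
                  observer_params(cv_by_condition = c(unstructured = 1e-12,
                                                      freq_grouped = 1e-12,
                                                      isi_grouped = 1e-12),
                                  participant_spread = 0,
                                  rt_outlier_rate = 0),
                  seed = 99)
}
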