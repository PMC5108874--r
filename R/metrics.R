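#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the subject with the shorter survival
#' has the lower prognostic index (higher index = longer predicted
#' survival). A pair is usable when the order of event times is known: the
#' shorter observed time must be an event and strictly smaller than the
#' other time. Pairs with tied times and both events are skipped;
#' prediction ties count 1/2.
#'
#' @param u Prognostic index.
#' @param y Times.
#' @param delta Event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(u, y, delta) {
  n <- length(u)
  stopifnot(length(y) == n, length(delta) == n)
  # usable pair (i, j): y_i < y_j and delta_i == 1
  shorter <- outer(y, y, "<") & (delta == 1)
  conc <- outer(u, u, "<")   # shorter survivor has lower index
  tie <- outer(u, u, "==")
  usable <- sum(shorter)
  if (usable == 0) stop("no usable pairs: c-index undefined")
  (sum(conc & shorter) + 0.5 * sum(tie & shorter)) / usable
}

# median split of the prognostic index; ties go to the low group
risk_groups <- function(u) {
  g <- ifelse(u <= stats::median(u), "low", "high")
  if (length(unique(g)) < 2)
    stop("risk group empty: prognostic index has no spread at the median")
  factor(g, levels = c("low", "high"))
}

#' Two-group log-rank chi-square of a prognostic index
#'
#' Splits subjects at the median of `u` into low/high prognostic groups
#' (ties to the low group) and computes the two-sample log-rank chi-square
#' statistic (1 df) between their survival curves.
#'
#' @inheritParams c_index
#' @return Nonnegative chi-square statistic.
#' @export
logrank_chi2 <- function(u, y, delta) {
  g <- risk_groups(u)
  if (sum(delta) == 0) stop("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(y, delta) ~ g)
  unname(sd$chisq)
}

#' Median-split hazard ratio of a prognostic index
#'
#' Univariate Cox fit of the indicator "below-median `u`" (the putative
#' high-risk group, since low index predicts short survival). The reported
#' ratio is `exp(|beta|)` so it is `>= 1` regardless of orientation; under
#' monotone likelihood (a group without events, or perfectly separated
#' groups) it is capped.
#'
#' @inheritParams c_index
#' @param cap Upper bound returned under monotone likelihood (default 100).
#' @return Hazard ratio `>= 1`.
#' @export
hazard_ratio <- function(u, y, delta, cap = 100) {
  g <- risk_groups(u)
  high_risk <- as.numeric(g == "low")  # below-median index
  if (min(tapply(delta, g, sum)) == 0)
    warning("monotone likelihood: a risk group has no events; HR capped")
  fit <- tryCatch(
    survival::coxph(survival::Surv(y, delta) ~ high_risk, ties = "breslow"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(cap)
  beta <- unname(stats::coef(fit))
  min(exp(abs(beta)), cap)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction, so identical samples give p = 1).
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  U <- sum(rank(c(a, b))[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U
  if (!ties && m + n <= 20) {
    p <- 2 * min(stats::pwilcox(U, m, n),
                 1 - stats::pwilcox(U - 1, m, n))
    return(min(p, 1))
  }
  N <- m + n
  tj <- table(c(a, b))
  sigma2 <- m * n / 12 * ((N + 1) - sum(tj^3 - tj) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (U - m * n / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' All three performance measures of a prognostic index
#'
#' @inheritParams c_index
#' @return List of class `performance_triple` with `c_index`,
#'   `logrank_chi2`, `hazard_ratio`.
#' @export
performance_triple <- function(u, y, delta) {
  structure(list(c_index = c_index(u, y, delta),
                 logrank_chi2 = logrank_chi2(u, y, delta),
                 hazard_ratio = hazard_ratio(u, y, delta)),
            class = "performance_triple")
}

#' @export
print.performance_triple <- function(x, ...) {
  cat(sprintf("c-index %.3f | log-rank chi2 %.3f | hazard ratio %.3f\n",
              x$c_index, x$logrank_chi2, x$hazard_ratio))
  invisible(x)
}
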