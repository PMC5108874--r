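#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function S(t). At tied times,
#' events are handled before censorings (the standard convention): the
#' at-risk count at an event time t includes every subject with `y >= t`.
#'
#' @param y Positive times.
#' @param delta Event indicators in \{0, 1\}; at least one event required.
#' @return Object of class `step_survival` with fields `times` (distinct
#'   event times, increasing), `surv` (S after each event time),
#'   `n_at_risk`, `n_events` and `t_max` (largest observation of any kind).
#' @export
km_estimate <- function(y, delta) {
  if (any(y <= 0)) stop("times must be positive")
  if (!all(delta %in% c(0, 1))) stop("delta must be 0/1")
  if (sum(delta) == 0) stop("no events: survival curve is unidentified")
  et <- sort(unique(y[delta == 1]))
  n_risk <- vapply(et, function(t) sum(y >= t), 0)
  n_ev <- vapply(et, function(t) sum(y == t & delta == 1), 0)
  surv <- cumprod(1 - n_ev / n_risk)
  structure(list(times = et, surv = surv, n_at_risk = n_risk,
                 n_events = n_ev, t_max = max(y)),
            class = "step_survival")
}

#' @export
print.step_survival <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event times, t_max=%g, S(t_max-)=%g\n",
              length(x$times), x$t_max, x$surv[length(x$surv)]))
  invisible(x)
}

# S(t), right-continuous: value after the last event time <= t.
km_surv_at <- function(s, t) {
  k <- findInterval(t, s$times)
  ifelse(k == 0, 1, s$surv[pmax(k, 1)])
}

#' Mean residual lifetime from a Kaplan-Meier curve
#'
#' `MRL(t) = integral_t^{t_max} S(u) du / S(t)` with the integral taken
#' exactly under the step function and truncated at the largest observed
#' time (restricted-mean convention: mass beyond a final censored
#' observation is ignored, keeping the estimate finite). Returns 0 when
#' `t >= t_max` or `S(t) = 0`.
#'
#' @param s A `step_survival` from [km_estimate()].
#' @param t Nonnegative evaluation time(s).
#' @return Nonnegative MRL value(s).
#' @export
mrl_at <- function(s, t) {
  vapply(t, function(tt) {
    if (tt >= s$t_max) return(0)
    St <- km_surv_at(s, tt)
    if (St <= 0) return(0)
    # breakpoints of the step function on (tt, t_max]
    brk <- c(tt, s$times[s$times > tt & s$times < s$t_max], s$t_max)
    lev <- km_surv_at(s, brk[-length(brk)])
    area <- sum(lev * diff(brk))
    area / St
  }, 0)
}

#' Mean residual lifetime table for a dataset
#'
#' Computes, from the Kaplan-Meier curve of the full dataset, the MRL at
#' each censored subject's censoring time; subjects with an event get 0 by
#' convention. This is the amount added to each censoring time by the
#' two-sided SVR model: the imputed event time is `y_i + MRL_i`.
#'
#' @param ds A [survival_dataset()] with at least one event.
#' @return Numeric vector of length `n` (class `mrl_table`).
#' @export
mrl_augment <- function(ds) {
  s <- km_estimate(ds$y, ds$delta)
  mrl <- numeric(n_subjects(ds))
  cen <- which(ds$delta == 0L)
  if (length(cen)) mrl[cen] <- mrl_at(s, ds$y[cen])
  structure(mrl, class = "mrl_table")
}

#' Export a Kaplan-Meier curve as a two-column table
#' @param s A `step_survival`.
#' @param path Optional TSV path; if `NULL`, the data frame is returned.
#' @return Data frame with columns `time` and `surv` (invisibly if written).
#' @export
km_as_table <- function(s, path = NULL) {
  df <- data.frame(time = c(0, s$times), surv = c(1, s$surv))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
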