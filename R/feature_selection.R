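#' Association tests between a prognostic index and each feature
#'
#' For a prognostic index `u` computed on the same subjects: a continuous
#' feature is tested by Pearson correlation (t-test on r); a two-level
#' categorical feature by a pooled-variance two-sample t-test on `u`; a
#' feature with three or more levels by a one-way ANOVA F-test. Rows in an
#' `"Unknown"` category are excluded from that feature's test (but nothing
#' else). Constant features, or a constant `u`, are flagged and skipped.
#'
#' @param ds A [survival_dataset()].
#' @param u Prognostic index, aligned with `ds`.
#' @param alpha Significance threshold used for the `significant` column.
#' @return Data frame: feature, test, statistic, p_value, significant.
#' @export
association_tests <- function(ds, u, alpha = 0.05) {
  stopifnot(length(u) == n_subjects(ds))
  out <- list()
  for (j in seq_len(n_features(ds))) {
    sc <- ds$schema[[j]]
    v <- ds$X[, j]
    row <- data.frame(feature = sc$name, test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      significant = NA)
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      row$test <- "skipped"
      out[[j]] <- row; next
    }
    if (sc$kind == "continuous") {
      ct <- stats::cor.test(v, u)
      row$test <- "pearson"
      row$statistic <- unname(ct$estimate)
      row$p_value <- ct$p.value
    } else {
      keep <- sc$categories[v] != "Unknown"
      g <- factor(sc$categories[v[keep]])
      uu <- u[keep]
      lv <- nlevels(droplevels(g))
      if (lv < 2 || stats::sd(uu) == 0) {
        row$test <- "skipped"
        out[[j]] <- row; next
      }
      if (lv == 2) {
        tt <- stats::t.test(uu ~ g, var.equal = TRUE)
        row$test <- "t"
        row$statistic <- unname(tt$statistic)
        row$p_value <- tt$p.value
      } else {
        an <- stats::anova(stats::lm(uu ~ g))
        row$test <- "anova"
        row$statistic <- an$`F value`[1]
        row$p_value <- an$`Pr(>F)`[1]
      }
    }
    row$significant <- row$p_value < alpha
    out[[j]] <- row
  }
  do.call(rbind, out)
}

#' Univariate concordance ranking of features
#'
#' Evaluates each feature alone in a standard linear censored SVR via
#' [evaluate_repeated()] (shared split seeds across features) and ranks
#' features by median test c-index, best first.
#'
#' @param ds A [survival_dataset()] with at least two features.
#' @param n_reps Replicates per feature.
#' @param seed Master seed (shared by every feature's replicate stream).
#' @param grid Hyperparameter grid for the per-feature SVR.
#' @return Object of class `feature_ranking`: data frame `ranking` with
#'   feature, criterion (median c-index) in descending order, and
#'   `method = "univariate"`.
#' @export
univariate_rank <- function(ds, n_reps = 10L, seed = 1L,
                            grid = list(gamma = 1)) {
  d <- n_features(ds)
  if (d < 2L) stop("need at least 2 features to rank")
  crit <- numeric(d)
  for (j in seq_len(d)) {
    s <- evaluate_repeated(subset_features(ds, j), "model1", "linear",
                           grid = grid, n_reps = n_reps, seed = seed)
    crit[j] <- s$median[["c_index"]]
  }
  ord <- order(-crit)
  structure(list(ranking = data.frame(feature = colnames(ds$X)[ord],
                                      criterion = crit[ord]),
                 method = "univariate"),
            class = "feature_ranking")
}

#' Evaluate nested top-p feature subsets
#'
#' For each requested subset size `p`, evaluates a linear standard SVR and
#' the Cox baseline on the top-`p` features of a ranking via
#' [evaluate_repeated()]; the `p` with the highest SVR median c-index is
#' flagged as best.
#'
#' @param ranking A `feature_ranking`.
#' @param ds The full [survival_dataset()].
#' @param p_values Integer subset sizes to evaluate (all `<= d`).
#' @param n_reps,seed,grid Passed to [evaluate_repeated()].
#' @return List of class `subset_path`: `evaluations` (one entry per `p`
#'   with members, SVR and Cox summaries), `best_p`, `table` (flat data
#'   frame of medians).
#' @export
select_top_p <- function(ranking, ds, p_values = seq_len(n_features(ds)),
                         n_reps = 10L, seed = 1L, grid = list(gamma = 1)) {
  if (max(p_values) > n_features(ds)) stop("p larger than feature count")
  evals <- list()
  for (p in p_values) {
    members <- ranking$ranking$feature[seq_len(p)]
    sub <- subset_features(ds, members)
    svr <- evaluate_repeated(sub, "model1", "linear", grid = grid,
                             n_reps = n_reps, seed = seed)
    cox <- evaluate_repeated(sub, "cox", n_reps = n_reps, seed = seed)
    evals[[as.character(p)]] <- list(p = p, members = members,
                                     svr = svr, cox = cox)
  }
  finalize_subset_path(evals)
}

finalize_subset_path <- function(evals) {
  tab <- do.call(rbind, lapply(evals, function(e)
    data.frame(p = e$p,
               svr_c_index = e$svr$median[["c_index"]],
               cox_c_index = e$cox$median[["c_index"]],
               svr_logrank = e$svr$median[["logrank_chi2"]],
               svr_hr = e$svr$median[["hazard_ratio"]])))
  best <- tab$p[which.max(tab$svr_c_index)]
  structure(list(evaluations = evals, best_p = best, table = tab),
            class = "subset_path")
}

#' Recursive feature elimination with linear censored SVR
#'
#' Backward elimination: starting from all `d` features, repeatedly fit a
#' linear standard SVR (with `gamma` re-tuned on a reduced grid), record
#' the subset's performance, and drop the feature with the smallest squared
#' weight (ties: the later-indexed feature). Produces exactly `d` nested
#' subset evaluations of sizes `d, d-1, ..., 1`; the best subset is the one
#' with the highest SVR median c-index.
#'
#' @param ds A standardized [survival_dataset()].
#' @param n_reps,seed Passed to [evaluate_repeated()] for each subset.
#' @param grid Gamma grid used both for the elimination fits (via
#'   3-fold CV when it has more than one point) and the evaluations.
#' @return A `subset_path` (see [select_top_p()]) whose evaluations also
#'   record `w2`, the squared weights at that step, and `dropped`, the
#'   feature removed after it.
#' @export
rfe <- function(ds, n_reps = 10L, seed = 1L, grid = list(gamma = 1)) {
  current <- colnames(ds$X)
  evals <- list()
  while (length(current) >= 1L) {
    sub <- subset_features(ds, current)
    p <- length(current)
    svr <- evaluate_repeated(sub, "model1", "linear", grid = grid,
                             n_reps = n_reps, seed = seed)
    cox <- evaluate_repeated(sub, "cox", n_reps = n_reps, seed = seed)

    dropped <- NA_character_; w2 <- NULL
    if (p > 1L) {
      st <- standardize(sub)$train
      npts <- length(grid$gamma)
      hp <- if (npts > 1)
        tune(st, "model1", "linear", grid = grid, folds = 3L,
             seed = child_seed(seed, p))$hp
      else hyper_params(grid$gamma[1])
      fit <- suppressWarnings(fit_model1(st, kernel_spec("linear"), hp))
      w2 <- fit$w_linear^2
      names(w2) <- current
      if (fit$degenerate || all(w2 == 0)) {
        dropped <- current[p]        # fall back: drop the last-indexed
      } else {
        worst <- which(w2 == min(w2))
        dropped <- current[worst[length(worst)]]  # ties: later index
      }
    }
    evals[[as.character(p)]] <- list(p = p, members = current, svr = svr,
                                     cox = cox, w2 = w2, dropped = dropped)
    if (p == 1L) break
    current <- setdiff(current, dropped)
  }
  finalize_subset_path(evals)
}
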