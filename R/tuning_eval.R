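fit_by_kind <- function(kind, ds, kernel, hp) {
  switch(kind,
         model1 = fit_model1(ds, kernel, hp),
         model2 = fit_model2(ds, kernel, hp),
         ssvr_mrl = fit_ssvr_mrl(ds, kernel, hp),
         stop("unknown model kind: ", kind))
}

make_kernel <- function(kernel_kind, point, schema = NULL) {
  switch(kernel_kind,
         linear = kernel_spec("linear"),
         polynomial = kernel_spec("polynomial",
                                  degree = point$degree %||% 2),
         rbf = kernel_spec("rbf", gamma_rbf = point$gamma_rbf %||% 1),
         clinical = kernel_spec("clinical", schema = schema),
         stop("unknown kernel kind: ", kernel_kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyperparameter grid
#'
#' `gamma` and (for the two-slack models) `mu` range over the powers
#' `2^(-8), 2^(-6), ..., 2^8`; the RBF bandwidth is taken as the inverse of
#' the \{0.1, 0.5, 0.9\} quantiles of the pairwise squared distances of the
#' training data; polynomial degree is 2 or 3. `reduced = TRUE` gives the
#' coarse grid used inside heavy loops (simulation benchmark, RFE).
#'
#' @param model_kind,kernel_kind Model and kernel selectors.
#' @param X Training matrix (needed for the RBF bandwidth quantiles).
#' @param reduced Use the coarse grid.
#' @return Named list of parameter vectors, ready for [tune()].
#' @export
default_grid <- function(model_kind = "model1", kernel_kind = "linear",
                         X = NULL, reduced = FALSE) {
  g <- if (reduced) 2^seq(-4, 4, by = 4) else 2^seq(-8, 8, by = 2)
  grid <- list(gamma = g)
  if (model_kind %in% c("model2", "ssvr_mrl"))
    grid$mu <- if (reduced) 2^seq(-4, 4, by = 4) else 2^seq(-8, 8, by = 2)
  if (kernel_kind == "rbf") {
    if (is.null(X)) stop("rbf grid needs the training matrix X")
    m <- min(nrow(X), 200L)
    Xs <- X[seq_len(m), , drop = FALSE]
    d2 <- as.numeric(stats::dist(Xs))^2
    q <- stats::quantile(d2[d2 > 0], c(0.1, 0.5, 0.9))
    grid$gamma_rbf <- unname(1 / q)
  }
  if (kernel_kind == "polynomial")
    grid$degree <- if (reduced) 2 else c(2, 3)
  grid
}

cv_folds <- function(n, folds, seed) {
  local_rng(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Hyperparameter tuning by k-fold cross-validation
#'
#' Exhaustive grid search maximizing the mean validation concordance index
#' over `folds` cross-validation folds (3 by default). Ties are broken
#' toward smaller `gamma`, then smaller `mu`, then smaller kernel
#' parameter. Folds are deterministic given `seed`. Folds on which the
#' model is degenerate or the c-index undefined are skipped; a grid point
#' with no scorable fold is dropped.
#'
#' @param ds Training [survival_dataset()].
#' @param model_kind `"model1"`, `"model2"` or `"ssvr_mrl"`.
#' @param kernel_kind `"linear"`, `"polynomial"`, `"rbf"` or `"clinical"`.
#' @param grid Named list of parameter vectors (see [default_grid()]).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List with `hp` ([hyper_params()]), `kernel` ([kernel_spec()])
#'   and `cv_score` (mean validation c-index of the winner).
#' @export
tune <- function(ds, model_kind = "model1", kernel_kind = "linear",
                 grid = default_grid(model_kind, kernel_kind, ds$X),
                 folds = 3L, seed = 1L) {
  if (!length(grid)) stop("empty grid")
  if (folds < 2L) stop("folds must be >= 2")
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fold_id <- cv_folds(n_subjects(ds), folds, seed)
  scores <- rep(NA_real_, nrow(pts))
  for (p in seq_len(nrow(pts))) {
    point <- as.list(pts[p, , drop = FALSE])
    hp <- hyper_params(point$gamma, point$mu %||% 0)
    kern <- make_kernel(kernel_kind, point, schema = ds$schema)
    fold_scores <- c()
    for (f in seq_len(folds)) {
      tr <- subset_rows(ds, which(fold_id != f))
      va <- subset_rows(ds, which(fold_id == f))
      if (sum(tr$delta) == 0) next
      sc <- tryCatch({
        fit <- suppressWarnings(fit_by_kind(model_kind, tr, kern, hp))
        c_index(predict(fit, va), va$y, va$delta)
      }, error = function(e) NA_real_)
      if (!is.na(sc)) fold_scores <- c(fold_scores, sc)
    }
    if (length(fold_scores)) scores[p] <- mean(fold_scores)
  }
  if (all(is.na(scores))) stop("tuning error: every grid point degenerate")
  # ties toward smaller gamma, then mu, then kernel parameter
  ord <- do.call(order, c(list(-scores), as.list(pts)))
  best <- as.list(pts[ord[1], , drop = FALSE])
  list(hp = hyper_params(best$gamma, best$mu %||% 0),
       kernel = make_kernel(kernel_kind, best, schema = ds$schema),
       cv_score = scores[ord[1]])
}

#' Repeated random-split evaluation of one model
#'
#' The repeated-holdout protocol: in each replicate the data are split
#' 2/3 train / 1/3 test, continuous features are standardized on the
#' training part, hyperparameters are tuned on the training part (if a
#' grid with more than one point is given), the model is fitted and the
#' three performance measures are computed on the test part. The summary
#' reports medians and SDs over the completed replicates.
#'
#' @param ds A [survival_dataset()].
#' @param model_kind `"model1"`, `"model2"`, `"ssvr_mrl"` or `"cox"`.
#' @param kernel_kind Kernel selector (ignored for Cox).
#' @param grid Hyperparameter grid; a single-point grid skips CV.
#' @param n_reps Number of random splits (100 in the reference protocol).
#' @param train_fraction Training proportion (default 2/3).
#' @param seed Master seed; replicate `r` uses the split seed
#'   `child_seed(seed, r)`, so different models called with the same `seed`
#'   see identical splits (paired replicate streams).
#' @param standardize_features Standardize continuous features on train.
#' @param tune_folds CV folds used by the internal [tune()].
#' @return Object of class `performance_summary`: `replicates` (data frame
#'   with one row per completed replicate), `median`, `sd`, `mean`,
#'   `n_reps`, `n_degenerate` and the model descriptor.
#' @export
evaluate_repeated <- function(ds, model_kind = "model1",
                              kernel_kind = "linear",
                              grid = list(gamma = 1),
                              n_reps = 100L, train_fraction = 2 / 3,
                              seed = 1L, standardize_features = TRUE,
                              tune_folds = 3L) {
  rows <- list(); n_degen <- 0L
  for (r in seq_len(n_reps)) {
    s_r <- child_seed(seed, r)
    tri <- suppressWarnings(tryCatch({
      sp <- split_train_test(ds, train_fraction, seed = s_r)
      tr <- sp$train; te <- sp$test
      if (standardize_features) {
        st <- standardize(tr, list(te))
        tr <- st$train; te <- st$others[[1]]
      }
      if (model_kind == "cox") {
        fit <- fit_cox_baseline(tr)
        u <- predict(fit, te)
      } else {
        npts <- prod(vapply(grid, length, 0L))
        if (npts > 1) {
          tn <- tune(tr, model_kind, kernel_kind, grid,
                     folds = tune_folds, seed = child_seed(seed, r, 7L))
          hp <- tn$hp; kern <- tn$kernel
        } else {
          point <- lapply(grid, `[[`, 1)
          hp <- hyper_params(point$gamma, point$mu %||% 0)
          kern <- make_kernel(kernel_kind, point, schema = tr$schema)
        }
        fit <- fit_by_kind(model_kind, tr, kern, hp)
        if (fit$degenerate) stop("degenerate fit")
        u <- predict(fit, te)
      }
      performance_triple(u, te$y, te$delta)
    }, error = function(e) NULL))
    if (is.null(tri)) { n_degen <- n_degen + 1L; next }
    rows[[length(rows) + 1L]] <-
      data.frame(rep = r, c_index = tri$c_index,
                 logrank_chi2 = tri$logrank_chi2,
                 hazard_ratio = tri$hazard_ratio)
  }
  if (!length(rows)) stop("no replicate completed")
  reps <- do.call(rbind, rows)
  if (n_degen > 0.2 * n_reps)
    warning(sprintf("%d of %d replicates degenerate", n_degen, n_reps))
  meas <- c("c_index", "logrank_chi2", "hazard_ratio")
  structure(list(
    replicates = reps,
    median = vapply(meas, function(m) stats::median(reps[[m]]), 0),
    sd = vapply(meas, function(m) stats::sd(reps[[m]]), 0),
    mean = vapply(meas, function(m) mean(reps[[m]]), 0),
    n_reps = n_reps, n_degenerate = n_degen,
    model = list(model_kind = model_kind, kernel_kind = kernel_kind)),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("%s (%s kernel), %d reps (%d degenerate)\n",
              x$model$model_kind, x$model$kernel_kind %||% "-",
              x$n_reps, x$n_degenerate))
  for (m in names(x$median))
    cat(sprintf("  %-13s median %.3f +/- %.3f (SD)\n", m,
                x$median[[m]], x$sd[[m]]))
  invisible(x)
}

#' Wilcoxon comparison of models against a reference
#'
#' For each non-reference summary and each of the three measures, the
#' two-sided Wilcoxon rank-sum p-value of its per-replicate values against
#' the reference's, with the usual significance stars
#' (`*` 0.05, `**` 0.01, `***` 0.001).
#'
#' @param summaries Named list of `performance_summary` objects produced
#'   with the same `n_reps` and master seed (paired replicate streams).
#' @param reference Name of the reference model in `summaries`.
#' @return Data frame: model, measure, median, p_value, stars.
#' @export
compare_models <- function(summaries, reference) {
  if (!reference %in% names(summaries))
    stop("reference '", reference, "' not among summaries")
  ref <- summaries[[reference]]
  nr <- vapply(summaries, function(s) as.integer(s$n_reps), 0L)
  if (length(unique(nr)) != 1L)
    stop("comparison error: summaries have mismatched replicate counts")
  meas <- c("c_index", "logrank_chi2", "hazard_ratio")
  out <- list()
  for (nm in setdiff(names(summaries), reference)) {
    s <- summaries[[nm]]
    for (m in meas) {
      p <- wilcoxon_rank_sum(s$replicates[[m]], ref$replicates[[m]])
      out[[length(out) + 1L]] <- data.frame(
        model = nm, measure = m, median = stats::median(s$replicates[[m]]),
        p_value = p, stars = stars_for(p))
    }
  }
  do.call(rbind, out)
}

stars_for <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
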