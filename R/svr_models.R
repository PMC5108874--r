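#' Regularization constants for censored SVR
#'
#' @param gamma Positive weight on the regression slacks.
#' @param mu Nonnegative weight on the second slack set (ranking constraints
#'   in the ranking model, censoring-upper constraints in the MRL model).
#' @return Object of class `hyper_params`.
#' @export
hyper_params <- function(gamma, mu = 0) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(gamma = gamma, mu = mu), class = "hyper_params")
}

#' Comparable-neighbor map
#'
#' For each subject `i`, finds its comparable neighbor `j(i)`: the subject
#' with the largest time strictly smaller than `y_i` whose position in the
#' event-time order relative to `i` is known. Under right censoring that is
#' exactly the subjects with an observed event before `y_i` (a censored `j`
#' with `y_j < y_i` tells nothing about order). Ties among candidates are
#' broken toward the smallest index.
#'
#' @param y Times.
#' @param delta Event indicators.
#' @return Integer vector of neighbor indices, `NA` where no comparable
#'   neighbor exists.
#' @export
comparable_neighbors <- function(y, delta) {
  n <- length(y)
  out <- rep(NA_integer_, n)
  ev <- which(delta == 1)
  if (!length(ev)) return(out)
  for (i in seq_len(n)) {
    cand <- ev[y[ev] < y[i]]
    if (!length(cand)) next
    out[i] <- cand[which.max(y[cand])]  # which.max returns first on ties
  }
  out
}

# ---- generic dual assembly -------------------------------------------------
#
# Every model is: min_w,b,slacks  (1/2) w'w + sum_k cap_k * slack_k
#   s.t.  s_k' u + bcoef_k * b >= rhs_k - slack_k,  slack_k >= 0,
# with u = (w'phi(x_1), ..., w'phi(x_n)).  The Wolfe dual over multipliers
# lambda (one per constraint row) is
#   min (1/2) lambda' (S K S') lambda - rhs' lambda
#   s.t. bcoef' lambda = 0,  0 <= lambda <= cap,
# and w = sum_i beta_i phi(x_i) with beta = S' lambda.

build_rows <- function(ds, hp, model_kind, mrl = NULL) {
  n <- n_subjects(ds)
  y <- ds$y; delta <- ds$delta
  S <- list(); bcoef <- c(); rhs <- c(); cap <- c(); tag <- c()
  e <- function(i, sgn = 1) { v <- numeric(n); v[i] <- sgn; v }
  for (i in seq_len(n)) {                       # lower: u_i >= y_i - eps_i
    S[[length(S) + 1L]] <- e(i)
    bcoef <- c(bcoef, 1); rhs <- c(rhs, y[i]); cap <- c(cap, hp$gamma)
    tag <- c(tag, "lower")
  }
  for (i in which(delta == 1)) {                # upper (events): u_i <= y_i + eps*_i
    S[[length(S) + 1L]] <- e(i, -1)
    bcoef <- c(bcoef, -1); rhs <- c(rhs, -y[i]); cap <- c(cap, hp$gamma)
    tag <- c(tag, "upper")
  }
  if (model_kind == "model2" && hp$mu > 0) {    # ranking over comparable pairs
    nb <- comparable_neighbors(y, delta)
    for (i in which(!is.na(nb))) {
      v <- e(i); v[nb[i]] <- v[nb[i]] - 1
      S[[length(S) + 1L]] <- v
      bcoef <- c(bcoef, 0); rhs <- c(rhs, y[i] - y[nb[i]])
      cap <- c(cap, hp$mu); tag <- c(tag, "rank")
    }
  }
  if (model_kind == "ssvr_mrl" && hp$mu > 0) {  # censored upper: u_i <= y_i + MRL_i + xi_i
    for (i in which(delta == 0)) {
      S[[length(S) + 1L]] <- e(i, -1)
      bcoef <- c(bcoef, -1); rhs <- c(rhs, -(y[i] + mrl[i]))
      cap <- c(cap, hp$mu); tag <- c(tag, "mrl")
    }
  }
  list(S = do.call(rbind, S), bcoef = bcoef, rhs = rhs, cap = cap, tag = tag)
}

# Compact dual variables. A subject's lower (u_i >= y_i - eps_i) and upper
# (u_i <= y_i + eps*_i, events only) regression multipliers alpha_i and
# alpha*_i enter the dual only through beta_i = alpha_i - alpha*_i and share
# the linear coefficient y_i, so they collapse exactly into one variable
# with box [-gamma, gamma] (events) or [0, gamma] (censored). Ranking and
# MRL multipliers stay separate (their linear coefficients differ).
build_vars <- function(ds, hp, model_kind, mrl = NULL) {
  n <- n_subjects(ds)
  y <- ds$y; delta <- ds$delta
  S <- diag(n)
  lin <- y
  bcoef <- rep(1, n)
  lo <- ifelse(delta == 1, -hp$gamma, 0)
  up <- rep(hp$gamma, n)
  if (model_kind == "model2" && hp$mu > 0) {
    nb <- comparable_neighbors(y, delta)
    for (i in which(!is.na(nb))) {
      v <- numeric(n); v[i] <- 1; v[nb[i]] <- -1
      S <- rbind(S, v)
      lin <- c(lin, y[i] - y[nb[i]]); bcoef <- c(bcoef, 0)
      lo <- c(lo, 0); up <- c(up, hp$mu)
    }
  }
  if (model_kind == "ssvr_mrl" && hp$mu > 0) {
    for (i in which(delta == 0)) {
      v <- numeric(n); v[i] <- -1
      S <- rbind(S, v)
      lin <- c(lin, -(y[i] + mrl[i])); bcoef <- c(bcoef, -1)
      lo <- c(lo, 0); up <- c(up, hp$mu)
    }
  }
  list(S = S, lin = lin, bcoef = bcoef, lo = lo, up = up)
}

# Box-and-one-equality QP via quadprog, with an escalating ridge because the
# dual Hessian S K S' is PSD but typically rank-deficient.
solve_dual_qp <- function(Q, lin, bcoef, lo, up) {
  k <- length(lin)
  # normalize each variable by its box scale so quadprog works on an O(1)
  # box whatever gamma/mu are; the ridge then stays harmless
  s <- pmax(abs(lo), abs(up)); s[s == 0] <- 1
  Qn <- Q * outer(s, s)
  linn <- lin * s
  bn <- bcoef * s
  Amat <- cbind(bn, diag(k), -diag(k))
  bvec <- c(0, lo / s, -up / s)
  scale <- max(mean(diag(Qn)), 1e-8)
  # Below ~1e-6*scale quadprog may return feasible-but-suboptimal points on
  # rank-deficient Hessians, so the ridge stays moderate and its bias is
  # removed by proximal-point iteration: re-solving with the linear term
  # lin + jit*lambda_t has the *unjittered* optimum as its fixed point.
  # small problems are refined to near machine precision (they back the
  # oracle-equivalence checks); large ones take a single regularized pass,
  # enough for statistical use at a fraction of the cost
  small <- k <= 100L
  max_prox <- if (small) 15L else 1L
  for (jit in scale * 10^seq(if (small) -6 else -4, -1)) {
    nu <- NULL
    ok <- TRUE
    f_prev <- Inf
    for (it in seq_len(max_prox)) {
      linp <- if (is.null(nu)) linn else linn + jit * nu
      sol <- tryCatch(
        quadprog::solve.QP(Qn + diag(jit, k), linp, Amat, bvec, meq = 1),
        error = function(e) NULL)
      if (is.null(sol)) { ok <- FALSE; break }
      nu <- sol$solution
      viol <- max(c(lo / s - nu, nu - up / s, abs(sum(bn * nu))))
      if (viol > 1e-6) { ok <- FALSE; break }
      f_cur <- 0.5 * sum(nu * drop(Qn %*% nu)) - sum(linn * nu)
      if (abs(f_prev - f_cur) <= 1e-12 * max(abs(f_cur), 1)) break
      f_prev <- f_cur
    }
    if (ok && !is.null(nu)) {
      lam <- pmin(pmax(nu * s, lo), up)
      if (small) lam <- polish_kkt(lam, Q, lin, bcoef, lo, up)
      return(lam)
    }
  }
  stop("fit error: dual QP did not solve (solver status: singular after ",
       "maximum ridge)")
}

# Active-set refinement of the (unjittered) dual started from the solver's
# answer: repeatedly solve the stationarity system
#   Q lambda - lin + nu * bcoef = 0  on the free set,  bcoef' lambda = 0
# by minimum-norm least squares, clip free variables that leave the box
# onto their bound, and release the worst KKT-sign violator among bound
# variables. Undoes the bias of the ridge and repairs a slightly wrong
# active set; the best feasible iterate (by dual objective) is returned.
polish_kkt <- function(lam, Q, lin, bcoef, lo, up, max_iter = 30L) {
  span <- pmax(up - lo, 1e-12)
  obj <- function(l) 0.5 * sum(l * drop(Q %*% l)) - sum(lin * l)
  feas <- function(l) all(l >= lo - 1e-9 * span) &&
    all(l <= up + 1e-9 * span) &&
    abs(sum(bcoef * l)) <= 1e-7 * max(sum(abs(l)), 1)
  best <- lam; f_best <- obj(lam)
  free <- lam > lo + 1e-7 * span & lam < up - 1e-7 * span
  cur <- lam
  for (it in seq_len(max_iter)) {
    Iset <- which(free); Bset <- which(!free)
    if (!length(Iset)) break
    rhs1 <- lin[Iset] -
      if (length(Bset)) drop(Q[Iset, Bset, drop = FALSE] %*% cur[Bset]) else 0
    rhs2 <- -sum(bcoef[Bset] * cur[Bset])
    A <- rbind(cbind(Q[Iset, Iset, drop = FALSE], bcoef[Iset]),
               c(bcoef[Iset], 0))
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    sol <- drop(sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% c(rhs1, rhs2)) / sv$d[pos]))
    nu <- sol[length(sol)]
    cand <- cur
    cand[Iset] <- sol[seq_along(Iset)]
    out_lo <- free & cand < lo - 1e-11 * span
    out_up <- free & cand > up + 1e-11 * span
    if (any(out_lo | out_up)) {
      # absorb box violators onto their bound and re-solve
      cand[out_lo] <- lo[out_lo]; cand[out_up] <- up[out_up]
      free[out_lo | out_up] <- FALSE
      cur <- cand
      next
    }
    cur <- pmin(pmax(cand, lo), up)
    # accept ties: the face solution can match the incumbent's objective
    # exactly (flat directions) while being the exact stationary point,
    # which the primal recovery is linearly sensitive to
    if (feas(cur) && obj(cur) <= f_best + 1e-9 * max(abs(f_best), 1)) {
      best <- cur; f_best <- min(obj(cur), f_best)
    }
    # KKT sign conditions at the bounds (multiplier nu from the lsq solve)
    g <- drop(Q %*% cur) - lin + nu * bcoef
    viol <- numeric(length(cur))
    at_lo <- !free & abs(cur - lo) <= 1e-9 * span
    at_up <- !free & abs(cur - up) <= 1e-9 * span
    viol[at_lo] <- pmax(-g[at_lo], 0)
    viol[at_up] <- pmax(g[at_up], 0)
    tol_g <- 1e-9 * max(abs(lin), 1)
    if (max(viol) <= tol_g) break
    free[which.max(viol)] <- TRUE
  }
  best
}

fit_censored_svr <- function(ds, kernel, hp, model_kind, mrl = NULL) {
  n <- n_subjects(ds)
  if (n < 2L) stop("need at least 2 subjects")
  if (model_kind == "ssvr_mrl") {
    if (is.null(mrl)) mrl <- mrl_augment(ds)
    if (length(mrl) != n) stop("mrl table not aligned with dataset")
  }
  degenerate <- sum(ds$delta) == 0L
  if (degenerate) {
    # all constraints are one-sided lower bounds: w = 0, b = max(y) is optimal
    warning("all observations censored: degenerate fit (constant model)")
    fit <- structure(list(model_kind = model_kind, beta = numeric(n),
                          b = max(ds$y), kernel = kernel, X_train = ds$X,
                          hp = hp, degenerate = TRUE,
                          w_linear = if (kernel$kind == "linear")
                            numeric(n_features(ds)) else NULL,
                          objective = 0),
                     class = "svr_fit")
    return(fit)
  }
  K <- gram(ds$X, ds$X, kernel)
  vars <- build_vars(ds, hp, model_kind, mrl)
  Q <- vars$S %*% K %*% t(vars$S)
  Q <- (Q + t(Q)) / 2
  lam <- solve_dual_qp(Q, vars$lin, vars$bcoef, vars$lo, vars$up)
  beta <- drop(t(vars$S) %*% lam)
  beta[abs(beta) < 1e-10] <- 0

  # bias from complementary slackness: a variable strictly inside its box
  # (and away from 0, where the collapsed pair carries no information) has
  # its constraint active: s_k' K beta + bcoef_k * b = lin_k
  sKb <- drop(vars$S %*% (K %*% beta))
  span <- vars$up - vars$lo
  interior <- which(vars$bcoef != 0 & abs(lam) > 1e-5 * span &
                    lam > vars$lo + 1e-5 * span &
                    lam < vars$up - 1e-5 * span)
  rows <- build_rows(ds, hp, model_kind, mrl)
  rKb <- drop(rows$S %*% (K %*% beta))
  if (length(interior)) {
    # median over active rows: robust to rows that are only near-active
    b <- stats::median((vars$lin[interior] - sKb[interior]) /
                         vars$bcoef[interior])
  } else {
    b <- optimal_bias(rows, rKb)
  }
  # the slack cost in b is piecewise linear: polish with the exact 1-d
  # minimizer when it improves on the complementary-slackness estimate
  b_alt <- optimal_bias(rows, rKb)
  cost_b <- function(bb) sum(rows$cap * pmax(0, rows$rhs - rKb -
                                                  rows$bcoef * bb))
  if (cost_b(b_alt) < cost_b(b)) b <- b_alt

  if (kernel$kind == "linear") {
    # primal active-set polish: the dual objective is quadratically flat
    # where the primal is linearly sensitive, so finish in primal space
    pol <- polish_primal_linear(ds$X, rows, drop(t(ds$X) %*% beta), b)
    if (!is.null(pol)) {
      # re-sync the expansion coefficients: X' (beta + d) = w_new
      dw <- pol$w - drop(t(ds$X) %*% beta)
      dbeta <- tryCatch(
        drop(ds$X %*% solve(crossprod(ds$X) +
                              diag(1e-10, ncol(ds$X)), dw)),
        error = function(e) NULL)
      if (!is.null(dbeta)) {
        beta <- beta + dbeta
        b <- pol$b
      }
    }
  }

  u <- drop(K %*% beta) + b
  rKb <- drop(rows$S %*% (K %*% beta))
  slack <- pmax(0, rows$rhs - rKb - rows$bcoef * b)
  obj <- 0.5 * sum(beta * drop(K %*% beta)) + sum(rows$cap * slack)

  structure(list(model_kind = model_kind, beta = beta, b = b,
                 kernel = kernel, X_train = ds$X, hp = hp,
                 degenerate = FALSE,
                 w_linear = if (kernel$kind == "linear")
                   drop(t(ds$X) %*% beta) else NULL,
                 objective = obj, fitted = u),
            class = "svr_fit")
}

# Primal active-set polish (linear kernel). Classify every constraint row
# at the current (w, b) as violated / active / inactive, then solve the
# equality-constrained QP "min 1/2||w||^2 + sum_viol cap_k * slack_k s.t.
# active rows tight" exactly through its KKT system. Iterates a few times
# so borderline rows can change state; returns the best consistent
# improvement or NULL.
polish_primal_linear <- function(X, rows, w, b) {
  A <- rows$S %*% X                     # row k: gradient of u-part
  bc <- rows$bcoef; rhs <- rows$rhs; cap <- rows$cap
  pobj <- function(w, b) {
    e <- drop(A %*% w) + bc * b - rhs
    0.5 * sum(w^2) + sum(cap * pmax(0, -e))
  }
  best <- list(w = w, b = b); f_best <- pobj(w, b)
  for (tol in max(abs(rhs), 1) * c(1e-8, 1e-6, 1e-4, 1e-3, 1e-2))
  for (it in 1:4) {
    e <- drop(A %*% best$w) + bc * best$b - rhs
    act <- which(abs(e) <= tol)
    vio <- which(e < -tol)
    if (!length(act)) break
    d <- length(best$w)
    gv <- if (length(vio))
      colSums(A[vio, , drop = FALSE] * cap[vio]) else numeric(d)
    gb <- sum(cap[vio] * bc[vio])
    Aa <- A[act, , drop = FALSE]; ba <- bc[act]
    # unknowns (w, b, nu): w - Aa' nu = gv ; -ba' nu = gb ; Aa w + ba b = rhs
    M <- rbind(cbind(diag(d), 0, -t(Aa)),
               c(numeric(d), 0, -ba),
               cbind(Aa, ba, matrix(0, length(act), length(act))))
    rv <- c(gv, gb, rhs[act])
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-12
    sol <- drop(sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rv) / sv$d[pos]))
    w_new <- sol[1:d]; b_new <- sol[d + 1]
    if (!all(is.finite(c(w_new, b_new)))) break
    f_new <- pobj(w_new, b_new)
    if (f_new < f_best - 1e-14 * max(abs(f_best), 1)) {
      best <- list(w = w_new, b = b_new); f_best <- f_new
    } else break
  }
  best
}

# Exact 1-d minimizer of the convex piecewise-linear slack cost in b, used
# when no constraint row is strictly active (e.g. tiny or separable data).
optimal_bias <- function(rows, sKb) {
  use <- which(rows$bcoef != 0 & rows$cap > 0)
  if (!length(use)) return(0)
  # slack_k(b) = max(0, a_k - bcoef_k * b), breakpoint at b = a_k / bcoef_k
  a <- rows$rhs[use] - sKb[use]
  bc <- rows$bcoef[use]; w <- rows$cap[use]
  brk <- sort(unique(a / bc))
  cost <- vapply(brk, function(b) sum(w * pmax(0, a - bc * b)), 0)
  brk[which.min(cost)]
}

#' Fit the standard censored SVR (regression constraints only)
#'
#' Minimizes `(1/2)||w||^2 + gamma * sum(eps_i + eps*_i)` subject to
#' `u_i >= y_i - eps_i` for everyone and `u_i <= y_i + eps*_i` for events
#' only: an uncensored subject pays for deviations on both sides, a
#' censored one only for predictions below its censoring time. Solved via
#' the Wolfe dual so any kernel can be used.
#'
#' @param ds Training [survival_dataset()].
#' @param kernel A [kernel_spec()] (linear by default).
#' @param hp A [hyper_params()].
#' @return Object of class `svr_fit` with the kernel-expansion coefficients
#'   `beta`, bias `b`, `w_linear` (linear kernel only), the primal
#'   `objective`, and a `degenerate` flag (all-censored training data).
#' @export
fit_model1 <- function(ds, kernel = kernel_spec("linear"),
                       hp = hyper_params(1)) {
  fit_censored_svr(ds, kernel, hp, "model1")
}

#' Fit censored SVR with ranking and regression constraints
#'
#' Adds to [fit_model1()]'s program one ranking constraint per subject with
#' a comparable neighbor: `u_i - u_j(i) >= y_i - y_j(i) - xi_i`, with the
#' `xi` slacks weighted by `mu`. With `mu = 0` the model reduces exactly to
#' the standard one.
#'
#' @inheritParams fit_model1
#' @return An `svr_fit`.
#' @export
fit_model2 <- function(ds, kernel = kernel_spec("linear"),
                       hp = hyper_params(1)) {
  fit_censored_svr(ds, kernel, hp, "model2")
}

#' Fit the two-sided MRL-augmented censored SVR
#'
#' Treats each censored subject's unknown event time as censoring time plus
#' Kaplan-Meier mean residual lifetime and penalizes predictions above that
#' sum: `u_i <= y_i + MRL_i + xi_i` for `delta_i = 0`, with the `xi` slacks
#' weighted by `mu`. For events the extra constraint is vacuous, so on
#' all-event data the fit coincides with [fit_model1()].
#'
#' @inheritParams fit_model1
#' @param mrl Optional [mrl_augment()] table; computed from `ds` if missing.
#' @return An `svr_fit`.
#' @export
fit_ssvr_mrl <- function(ds, kernel = kernel_spec("linear"),
                         hp = hyper_params(1), mrl = NULL) {
  fit_censored_svr(ds, kernel, hp, "ssvr_mrl", mrl = mrl)
}

#' Prognostic index for new data
#'
#' Evaluates the kernel expansion `u(x) = sum_i beta_i k(x_i, x) + b`.
#' Higher values predict longer survival.
#'
#' @param object An `svr_fit`.
#' @param newdata Numeric matrix (or `survival_dataset`) with the training
#'   dimensionality, on the training standardization scale.
#' @param ... Unused.
#' @return Numeric vector of prognostic indices.
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "survival_dataset")) newdata$X
       else as.matrix(newdata)
  if (ncol(X) != ncol(object$X_train))
    stop("newdata has ", ncol(X), " features; model was trained with ",
         ncol(object$X_train))
  drop(gram(X, object$X_train, object$kernel) %*% object$beta) + object$b
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf("censored SVR fit [%s, %s kernel]: n=%d, gamma=%g, mu=%g%s\n",
              x$model_kind, x$kernel$kind, nrow(x$X_train), x$hp$gamma,
              x$hp$mu, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Cox proportional hazards baseline
#'
#' Fits a Cox model (Breslow tie handling) on all features and returns its
#' negated linear predictor as the prognostic index, so that -- as with the
#' SVR models -- higher values predict longer survival. A rank-deficient or
#' non-converging design falls back to a lightly ridge-penalized fit.
#'
#' @param ds Training [survival_dataset()] with at least one event.
#' @return Object of class `cox_baseline` with `coef` and a `predict`
#'   method returning the prognostic index.
#' @export
fit_cox_baseline <- function(ds) {
  if (sum(ds$delta) == 0) stop("Cox baseline needs at least one event")
  X <- ds$X
  srv <- survival::Surv(ds$y, ds$delta)
  fit <- tryCatch(suppressWarnings({
    f <- survival::coxph(srv ~ X, ties = "breslow",
                         control = survival::coxph.control(iter.max = 50))
    if (any(is.na(stats::coef(f)))) stop("rank deficient")
    f
  }), error = function(e) NULL)
  if (is.null(fit)) {
    message("Cox baseline: falling back to ridge-penalized fit")
    fit <- suppressWarnings(
      survival::coxph(srv ~ survival::ridge(X, theta = 1e-3, scale = FALSE),
                      ties = "breslow"))
  }
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(coef = unname(cf)), class = "cox_baseline")
}

#' @rdname fit_cox_baseline
#' @param object A `cox_baseline`.
#' @param newdata Matrix or `survival_dataset`.
#' @param ... Unused.
#' @export
predict.cox_baseline <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "survival_dataset")) newdata$X
       else as.matrix(newdata)
  -drop(X %*% object$coef)
}

#' Save / load a fitted SVR model as structured text (JSON)
#'
#' @param fit An `svr_fit`.
#' @param path File path.
#' @param params Optional standardization parameters to store alongside.
#' @export
save_svr_model <- function(fit, path, params = NULL) {
  obj <- list(model_kind = fit$model_kind, beta = fit$beta, b = fit$b,
              kernel = fit$kernel[!vapply(fit$kernel, is.null, TRUE)],
              X_train = fit$X_train, hp = unclass(fit$hp),
              degenerate = fit$degenerate, w_linear = fit$w_linear,
              standardization = params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
}

#' @rdname save_svr_model
#' @return `load_svr_model` returns the restored `svr_fit` (with attribute
#'   `"standardization"` when parameters were stored).
#' @export
load_svr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- kernel_spec(obj$kernel$kind, degree = obj$kernel$degree,
                    gamma_rbf = obj$kernel$gamma_rbf)
  fit <- structure(list(model_kind = obj$model_kind, beta = obj$beta,
                        b = obj$b, kernel = ks,
                        X_train = as.matrix(obj$X_train),
                        hp = hyper_params(obj$hp$gamma, obj$hp$mu),
                        degenerate = isTRUE(obj$degenerate),
                        w_linear = obj$w_linear),
                   class = "svr_fit")
  attr(fit, "standardization") <- obj$standardization
  fit
}
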