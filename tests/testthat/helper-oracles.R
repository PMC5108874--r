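# Shared fixtures and independent oracles. Everything here is built in code
# at test time; no stored data.

# small random right-censored dataset, integer-ish times to provoke ties
tiny_surv <- function(n, seed, d = 2L, tie_times = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- if (tie_times) sample(1:5, n, replace = TRUE) + 0
       else rexp(n) + 0.1
  delta <- rbinom(n, 1, 0.7)
  if (sum(delta) == 0) delta[sample(n, 1)] <- 1L
  survival_dataset(X, y, delta)
}

# Independent primal solve of the printed optimization programs (linear
# kernel): variables (w, b, eps, eps*, xi), slacks entering linearly, tiny
# quadratic regularization on b and the slacks so quadprog's PD requirement
# is met. Deliberately does NOT reuse the package's dual machinery.
primal_oracle <- function(ds, hp, model_kind = "model1", mrl = NULL,
                          reg = 1e-8) {
  X <- ds$X; y <- ds$y; delta <- ds$delta
  n <- nrow(X); d <- ncol(X)
  ev <- which(delta == 1)

  xi_idx <- integer(0)        # subjects owning a xi slack
  if (model_kind == "model2") {
    nb <- comparable_neighbors(y, delta)
    xi_idx <- which(!is.na(nb))
  } else if (model_kind == "ssvr_mrl") {
    if (is.null(mrl)) mrl <- mrl_augment(ds)
    xi_idx <- which(delta == 0)
  }
  nv <- d + 1 + n + length(ev) + length(xi_idx)
  iw <- 1:d; ib <- d + 1
  ie <- d + 1 + seq_len(n)
  ies <- d + 1 + n + seq_along(ev)
  ix <- d + 1 + n + length(ev) + seq_along(xi_idx)

  D <- diag(c(rep(1, d), rep(reg, nv - d)))
  dv <- numeric(nv)
  dv[ie] <- -hp$gamma; dv[ies] <- -hp$gamma; dv[ix] <- -hp$mu

  rows <- list(); rhs <- c()
  add <- function(a, r) { rows[[length(rows) + 1]] <<- a; rhs <<- c(rhs, r) }
  for (i in 1:n) {                       # w'x_i + b + eps_i >= y_i
    a <- numeric(nv); a[iw] <- X[i, ]; a[ib] <- 1; a[ie[i]] <- 1
    add(a, y[i])
  }
  for (k in seq_along(ev)) {             # -(w'x_i + b) + eps*_i >= -y_i
    i <- ev[k]
    a <- numeric(nv); a[iw] <- -X[i, ]; a[ib] <- -1; a[ies[k]] <- 1
    add(a, -y[i])
  }
  if (model_kind == "model2") {
    for (k in seq_along(xi_idx)) {       # w'(x_i - x_j) + xi_i >= y_i - y_j
      i <- xi_idx[k]; j <- nb[i]
      a <- numeric(nv); a[iw] <- X[i, ] - X[j, ]; a[ix[k]] <- 1
      add(a, y[i] - y[j])
    }
  } else if (model_kind == "ssvr_mrl") {
    for (k in seq_along(xi_idx)) {       # -(w'x_i + b) + xi_i >= -(y_i+MRL_i)
      i <- xi_idx[k]
      a <- numeric(nv); a[iw] <- -X[i, ]; a[ib] <- -1; a[ix[k]] <- 1
      add(a, -(y[i] + mrl[i]))
    }
  }
  for (s in c(ie, ies, ix)) {            # slack nonnegativity
    a <- numeric(nv); a[s] <- 1
    add(a, 0)
  }
  A <- t(do.call(rbind, rows))
  # proximal iteration removes the bias of the tiny regularization on the
  # linear variables (fixed point = optimum of the reg-free program)
  sol <- NULL
  for (it in 1:20) {
    dv_t <- dv
    if (!is.null(sol)) dv_t[-iw] <- dv[-iw] + reg * sol[-iw]
    prev <- sol
    sol <- quadprog::solve.QP(D, dv_t, A, rhs)$solution
    if (!is.null(prev) && max(abs(sol - prev)) < 1e-10) break
  }
  w <- sol[iw]; b <- sol[ib]
  slk <- pmax(sol[-(1:(d + 1))], 0)
  obj <- 0.5 * sum(w^2) + hp$gamma * sum(slk[seq_len(n + length(ev))]) +
    hp$mu * sum(slk[n + length(ev) + seq_along(xi_idx)])
  list(w = w, b = b, objective = obj)
}

# brute-force c-index by explicit pair loop under the comparability rule
c_index_loop <- function(u, y, delta) {
  num <- 0; den <- 0
  n <- length(u)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (y[i] < y[j] && delta[i] == 1) {
      den <- den + 1
      if (u[i] < u[j]) num <- num + 1
      else if (u[i] == u[j]) num <- num + 0.5
    }
  }
  num / den
}

# 1-d partial-likelihood maximization for a binary covariate by golden
# section (Breslow ties), independent of survival::coxph
cox_loglik_binary <- function(beta, y, delta, z) {
  ll <- 0
  for (t in unique(y[delta == 1])) {
    dset <- which(y == t & delta == 1)
    risk <- which(y >= t)
    ll <- ll + beta * sum(z[dset]) -
      length(dset) * log(sum(exp(beta * z[risk])))
  }
  ll
}
golden_cox <- function(y, delta, z, lower = -8, upper = 8) {
  stats::optimize(function(b) -cox_loglik_binary(b, y, delta, z),
                  c(lower, upper))$minimum
}
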