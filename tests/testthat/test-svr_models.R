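lin <- kernel_spec("linear")

test_that("comparable_neighbors applies the comparability rule", {
  # censored-at-2 is comparable to event-at-1; event-at-3 can only look back
  # to the event, not to the censored subject
  expect_equal(comparable_neighbors(c(1, 2, 3), c(1, 0, 1)),
               c(NA, 1L, 1L))
  expect_equal(comparable_neighbors(c(1, 2, 3), c(0, 0, 0)),
               rep(NA_integer_, 3))
  expect_equal(comparable_neighbors(c(3, 1, 2), c(1, 1, 1)),
               c(3L, NA, 2L))
  # ties among candidates break toward the smallest index
  expect_equal(comparable_neighbors(c(1, 1, 2), c(1, 1, 1))[3], 1L)
})

test_that("model 1 interpolates noiseless uncensored points", {
  ds <- survival_dataset(matrix(c(0, 1), 2, 1), c(1, 2), c(1, 1))
  f <- fit_model1(ds, lin, hyper_params(1e4))
  expect_lt(max(abs(predict(f, ds) - ds$y)), 1e-3)
  expect_equal(unname(f$w_linear), 1, tolerance = 1e-3)
  # dual expansion == primal w'x + b
  xs <- matrix(seq(-2, 2, 0.5), ncol = 1)
  expect_equal(predict(f, xs), drop(xs %*% f$w_linear) + f$b,
               tolerance = 1e-6)
})

test_that("predict is the kernel expansion", {
  f <- structure(list(model_kind = "model1", beta = c(1, -1), b = 0,
                      kernel = lin, X_train = matrix(c(1, 2), 2, 1),
                      hp = hyper_params(1), degenerate = FALSE,
                      w_linear = NULL),
                 class = "svr_fit")
  expect_equal(predict(f, matrix(3, 1, 1)), 1 * 3 - 1 * 6)
  f$beta <- c(0, 0); f$b <- 4.5
  expect_equal(predict(f, matrix(c(-1, 7), 2, 1)), c(4.5, 4.5))
  expect_error(predict(f, matrix(0, 1, 2)), "features")
})

test_that("all-censored data produce a flagged degenerate fit", {
  ds <- survival_dataset(matrix(rnorm(5), 5, 1), 1:5, rep(0L, 5))
  expect_warning(f <- fit_model1(ds, lin, hyper_params(1)), "degenerate")
  expect_true(f$degenerate)
  expect_equal(unname(predict(f, ds)), rep(5, 5))  # constant at max y
})

test_that("analytic reductions hold", {
  ds <- tiny_surv(25, seed = 31, d = 3, tie_times = FALSE)
  f1 <- fit_model1(ds, lin, hyper_params(2))
  # mu = 0: both extended models collapse to model 1
  f2 <- fit_model2(ds, lin, hyper_params(2, 0))
  f3 <- fit_ssvr_mrl(ds, lin, hyper_params(2, 0))
  expect_equal(predict(f2, ds), predict(f1, ds), tolerance = 1e-5)
  expect_equal(predict(f3, ds), predict(f1, ds), tolerance = 1e-5)

  # all events: the MRL constraints are vacuous
  dse <- survival_dataset(ds$X, ds$y, rep(1L, 25))
  fe1 <- fit_model1(dse, lin, hyper_params(2))
  fe3 <- fit_ssvr_mrl(dse, lin, hyper_params(2, 5))
  expect_equal(predict(fe3, dse), predict(fe1, dse), tolerance = 1e-5)
  expect_equal(fe3$objective, fe1$objective, tolerance = 1e-6)
})

test_that("large mu forces the MRL upper constraint", {
  set.seed(7)
  X <- matrix(rnorm(30), 30, 1)
  y <- 5 + drop(X) + rnorm(30, sd = 0.1)
  delta <- rep(1L, 30); delta[15] <- 0L
  ds <- survival_dataset(X, pmax(y, 0.1), delta)
  mrl <- mrl_augment(ds)
  mrl[15] <- 1e-3  # tiny residual lifetime
  f <- fit_ssvr_mrl(ds, lin, hyper_params(1, 1e4), mrl = mrl)
  expect_lte(predict(f, ds)[15], ds$y[15] + mrl[15] + 1e-4)
})

test_that("ranking constraints enforce order on monotone data", {
  set.seed(9)
  x <- seq(0, 1, length.out = 30)
  ds <- survival_dataset(matrix(x, ncol = 1), 1 + x, rep(1L, 30))
  f <- fit_model2(ds, lin, hyper_params(1, 100))
  xte <- matrix(seq(0.05, 0.95, length.out = 20), ncol = 1)
  u <- predict(f, xte)
  expect_equal(c_index(u, 1 + drop(xte), rep(1, 20)), 1)
})

test_that("training loss is non-increasing in gamma", {
  ds <- tiny_surv(30, seed = 13, d = 2, tie_times = FALSE)
  loss <- function(f) {
    u <- predict(f, ds)
    sum(ifelse(ds$delta == 1, abs(u - ds$y), pmax(ds$y - u, 0)))
  }
  losses <- vapply(c(0.01, 0.1, 1, 10, 100),
                   function(g) loss(fit_model1(ds, lin, hyper_params(g))), 0)
  expect_true(all(diff(losses) <= 1e-6))
})

test_that("weight direction is recovered on noiseless linear data", {
  set.seed(21)
  w0 <- c(2, -1, 0.5)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- 10 + drop(X %*% w0)
  ds <- survival_dataset(X, pmax(y, 0.01), rep(1L, 120))
  f <- fit_model1(ds, lin, hyper_params(100))
  cs <- sum(f$w_linear * w0) / sqrt(sum(f$w_linear^2) * sum(w0^2))
  expect_gt(cs, 0.99)
})

test_that("Cox baseline has the right orientation and null behavior", {
  set.seed(5)
  z <- rep(0:1, each = 60)
  y <- rexp(120, rate = ifelse(z == 1, 3, 1))  # z=1 dies faster
  ds <- survival_dataset(matrix(z, ncol = 1), y, rep(1L, 120))
  f <- fit_cox_baseline(ds)
  expect_gt(f$coef[1], 0)                      # higher hazard for z=1
  u <- predict(f, ds)
  expect_gt(mean(u[z == 0]) - mean(u[z == 1]), 0)  # higher index = longer
  # matches the independent golden-section partial-likelihood oracle
  expect_equal(f$coef[1], golden_cox(y, rep(1L, 120), z), tolerance = 1e-4)

  # independent covariate: small coefficient, c-index near 1/2
  set.seed(6)
  ds0 <- survival_dataset(matrix(rnorm(400), 400, 1), rexp(400) + .01,
                          rep(1L, 400))
  f0 <- fit_cox_baseline(ds0)
  expect_lt(abs(f0$coef[1]), 0.15)
  expect_lt(abs(c_index(predict(f0, ds0), ds0$y, ds0$delta) - 0.5), 0.06)

  # duplicating the whole sample leaves the coefficients unchanged
  dsd <- survival_dataset(rbind(ds$X, ds$X), c(y, y), rep(1L, 240))
  expect_equal(fit_cox_baseline(dsd)$coef, f$coef, tolerance = 1e-6)
})

test_that("models fit through nonlinear kernels", {
  ds <- tiny_surv(25, seed = 55, d = 2, tie_times = FALSE)
  for (ks in list(kernel_spec("rbf", gamma_rbf = 0.5),
                  kernel_spec("polynomial", degree = 2))) {
    f <- fit_ssvr_mrl(ds, ks, hyper_params(1, 1))
    expect_true(all(is.finite(predict(f, ds))))
  }
})

test_that("model save/load round-trips predictions", {
  ds <- tiny_surv(15, seed = 77, d = 2, tie_times = FALSE)
  f <- fit_model1(ds, kernel_spec("rbf", gamma_rbf = 0.3), hyper_params(1))
  path <- withr::local_tempfile(fileext = ".json")
  save_svr_model(f, path)
  g <- load_svr_model(path)
  expect_equal(predict(g, ds), predict(f, ds), tolerance = 1e-10)
})
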