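test_that("load_dataset parses, validates and types a small CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,age,grade",
               "1,1,50,A", "2,0,60,B", "3,1,70,Unknown"), f)
  ds <- load_dataset(f, "time", "event")
  expect_s3_class(ds, "survival_dataset")
  expect_equal(n_subjects(ds), 3L)
  expect_equal(n_features(ds), 2L)
  expect_equal(ds$y, c(1, 2, 3))
  expect_equal(ds$delta, c(1L, 0L, 1L))
  expect_equal(ds$schema[[1]]$kind, "continuous")
  gr <- ds$schema[[2]]
  expect_equal(gr$kind, "categorical")
  expect_setequal(gr$categories, c("A", "B", "Unknown"))

  # missing categorical becomes Unknown; missing continuous drops the row
  writeLines(c("time,event,age,grade", "1,1,50,", "2,0,,B", "3,1,70,A"), f)
  expect_message(ds2 <- load_dataset(f, "time", "event"), "dropping 1")
  expect_equal(n_subjects(ds2), 2L)
  expect_true("Unknown" %in% ds2$schema[[2]]$categories)
})

test_that("load_dataset rejects bad schemas and values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,x", "0,1,1", "2,0,2", "3,1,3"), f)
  expect_error(load_dataset(f, "time", "event"), "non-positive time")
  expect_error(load_dataset(f, "wrong", "event"), "not found")
  writeLines(c("time,event,x", "1,dead,1", "2,alive,2"), f)
  expect_error(load_dataset(f, "time", "event"), "outside \\{0,1\\}")
  ds <- load_dataset(f, "time", "event",
                     schema_hints = list(event = c(alive = 0, dead = 1)))
  expect_equal(ds$delta, c(1L, 0L))
})

test_that("write + reload round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,event,age,grade",
               "1.25,1,50.5,A", "2.5,0,60.25,B", "3,1,70,A"), f)
  ds <- load_dataset(f, "time", "event")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f2)
  ds2 <- load_dataset(f2, "time", "event")
  expect_identical(ds2$X, ds$X)
  expect_identical(ds2$y, ds$y)
  expect_identical(ds2$delta, ds$delta)
})

test_that("split_train_test sizes, disjointness, determinism", {
  ds <- tiny_surv(6, seed = 1)
  sp <- split_train_test(ds, 2 / 3, seed = 1)
  expect_equal(n_subjects(sp$train), 4L)
  expect_equal(n_subjects(sp$test), 2L)
  sp2 <- split_train_test(ds, 2 / 3, seed = 1)
  expect_identical(sp$train$X, sp2$train$X)
  expect_identical(sp$test$y, sp2$test$y)

  # partition property over several draws
  ds2 <- tiny_surv(41, seed = 2)
  for (s in 1:5) {
    sp <- split_train_test(ds2, 0.6, seed = s)
    ally <- sort(c(sp$train$y + 1e3 * sp$train$X[, 1],
                   sp$test$y + 1e3 * sp$test$X[, 1]))
    expect_equal(ally, sort(ds2$y + 1e3 * ds2$X[, 1]))
    expect_true(sum(sp$train$delta) >= 1)
  }

  # protocol-scale arithmetic: n=542 at 2/3
  big <- tiny_surv(542, seed = 3)
  sp <- split_train_test(big, 2 / 3, seed = 9)
  expect_equal(n_subjects(sp$train), 362L)
  expect_equal(n_subjects(sp$test), 180L)

  none <- survival_dataset(matrix(rnorm(4), 4, 1), 1:4, rep(0L, 4))
  expect_error(split_train_test(none, 2 / 3, 1), "no events")
})

test_that("standardize uses training statistics only", {
  tr <- survival_dataset(matrix(c(0, 2), 2, 1), c(1, 2), c(1, 1))
  te <- survival_dataset(matrix(c(4), 1, 1), 3, 1L)
  st <- standardize(tr, list(te))
  expect_equal(unname(st$train$X[, 1]), c(-1, 1))  # population SD = 1
  expect_equal(unname(st$others[[1]]$X[, 1]), 3)   # (4-1)/1, train params

  cst <- survival_dataset(matrix(5, 3, 1), 1:3, c(1, 1, 1))
  expect_equal(unname(standardize(cst)$train$X[, 1]), c(0, 0, 0))

  # categorical untouched; continuous mean 0 / SD 1 within 1e-12
  set.seed(4)
  X <- cbind(rnorm(50, 3, 2), sample(1:3, 50, TRUE))
  sc <- list(feature_schema("a", "continuous", range = range(X[, 1])),
             feature_schema("g", "categorical", categories = c("p", "q", "r")))
  ds <- survival_dataset(X, rexp(50) + .1, rbinom(50, 1, .5), sc)
  out <- standardize(ds)$train
  expect_equal(mean(out$X[, 1]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out$X[, 1]^2)), 1, tolerance = 1e-12)
  expect_identical(out$X[, 2], ds$X[, 2])
})

test_that("constructor invariants are enforced", {
  expect_error(survival_dataset(matrix(1, 2, 1), c(1, -1), c(1, 1)),
               "non-positive")
  expect_error(survival_dataset(matrix(1, 2, 1), c(1, 2), c(1, 2)),
               "outside \\{0,1\\}")
  expect_error(survival_dataset(matrix(1, 2, 1), c(1, 2, 3), c(1, 1, 1)),
               "matching")
})
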