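#' Feature schema entry
#'
#' Describes one feature of a survival dataset: its name, whether it is
#' continuous or categorical, its category labels (categorical) or its
#' observed training range (continuous, needed by the clinical kernel).
#'
#' @param name Feature name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param categories Character vector of category labels (categorical only).
#' @param range Numeric `c(min, max)` observed on training data
#'   (continuous only).
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(name, kind = c("continuous", "categorical"),
                           categories = NULL, range = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 1L)
      stop("categorical feature '", name, "' needs >= 1 category")
  } else {
    if (!is.null(range)) {
      if (length(range) != 2L || any(!is.finite(range)) || range[2] < range[1])
        stop("continuous feature '", name, "' needs range with max >= min")
    }
  }
  structure(list(name = name, kind = kind,
                 categories = categories, range = range),
            class = "feature_schema")
}

#' Right-censored survival dataset
#'
#' Container for a feature matrix `X`, strictly positive follow-up times `y`,
#' event indicators `delta` (1 = event, 0 = right-censored) and a per-feature
#' schema. Categorical features are stored integer-coded (1-based index into
#' the schema's category list).
#'
#' @param X Numeric matrix, one row per subject.
#' @param y Positive numeric vector of survival/censoring times.
#' @param delta Integer vector of event indicators in \{0, 1\}.
#' @param schema List of [feature_schema()] objects, one per column of `X`;
#'   if `NULL`, all columns are treated as continuous.
#' @return An object of class `survival_dataset` with fields `X`, `y`,
#'   `delta`, `schema`.
#' @export
survival_dataset <- function(X, y, delta, schema = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  delta <- as.integer(delta)
  n <- nrow(X)
  if (length(y) != n || length(delta) != n)
    stop("X, y and delta must have matching lengths")
  if (any(!is.finite(y)) || any(y <= 0)) {
    bad <- which(!is.finite(y) | y <= 0)[1L]
    stop("non-positive or missing time at row ", bad)
  }
  if (!all(delta %in% c(0L, 1L)))
    stop("event indicator outside {0,1} at row ",
         which(!(delta %in% c(0L, 1L)))[1L])
  if (any(!is.finite(X)))
    stop("X contains missing or non-finite entries")
  if (is.null(schema)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
    schema <- lapply(seq_len(ncol(X)), function(j)
      feature_schema(nm[j], "continuous", range = range(X[, j])))
  }
  if (length(schema) != ncol(X))
    stop("schema length must equal ncol(X)")
  if (is.null(colnames(X)))
    colnames(X) <- vapply(schema, `[[`, "", "name")
  structure(list(X = X, y = y, delta = delta, schema = schema),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: n=%d, d=%d, events=%d (%.1f%%)\n",
              nrow(x$X), ncol(x$X), sum(x$delta),
              100 * mean(x$delta)))
  invisible(x)
}

#' Number of subjects / features
#' @param ds A `survival_dataset`.
#' @return Integer count.
#' @export
n_subjects <- function(ds) nrow(ds$X)

#' @rdname n_subjects
#' @export
n_features <- function(ds) ncol(ds$X)

#' Load a survival dataset from delimited text
#'
#' Reads a CSV/TSV with header, validates times and event indicators, and
#' infers per-feature kinds (numeric columns become continuous, everything
#' else categorical). Missing categorical values become an explicit
#' `"Unknown"` category; rows with missing continuous values are dropped
#' with a message.
#'
#' @param path File path to delimited text with a header row.
#' @param time_col,event_col Names of the time and event columns.
#' @param schema_hints Optional named list. Entries may be `"continuous"` /
#'   `"categorical"` to force a feature's kind, or, for `event_col`, a named
#'   vector mapping labels to 0/1 (e.g. `c(alive = 0, dead = 1)`).
#' @param delimiter Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A [survival_dataset()].
#' @export
load_dataset <- function(path, time_col, event_col, schema_hints = NULL,
                         delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  for (col in c(time_col, event_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path)

  ev <- df[[event_col]]
  if (!is.null(schema_hints) && event_col %in% names(schema_hints)) {
    map <- schema_hints[[event_col]]
    ev <- unname(map[as.character(ev)])
  }
  ev <- suppressWarnings(as.numeric(ev))
  if (any(is.na(ev)) || !all(ev %in% c(0, 1)))
    stop("event column '", event_col,
         "' has values outside {0,1}; supply schema_hints to map labels")

  y <- suppressWarnings(as.numeric(df[[time_col]]))
  if (any(is.na(y)))
    stop("time column '", time_col, "' has non-numeric entries")
  if (any(y <= 0))
    stop("non-positive time at row ", which(y <= 0)[1L])

  feat <- setdiff(names(df), c(time_col, event_col))
  kinds <- vapply(feat, function(f) {
    hint <- schema_hints[[f]]
    if (is.character(hint) && length(hint) == 1L &&
        hint %in% c("continuous", "categorical")) return(hint)
    if (is.numeric(df[[f]])) "continuous" else "categorical"
  }, "")

  # drop rows with missing continuous values (logged), keep n in sync
  cont <- feat[kinds == "continuous"]
  if (length(cont)) {
    keep <- !Reduce(`|`, lapply(cont, function(f) is.na(df[[f]])), FALSE)
    if (any(!keep)) {
      message("dropping ", sum(!keep),
              " row(s) with missing continuous values")
      df <- df[keep, , drop = FALSE]
      y <- y[keep]; ev <- ev[keep]
    }
  }

  schema <- vector("list", length(feat))
  Xcols <- vector("list", length(feat))
  for (j in seq_along(feat)) {
    f <- feat[j]
    if (kinds[j] == "continuous") {
      v <- as.numeric(df[[f]])
      schema[[j]] <- feature_schema(f, "continuous", range = range(v))
      Xcols[[j]] <- v
    } else {
      v <- as.character(df[[f]])
      v[is.na(v)] <- "Unknown"
      cats <- unique(v)
      # keep Unknown last for readability
      if ("Unknown" %in% cats) cats <- c(setdiff(cats, "Unknown"), "Unknown")
      schema[[j]] <- feature_schema(f, "categorical", categories = cats)
      Xcols[[j]] <- match(v, cats)
    }
  }
  X <- do.call(cbind, Xcols)
  colnames(X) <- feat
  survival_dataset(X, y, as.integer(ev), schema)
}

#' Write a survival dataset back to delimited text
#'
#' Inverse of [load_dataset()]: categorical codes are expanded back to their
#' labels.
#'
#' @param ds A `survival_dataset`.
#' @param path Output file path.
#' @param time_col,event_col Column names to use.
#' @param delimiter Field delimiter.
#' @export
write_dataset <- function(ds, path, time_col = "time", event_col = "event",
                          delimiter = ",") {
  cols <- list()
  cols[[time_col]] <- ds$y
  cols[[event_col]] <- ds$delta
  for (j in seq_along(ds$schema)) {
    sc <- ds$schema[[j]]
    cols[[sc$name]] <- if (sc$kind == "categorical")
      sc$categories[ds$X[, j]] else ds$X[, j]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
}

subset_rows <- function(ds, idx) {
  survival_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$delta[idx],
                   ds$schema)
}

#' Select a subset of features by name or index
#' @param ds A `survival_dataset`.
#' @param features Character names or integer indices of features to keep.
#' @return A `survival_dataset` with the reduced feature set.
#' @export
subset_features <- function(ds, features) {
  if (is.character(features))
    features <- match(features, colnames(ds$X))
  if (any(is.na(features))) stop("unknown feature requested")
  survival_dataset(ds$X[, features, drop = FALSE], ds$y, ds$delta,
                   ds$schema[features])
}

#' Random train/test split
#'
#' Partitions the rows into a training set of size `ceiling(n * fraction)`
#' and a test set with the rest. Deterministic for a fixed seed. If the
#' training part ends up without any event the split is redrawn (bounded
#' number of retries).
#'
#' @param ds A `survival_dataset`.
#' @param train_fraction Proportion in (0, 1); default 2/3.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(ds, train_fraction = 2 / 3, seed = 1L) {
  n <- n_subjects(ds)
  if (n < 3L) stop("need at least 3 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0,1)")
  if (sum(ds$delta) == 0L)
    stop("dataset has no events; cannot produce a usable training split")
  n_train <- ceiling(n * train_fraction)
  rng <- local_rng(seed)
  for (try in 1:50) {
    idx <- sample.int(n, n_train)
    if (sum(ds$delta[idx]) >= 1L)
      return(list(train = subset_rows(ds, sort(idx)),
                  test = subset_rows(ds, sort(setdiff(seq_len(n), idx)))))
  }
  stop("could not draw a training split containing an event")
}

#' Standardize continuous features by training statistics
#'
#' Centers and scales continuous features using the training mean and
#' standard deviation (denominator `n`, i.e. the population convention);
#' categorical features are untouched. The same transformation is applied
#' to any additional datasets. A constant feature is scaled by 1.
#'
#' @param train Training `survival_dataset`.
#' @param others Optional list of further datasets sharing the schema.
#' @return List with `train`, `others` (transformed) and `params`
#'   (per-feature `center`/`scale`, reusable via [apply_standardization()]).
#' @export
standardize <- function(train, others = list()) {
  d <- n_features(train)
  center <- numeric(d); scale <- rep(1, d)
  for (j in seq_len(d)) {
    if (train$schema[[j]]$kind != "continuous") next
    v <- train$X[, j]
    center[j] <- mean(v)
    s <- sqrt(mean((v - center[j])^2))
    scale[j] <- if (s > 0) s else 1
  }
  params <- list(center = center, scale = scale)
  list(train = apply_standardization(train, params),
       others = lapply(others, apply_standardization, params = params),
       params = params)
}

#' @rdname standardize
#' @param ds Dataset to transform.
#' @param params Parameters from a previous [standardize()] call.
#' @export
apply_standardization <- function(ds, params) {
  X <- sweep(sweep(ds$X, 2, params$center, "-"), 2, params$scale, "/")
  survival_dataset(X, ds$y, ds$delta, ds$schema)
}

# Reset the RNG stream. Every randomized entry point calls this with an
# explicit (child) seed, so results are reproducible from the master seed.
local_rng <- function(seed) {
  set.seed(as.integer(seed) %% 2147483647L)
  invisible(NULL)
}

# Deterministic 31-bit child seed from a master seed and stream indices.
child_seed <- function(seed, ...) {
  ix <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (v in ix) h <- (h * 1103515245 + v * 12345 + 2027) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}
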