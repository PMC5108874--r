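#' Kernel specification
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"rbf"`, `"clinical"`.
#' @param degree Polynomial degree (positive integer; polynomial kernel).
#' @param gamma_rbf RBF bandwidth parameter, `exp(-gamma_rbf * ||a-b||^2)`.
#' @param schema List of [feature_schema()] objects (clinical kernel only);
#'   continuous entries must carry their training `range`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "rbf", "clinical"),
                        degree = NULL, gamma_rbf = NULL, schema = NULL) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    if (is.null(degree) || degree < 1 || degree != round(degree))
      stop("polynomial kernel needs a positive integer degree")
  }
  if (kind == "rbf") {
    if (is.null(gamma_rbf) || gamma_rbf <= 0)
      stop("rbf kernel needs gamma_rbf > 0")
  }
  if (kind == "clinical") {
    if (is.null(schema))
      stop("clinical kernel needs a feature schema with training ranges")
  }
  structure(list(kind = kind, degree = degree, gamma_rbf = gamma_rbf,
                 schema = schema), class = "kernel_spec")
}

#' Gram matrix between two sets of rows
#'
#' Kernel values `k(a_i, b_j)` for every row `a_i` of `A` and `b_j` of `B`.
#' Linear: `A B^T`. Polynomial (inhomogeneous): `(A B^T + 1)^degree`.
#' RBF: `exp(-gamma_rbf ||a - b||^2)`. Clinical: the additive kernel for
#' mixed data, averaged over features so values stay in `[0, 1]` --
#' a continuous feature with training range `r` contributes
#' `max(0, (r - |x - z|)) / r` and a categorical feature contributes the
#' equality indicator.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @param spec A [kernel_spec()].
#' @return `nrow(A) x nrow(B)` matrix.
#' @export
gram <- function(A, B, spec) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B have different dimensionality")
  switch(spec$kind,
    linear = A %*% t(B),
    polynomial = (A %*% t(B) + 1)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      d2[d2 < 0] <- 0
      exp(-spec$gamma_rbf * d2)
    },
    clinical = gram_clinical(A, B, spec$schema)
  )
}

gram_clinical <- function(A, B, schema) {
  d <- ncol(A)
  if (length(schema) != d)
    stop("clinical kernel schema does not match data dimensionality")
  K <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(d)) {
    sc <- schema[[j]]
    dif <- outer(A[, j], B[, j], "-")
    if (sc$kind == "continuous") {
      if (is.null(sc$range)) stop("continuous feature '", sc$name,
                                  "' lacks a training range")
      r <- sc$range[2] - sc$range[1]
      comp <- if (r > 0) (r - abs(dif)) / r else (dif == 0) * 1
      comp[comp < 0] <- 0   # out-of-range test values clamp at 0
      K <- K + comp
    } else {
      K <- K + (dif == 0)
    }
  }
  K / d
}

#' Make a square kernel block numerically positive semidefinite
#'
#' Adds the smallest diagonal jitter from the geometric ladder
#' `jitter_max * 10^(-12), 10^(-11), ...` that brings the minimum eigenvalue
#' above `-1e-10`. Returns `K` unchanged when it is already (numerically)
#' PSD.
#'
#' @param K Symmetric matrix.
#' @param jitter_max Largest jitter allowed before giving up.
#' @return Jittered (or untouched) matrix.
#' @export
ensure_psd <- function(K, jitter_max = 1e-4) {
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= -1e-10) return(K)
  for (jit in jitter_max * 10^seq(-12, 0)) {
    if (jit + ev_min >= -1e-10)
      return(K + diag(jit, nrow(K)))
  }
  stop("conditioning error: jitter_max = ", jitter_max,
       " insufficient (min eigenvalue ", signif(ev_min, 3), ")")
}
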