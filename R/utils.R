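## Internal numerical helpers shared across modules.

# Default identity-check tolerances (absolute / relative); see package vignette.
.fmb_tol_abs <- 1e-10
.fmb_tol_rel <- 1e-8

#' @noRd
is_simplex <- function(q, tol = 1e-12) {
  is.numeric(q) && length(q) >= 1L && all(is.finite(q)) &&
    all(q > 0) && abs(sum(q) - 1) <= tol
}

#' @noRd
check_simplex <- function(q, name = "q", tol = 1e-12) {
  if (!is.numeric(q) || length(q) < 1L || !all(is.finite(q))) {
    stop(sprintf("`%s` must be a finite numeric vector", name), call. = FALSE)
  }
  if (any(q <= 0)) {
    stop(sprintf("`%s` must be strictly positive (zero or negative entry at position %d)",
                 name, which(q <= 0)[1L]), call. = FALSE)
  }
  if (abs(sum(q) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.15g)", name, sum(q)), call. = FALSE)
  }
  invisible(q)
}

#' @noRd
as_trait_matrix <- function(theta, m = NULL) {
  if (is.null(dim(theta))) theta <- matrix(as.numeric(theta), ncol = 1L)
  theta <- as.matrix(theta)
  storage.mode(theta) <- "double"
  if (!is.null(m) && nrow(theta) != m) {
    stop(sprintf("trait matrix has %d rows but %d weights were supplied",
                 nrow(theta), m), call. = FALSE)
  }
  theta
}

# Population (not sample) moments under weights q; the Price identities hold
# only under this convention.
#' @noRd
wmean <- function(x, q) {
  if (is.null(dim(x))) sum(q * x) else as.numeric(crossprod(q, x))
}

#' @noRd
wcov_vec <- function(x, y, q) {
  sum(q * x * y) - sum(q * x) * sum(q * y)
}

# q-weighted covariance matrix Cov_q(X, Y); X, Y are m x nx, m x ny matrices.
#' @noRd
wcov <- function(X, Y = X, q) {
  X <- as_trait_matrix(X)
  Y <- as_trait_matrix(Y)
  xbar <- as.numeric(crossprod(q, X))
  ybar <- as.numeric(crossprod(q, Y))
  Xc <- sweep(X, 2L, xbar, "-")
  Yc <- sweep(Y, 2L, ybar, "-")
  crossprod(Xc, q * Yc)
}

#' @noRd
is_symmetric_num <- function(A, tol = 1e-12) {
  is.matrix(A) && nrow(A) == ncol(A) &&
    max(abs(A - t(A))) <= tol * max(1, max(abs(A)))
}

#' @noRd
symmetrize <- function(A) (A + t(A)) / 2

# Symmetric PSD square root via eigendecomposition (kept symmetric on purpose;
# Cholesky would break the documented draw order symmetry for Langevin noise).
#' @noRd
sym_sqrt <- function(A) {
  e <- eigen(symmetrize(A), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' @noRd
check_pd <- function(A, name = "matrix", tol = 1e-12) {
  if (!is_symmetric_num(A, tol = 1e-8)) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(symmetrize(A), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(1, max(abs(ev)))) {
    stop(sprintf("`%s` must be positive definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(A)
}

#' @noRd
format_num <- function(x, digits = 6L) formatC(x, digits = digits, format = "g")
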