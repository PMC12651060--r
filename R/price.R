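#' Weighted least-squares regression with intercept
#'
#' Solves the `q`-weighted normal equations of `response` on `predictors`
#' with an intercept, using population moments.  The slope vector satisfies
#' `Cov_q(X, X) b = Cov_q(X, y)`; when the centered predictor covariance is
#' singular the minimum-norm (Moore-Penrose) solution is returned and the
#' `singular` flag is set rather than failing silently.
#'
#' @param response length-`m` numeric vector.
#' @param predictors `m x n` matrix (a vector is treated as one column).
#' @param weights simplex weight vector of length `m`.
#' @return object of class `fmb_regression`: list with `coefficients`,
#'   `intercept`, `residuals` (weighted-orthogonal to each centered predictor
#'   column), and logical `singular`.
#' @examples
#' fit <- weighted_regression(c(0.5, 1.5), c(0, 1), c(0.5, 0.5))
#' fit$coefficients  # 1
#' @export
weighted_regression <- function(response, predictors, weights) {
  check_simplex(weights, "weights")
  X <- as_trait_matrix(predictors, length(weights))
  y <- as.numeric(response)
  if (length(y) != length(weights)) stop("`response` has wrong length", call. = FALSE)
  Cxx <- wcov(X, X, weights)
  cxy <- as.numeric(wcov(X, matrix(y, ncol = 1L), weights))
  n <- ncol(X)
  rk <- if (n > 0L) qr(Cxx, tol = 1e-10)$rank else 0L
  singular <- rk < n
  coefficients <- if (!singular) {
    as.numeric(solve(Cxx, cxy))
  } else {
    as.numeric(MASS::ginv(Cxx) %*% cxy)
  }
  intercept <- sum(weights * y) -
    sum(as.numeric(crossprod(weights, X)) * coefficients)
  residuals <- y - intercept - as.numeric(X %*% coefficients)
  structure(list(coefficients = coefficients, intercept = intercept,
                 residuals = residuals, singular = singular),
            class = "fmb_regression")
}

#' @export
print.fmb_regression <- function(x, ...) {
  cat("Weighted regression fit\n")
  cat("  intercept:", format_num(x$intercept), "\n")
  cat("  coefficients:", format_num(x$coefficients), "\n")
  if (x$singular) cat("  note: rank-deficient predictors; minimum-norm solution\n")
  invisible(x)
}

#' Force-metric-bias decomposition of one population update
#'
#' Re-expresses the exact Price partition of mean change as the FMB law
#' `delta theta_bar = M f + C beta + gamma`: the selection term
#' `Cov_q(w, theta)` becomes metric times force, where `M = Cov_q(theta)` and
#' `f` is the vector of partial regression coefficients of fitness on traits
#' (the Lande-equation form); the transmission term `E_q(w dtheta)` becomes
#' `C beta + gamma`, with `C = Cov_q(dtheta)`, `beta` the regression of
#' fitness on the trait changes, and `gamma = E_q(dtheta)` the intrinsic
#' bias.  All moments use the initial weights `q`.
#'
#' Singular trait or trait-change covariances are handled by the
#' Moore-Penrose pseudoinverse inside [weighted_regression()]; the returned
#' object records this in `singular`.  Because the fitness covariance lies in
#' the column space of the corresponding covariance matrix, `M f` still
#' reproduces `Cov_q(w, theta)` exactly in that case.
#'
#' @param pop an [population()] object.
#' @return object of class `fmb_decomposition` with fields `metric` (M),
#'   `force` (f), `bias_metric` (C), `bias_slope` (beta), `intrinsic_bias`
#'   (gamma), `selection_term`, `transmission_term`, `total`, and `singular`.
#' @examples
#' pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
#' fit <- fmb_decompose(pop)
#' fit$metric   # 0.25
#' fit$force    # 1
#' @export
fmb_decompose <- function(pop) {
  stopifnot(inherits(pop, "fmb_population"))
  q <- pop$weights
  w <- pop$fitness
  theta <- pop$traits
  dtheta <- trait_change(pop)
  part <- price_partition(pop)

  M <- symmetrize(wcov(theta, theta, q))
  ffit <- weighted_regression(w, theta, q)
  C <- symmetrize(wcov(dtheta, dtheta, q))
  bfit <- weighted_regression(w, dtheta, q)
  gamma <- as.numeric(crossprod(q, dtheta))

  structure(
    list(metric = M,
         force = ffit$coefficients,
         bias_metric = C,
         bias_slope = bfit$coefficients,
         intrinsic_bias = gamma,
         selection_term = part$selection,
         transmission_term = part$transmission,
         total = delta_mean(pop),
         singular = c(metric = ffit$singular, bias_metric = bfit$singular)),
    class = "fmb_decomposition")
}

#' @export
print.fmb_decomposition <- function(x, ...) {
  cat("Force-metric-bias decomposition\n")
  cat("  total change     :", format_num(x$total), "\n")
  cat("  selection  (M f) :", format_num(x$selection_term), "\n")
  cat("  transmission (b) :", format_num(x$transmission_term), "\n")
  if (any(x$singular)) {
    cat("  note: singular", paste(names(x$singular)[x$singular], collapse = ", "),
        "- pseudoinverse used\n")
  }
  invisible(x)
}

#' @export
summary.fmb_decomposition <- function(object, ...) {
  Mf <- as.numeric(object$metric %*% object$force)
  Cb <- as.numeric(object$bias_metric %*% object$bias_slope)
  out <- list(decomposition = object,
              Mf = Mf,
              Cbeta = Cb,
              reconstruction = Mf + Cb + object$intrinsic_bias,
              residual_selection = max(abs(Mf - object$selection_term)),
              residual_transmission =
                max(abs(Cb + object$intrinsic_bias - object$transmission_term)),
              expected_gain = expected_gain(object$metric, object$force))
  class(out) <- "summary.fmb_decomposition"
  out
}

#' @export
print.summary.fmb_decomposition <- function(x, ...) {
  d <- x$decomposition
  print(d)
  cat("  M f              :", format_num(x$Mf), "\n")
  cat("  C beta           :", format_num(x$Cbeta), "\n")
  cat("  gamma            :", format_num(d$intrinsic_bias), "\n")
  cat("  expected gain f'Mf:", format_num(x$expected_gain), "\n")
  cat("  identity residuals:", format_num(x$residual_selection), "(selection)",
      format_num(x$residual_transmission), "(transmission)\n")
  invisible(x)
}

#' @export
coef.fmb_decomposition <- function(object, ...) object$force

#' Expected performance gain of a metric-force update
#'
#' The partial increase in mean fitness caused by the direct force over one
#' update is the quadratic form `f' M f`, nonnegative for any positive
#' semidefinite metric.  With the trait covariance as metric this equals the
#' squared Fisher-Rao step length of the underlying frequency change.
#'
#' @param M `n x n` symmetric positive semidefinite metric.
#' @param f length-`n` force vector.
#' @return nonnegative scalar.
#' @export
expected_gain <- function(M, f) {
  if (is.null(dim(M))) M <- matrix(M, 1L, 1L)
  if (!is_symmetric_num(M, tol = 1e-8)) {
    stop("`M` must be symmetric", call. = FALSE)
  }
  as.numeric(crossprod(f, M %*% f))
}
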