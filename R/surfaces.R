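#' Performance surface with closed-form derivatives
#'
#' Bundles a scalar performance function `U(theta)` with its gradient and
#' Hessian and an orientation flag.  All optimizer steps in the package act
#' on such surfaces; maximization of `U` is the primary convention, and
#' minimization is obtained by negating `U` (which flips the sign of both
#' gradient and Hessian in the curvature conditions).
#'
#' @param evaluate function `theta -> scalar`.
#' @param gradient function `theta -> length-n vector`.
#' @param hessian function `theta -> n x n matrix`.
#' @param orientation `"maximize"` (default) or `"minimize"`.
#' @param name optional label.
#' @return object of class `performance_surface`.
#' @seealso [generate_surface()] for the built-in catalog,
#'   [check_surface()] for the finite-difference self-check.
#' @export
performance_surface <- function(evaluate, gradient, hessian,
                                orientation = c("maximize", "minimize"),
                                name = "surface") {
  orientation <- match.arg(orientation)
  stopifnot(is.function(evaluate), is.function(gradient), is.function(hessian))
  structure(list(evaluate = evaluate, gradient = gradient, hessian = hessian,
                 orientation = orientation, name = name),
            class = "performance_surface")
}

#' @export
print.performance_surface <- function(x, ...) {
  cat(sprintf("Performance surface '%s' (%s)\n", x$name, x$orientation))
  invisible(x)
}

# Effective gradient/Hessian in the maximize convention.
#' @noRd
surface_sign <- function(surface) if (surface$orientation == "maximize") 1 else -1

#' @noRd
eff_gradient <- function(surface, theta) surface_sign(surface) * surface$gradient(theta)

#' @noRd
eff_hessian <- function(surface, theta) surface_sign(surface) * surface$hessian(theta)

#' Finite-difference self-check of a surface's derivatives
#'
#' Compares the analytic gradient against a central finite difference of
#' `evaluate` at random probe points.  Returns the maximum relative error;
#' values above about `1e-5` indicate an inconsistent surface definition.
#'
#' @param surface a [performance_surface()].
#' @param n dimension of the parameter vector.
#' @param probes number of random probe points.
#' @param h finite-difference step.
#' @param probe function drawing one probe point of dimension `n`; defaults
#'   to standard normal draws (use a positive sampler for positive-orthant
#'   surfaces).
#' @return maximum relative gradient error across probes.
#' @export
check_surface <- function(surface, n, probes = 5L, h = 1e-6,
                          probe = function(n) stats::rnorm(n)) {
  worst <- 0
  for (p in seq_len(probes)) {
    theta <- probe(n)
    g <- surface$gradient(theta)
    fd <- vapply(seq_len(n), function(j) {
      e <- numeric(n); e[j] <- h
      (surface$evaluate(theta + e) - surface$evaluate(theta - e)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(fd - g)) / max(1, max(abs(g))))
  }
  worst
}

#' Built-in catalog of performance surfaces
#'
#' Generates the closed-form test surfaces used throughout the optimizer and
#' evolution-strategy examples.  All surfaces are oriented for maximization.
#'
#' * `"quadratic"`: `U = -1/2 theta' A theta` with `A` symmetric positive
#'   definite; eigenvalues log-spaced so that the condition number equals
#'   `condition`, random orthogonal eigenbasis (uses the current RNG state).
#' * `"shifted_quadratic"`: the same with maximizer at a random point
#'   `theta*`, `U = -1/2 (theta - theta*)' A (theta - theta*)`.
#' * `"quartic1d"`: one-dimensional `U = -(theta^4)/4 - a * theta^2 / 2`
#'   with `a >= 0`, strictly concave for `a > 0`.
#' * `"entropy_domain"`: positive-orthant surface
#'   `U = sum(a * log(theta) - b * theta)`, strictly concave on
#'   `theta > 0` with maximizer `a/b`; suited to entropy-potential mirror
#'   steps.
#'
#' @param name catalog entry.
#' @param n parameter dimension (forced to 1 for `"quartic1d"`).
#' @param condition condition number of the quadratic Hessian.
#' @param a,b coefficients of the quartic / entropy-domain surfaces.
#' @return a [performance_surface()].
#' @examples
#' set.seed(1)
#' s <- generate_surface("quadratic", n = 3, condition = 10)
#' check_surface(s, n = 3) < 1e-5
#' @export
generate_surface <- function(name = c("quadratic", "shifted_quadratic",
                                      "quartic1d", "entropy_domain"),
                             n = 2L, condition = 10, a = 1, b = 1) {
  name <- match.arg(name)
  if (name == "quartic1d") n <- 1L
  if (name %in% c("quadratic", "shifted_quadratic")) {
    evals <- if (n == 1L) 1 else exp(seq(0, log(condition), length.out = n))
    Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    A <- symmetrize(Q %*% (evals * t(Q)))
    center <- if (name == "shifted_quadratic") stats::rnorm(n) else numeric(n)
    performance_surface(
      evaluate = function(theta) -0.5 * sum((theta - center) * (A %*% (theta - center))),
      gradient = function(theta) as.numeric(-A %*% (theta - center)),
      hessian = function(theta) -A,
      name = name)
  } else if (name == "quartic1d") {
    performance_surface(
      evaluate = function(theta) -(theta[1]^4) / 4 - a * theta[1]^2 / 2,
      gradient = function(theta) -theta[1]^3 - a * theta[1],
      hessian = function(theta) matrix(-3 * theta[1]^2 - a, 1L, 1L),
      name = name)
  } else {
    performance_surface(
      evaluate = function(theta) sum(a * log(theta) - b * theta),
      gradient = function(theta) a / theta - b,
      hessian = function(theta) diag(-a / theta^2, length(theta)),
      name = name)
  }
}
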