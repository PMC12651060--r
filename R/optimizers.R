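#' Audited force-metric-bias step
#'
#' Container for one optimizer update together with its FMB decomposition.
#' Every constructor in the optimizer zoo returns one of these, and the
#' constructor enforces the audit identity
#' `step = metric %*% force + bias_metric_part + intrinsic_bias + noise`
#' to machine precision: an algorithm's step is never reported without the
#' decomposition that reproduces it.
#'
#' @param metric `n x n` positive semidefinite metric `M`.
#' @param force length-`n` force vector `f`.
#' @param bias_metric_part length-`n` vector `C beta` (performance-correlated
#'   bias).
#' @param intrinsic_bias length-`n` vector `gamma`.
#' @param noise length-`n` vector `xi` (zero for deterministic methods).
#' @param step length-`n` update `dtheta`.
#' @param method label of the producing algorithm.
#' @return object of class `fmb_step`.
#' @export
fmb_step <- function(metric, force, bias_metric_part = NULL,
                     intrinsic_bias = NULL, noise = NULL, step = NULL,
                     method = "step") {
  if (is.null(dim(metric))) metric <- diag(as.numeric(metric), length(force))
  n <- length(force)
  if (is.null(bias_metric_part)) bias_metric_part <- numeric(n)
  if (is.null(intrinsic_bias)) intrinsic_bias <- numeric(n)
  if (is.null(noise)) noise <- numeric(n)
  reconstructed <- as.numeric(metric %*% force) + bias_metric_part +
    intrinsic_bias + noise
  if (is.null(step)) {
    step <- reconstructed
  } else if (max(abs(step - reconstructed)) >
             1e-12 * max(1, max(abs(step)))) {
    stop(sprintf("FMB audit failed for %s: step and decomposition disagree by %.3g",
                 method, max(abs(step - reconstructed))), call. = FALSE)
  }
  structure(list(metric = metric, force = force,
                 bias_metric_part = bias_metric_part,
                 intrinsic_bias = intrinsic_bias, noise = noise,
                 step = step, method = method),
            class = "fmb_step")
}

#' @export
print.fmb_step <- function(x, ...) {
  cat(sprintf("FMB step (%s)\n", x$method))
  cat("  step :", format_num(x$step), "\n")
  cat("  M f  :", format_num(as.numeric(x$metric %*% x$force)), "\n")
  if (any(x$bias_metric_part != 0)) cat("  C b  :", format_num(x$bias_metric_part), "\n")
  if (any(x$intrinsic_bias != 0)) cat("  gamma:", format_num(x$intrinsic_bias), "\n")
  if (any(x$noise != 0)) cat("  xi   :", format_num(x$noise), "\n")
  invisible(x)
}

#' Optimizer state for stateful update rules
#'
#' Holds the evolving quantities of momentum and quasi-Newton methods: the
#' current position, the exponential moving averages of the gradient
#' (`momentum`) and squared gradient (`second_moment`), the running
#' inverse-metric estimate of quasi-Newton updates, and the step counter.
#'
#' @param position length-`n` numeric vector.
#' @param momentum length-`n` vector; defaults to zero.
#' @param second_moment nonnegative length-`n` vector; defaults to zero.
#' @param inverse_metric_estimate symmetric positive definite `n x n`
#'   matrix; defaults to the identity.
#' @return object of class `optimizer_state`.
#' @export
optimizer_state <- function(position, momentum = NULL, second_moment = NULL,
                            inverse_metric_estimate = NULL) {
  n <- length(position)
  if (is.null(momentum)) momentum <- numeric(n)
  if (is.null(second_moment)) second_moment <- numeric(n)
  if (any(second_moment < 0)) stop("`second_moment` must be nonnegative", call. = FALSE)
  if (is.null(inverse_metric_estimate)) inverse_metric_estimate <- diag(n)
  if (!is_symmetric_num(inverse_metric_estimate, tol = 1e-8)) {
    stop("`inverse_metric_estimate` must be symmetric", call. = FALSE)
  }
  structure(list(position = position, momentum = momentum,
                 second_moment = second_moment,
                 inverse_metric_estimate = inverse_metric_estimate,
                 step_index = 0L, skipped_update = FALSE),
            class = "optimizer_state")
}

#' Gradient ascent/descent step
#'
#' The simplest member of the zoo: `M = eta I`, `f = grad U`, no bias or
#' noise.  Under the minimize orientation the step descends the surface.
#'
#' @param surface a [performance_surface()].
#' @param theta current parameter vector.
#' @param eta positive step size.
#' @return an [fmb_step()].
#' @export
gd_step <- function(surface, theta, eta) {
  stopifnot(eta > 0)
  g <- eff_gradient(surface, theta)
  fmb_step(metric = diag(eta, length(theta)), force = g, method = "gradient")
}

#' Newton step with inverse-Hessian metric
#'
#' `M = (-H)^-1` (maximize orientation) and `f = grad U`, so one step lands
#' exactly on the maximizer of a concave quadratic.  If the curvature is not
#' definite in the required direction the step fails with a `MetricNotPD`
#' condition unless a damping `lambda > 0` is supplied, in which case
#' `M = (-H + lambda I)^-1`.
#'
#' @inheritParams gd_step
#' @param lambda optional nonnegative damping added to the curvature.
#' @return an [fmb_step()].
#' @export
newton_step <- function(surface, theta, lambda = 0) {
  g <- eff_gradient(surface, theta)
  Hpos <- -eff_hessian(surface, theta) + diag(lambda, length(theta))
  ev <- eigen(symmetrize(Hpos), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(structure(class = c("MetricNotPD", "error", "condition"),
                   list(message = sprintf(
                     "curvature not positive definite (min eigenvalue %.3g); supply damping `lambda`",
                     min(ev)), call = sys.call())))
  }
  fmb_step(metric = solve(symmetrize(Hpos)), force = g, method = "newton")
}

#' Second-order model of the performance gain of a step
#'
#' Evaluates the local quadratic model `f' dtheta + dtheta' H dtheta / 2`
#' (equivalently `f' dtheta - dtheta' M^-1 dtheta / 2` with `M = (-H)^-1`)
#' in the maximize convention.  Among all steps of equal metric length the
#' Newton direction maximizes this predicted gain, and on a quadratic
#' surface the prediction is exact.
#'
#' @inheritParams gd_step
#' @param dtheta proposed step.
#' @return predicted gain (scalar, in units of `U`).
#' @export
quadratic_model_gain <- function(surface, theta, dtheta) {
  g <- eff_gradient(surface, theta)
  H <- eff_hessian(surface, theta)
  sum(g * dtheta) + 0.5 * as.numeric(crossprod(dtheta, H %*% dtheta))
}

#' Quasi-Newton (BFGS) inverse-metric update
#'
#' Updates the running inverse-curvature estimate from one observed pair of
#' parameter step `dtheta` and gradient change `dgrad`, by the standard
#' inverse-Hessian secant rule.  In the maximize orientation the estimate
#' approximates `(-H)^-1`, so the secant direction is `y = -dgrad`; under
#' minimization `y = dgrad`.  The update is applied only when the curvature
#' condition `dtheta . y > 0` holds; otherwise the state is returned
#' unchanged with `skipped_update = TRUE`.  After the update the secant
#' equation `B y = dtheta` holds exactly and the estimate stays symmetric
#' positive definite.
#'
#' @param state an [optimizer_state()].
#' @param dtheta parameter step taken.
#' @param dgrad gradient change across the step.
#' @param orientation `"maximize"` or `"minimize"`.
#' @return updated [optimizer_state()].
#' @export
bfgs_metric_update <- function(state, dtheta, dgrad,
                               orientation = c("maximize", "minimize")) {
  stopifnot(inherits(state, "optimizer_state"))
  orientation <- match.arg(orientation)
  y <- if (orientation == "maximize") -dgrad else dgrad
  s <- dtheta
  sy <- sum(s * y)
  state$step_index <- state$step_index + 1L
  if (!is.finite(sy) || sy <= 1e-12 * sqrt(sum(s^2) * sum(y^2))) {
    state$skipped_update <- TRUE
    return(state)
  }
  state$skipped_update <- FALSE
  B <- state$inverse_metric_estimate
  rho <- 1 / sy
  n <- length(s)
  V <- diag(n) - rho * tcrossprod(s, y)      # I - rho s y'
  state$inverse_metric_estimate <-
    symmetrize(V %*% B %*% t(V) + rho * tcrossprod(s, s))
  state
}

#' Natural-gradient step
#'
#' Preconditions the local gradient by the inverse of a Fisher information
#' matrix: `M = G^-1`, `f = grad U`.  With the Fisher matrix computed from
#' Boltzmann performance weighting ([boltzmann_fisher()]) and a constant
#' Hessian, the step coincides with the Newton step.
#'
#' @inheritParams gd_step
#' @param fisher symmetric positive definite `n x n` Fisher matrix.
#' @return an [fmb_step()].
#' @export
natural_gradient_step <- function(surface, theta, fisher) {
  check_pd(fisher, "fisher")
  g <- eff_gradient(surface, theta)
  fmb_step(metric = solve(symmetrize(fisher)), force = g,
           method = "natural gradient")
}

#' Fisher matrix under Boltzmann performance weighting
#'
#' Weights points of the domain by `q(theta) proportional to
#' exp(inv_temp * U(theta))` and returns `G = -E_q[H(theta)]`, the
#' Boltzmann-averaged negative Hessian.  For a quadratic surface the Hessian
#' is constant and `G` equals its negative exactly; as `inv_temp` grows the
#' weighting concentrates on the maximizer and `G` approaches the local
#' negative Hessian there.
#'
#' @param surface a [performance_surface()] (maximize orientation).
#' @param grid matrix of domain points (rows) or a numeric vector for one
#'   dimension; quadrature runs over these points.
#' @param inv_temp positive inverse temperature (default 1).
#' @return symmetric `n x n` matrix.
#' @export
boltzmann_fisher <- function(surface, grid, inv_temp = 1) {
  if (is.null(dim(grid))) grid <- matrix(grid, ncol = 1L)
  u <- apply(grid, 1L, function(th) surface$evaluate(th))
  lw <- inv_temp * u
  lw <- lw - max(lw)
  wts <- exp(lw)
  Z <- sum(wts)
  if (!is.finite(Z) || Z <= 0) stop("divergent Boltzmann normalizer on the grid", call. = FALSE)
  wts <- wts / Z
  n <- ncol(grid)
  G <- matrix(0, n, n)
  for (i in seq_len(nrow(grid))) {
    G <- G - wts[i] * eff_hessian(surface, grid[i, ])
  }
  symmetrize(G)
}

#' First-order mirror step
#'
#' Newton-like step in a mirror geometry: the metric is the inverse Hessian
#' of a strictly convex potential `phi`, scaled by the step size,
#' `M = eta Hphi^-1`, with the local gradient as force.  This is the
#' first-order approximation of the exact mirror update
#' ([mirror_step_exact()]); the two differ at order `eta^2`.
#'
#' @inheritParams gd_step
#' @param potential a [mirror_potential()].
#' @return an [fmb_step()].
#' @export
mirror_step_first_order <- function(surface, theta, potential, eta) {
  stopifnot(eta > 0, inherits(potential, "mirror_potential"))
  Hphi <- potential$hessian(theta)
  if (is.null(dim(Hphi))) Hphi <- diag(as.numeric(Hphi), length(theta))
  check_pd(Hphi, "potential Hessian")
  g <- eff_gradient(surface, theta)
  fmb_step(metric = eta * solve(symmetrize(Hphi)), force = g,
           method = "mirror (first order)")
}

#' Exact mirror step
#'
#' Solves the mirror fixed point `grad phi(theta') = grad phi(theta) +
#' eta * grad U(theta)` exactly through the potential's inverse gradient
#' map.  For the entropy potential this is the exponentiated-gradient
#' update `theta' = theta * exp(eta * grad U)`; for a quadratic potential it
#' reduces to the first-order step for every `eta`.
#'
#' @inheritParams mirror_step_first_order
#' @return updated parameter vector `theta'`.
#' @export
mirror_step_exact <- function(surface, theta, potential, eta) {
  stopifnot(eta > 0, inherits(potential, "mirror_potential"))
  if (is.null(potential$grad_inverse)) {
    stop("`potential` has no invertible gradient map", call. = FALSE)
  }
  g <- eff_gradient(surface, theta)
  target <- potential$grad(theta) + eta * g
  potential$grad_inverse(target)
}

#' Mirror potentials
#'
#' Strictly convex potentials defining mirror geometries.
#' `mirror_potential("quadratic")` is `phi = ||theta||^2 / 2` (identity
#' mirror map, recovers plain gradient steps); `mirror_potential("entropy")`
#' is the negative entropy `phi = sum(theta * log(theta))` on the positive
#' orthant, whose inverse gradient map yields exponentiated-gradient
#' updates.  A custom potential supplies `grad`, `hessian`, and optionally
#' `grad_inverse` directly.
#'
#' @param name `"quadratic"` or `"entropy"`.
#' @param grad,hessian,grad_inverse functions for a custom potential.
#' @return object of class `mirror_potential`.
#' @export
mirror_potential <- function(name = c("quadratic", "entropy"),
                             grad = NULL, hessian = NULL, grad_inverse = NULL) {
  if (is.null(grad)) {
    name <- match.arg(name)
    if (name == "quadratic") {
      grad <- function(theta) theta
      hessian <- function(theta) diag(length(theta))
      grad_inverse <- function(u) u
    } else {
      grad <- function(theta) 1 + log(theta)
      hessian <- function(theta) diag(1 / theta, length(theta))
      grad_inverse <- function(u) exp(u - 1)
    }
  } else {
    name <- "custom"
    stopifnot(is.function(grad), is.function(hessian))
  }
  structure(list(name = name, grad = grad, hessian = hessian,
                 grad_inverse = grad_inverse),
            class = "mirror_potential")
}

#' Regularized gradient step with prior shrinkage bias
#'
#' `dtheta = eta * (grad U - lambda * (theta - prior_point))`: the direct
#' force pushes up the surface while an intrinsic bias
#' `gamma = -eta * lambda * (theta - prior_point)` pulls every parameter
#' toward a prior value.  The fixed point balances the two forces,
#' `grad U = lambda (theta - prior_point)`.
#'
#' @inheritParams gd_step
#' @param lambda positive shrinkage strength.
#' @param prior_point shrinkage target (default the origin).
#' @return an [fmb_step()].
#' @export
regularized_gd_step <- function(surface, theta, eta, lambda,
                                prior_point = numeric(length(theta))) {
  stopifnot(eta > 0, lambda > 0)
  g <- eff_gradient(surface, theta)
  fmb_step(metric = diag(eta, length(theta)), force = g,
           intrinsic_bias = -eta * lambda * (theta - prior_point),
           method = "regularized gradient")
}

#' Momentum (exponential moving average gradient) step
#'
#' Maintains `m_t = (1 - u) g_t + u m_{t-1}` and steps by `eta m_t`.  In FMB
#' terms the metric is `eta (1 - u) I` acting on the fresh gradient, and the
#' carried momentum enters as intrinsic bias `gamma = eta u m_{t-1}`,
#' uncorrelated with the current force.
#'
#' @param state an [optimizer_state()] holding the previous momentum.
#' @inheritParams gd_step
#' @param u momentum retention in `[0, 1)`.
#' @return list with updated `state` (position advanced, momentum stored)
#'   and the audited `step` ([fmb_step()]).
#' @export
polyak_step <- function(state, surface, eta, u) {
  stopifnot(inherits(state, "optimizer_state"), eta > 0, u >= 0, u < 1)
  g <- eff_gradient(surface, state$position)
  m_new <- (1 - u) * g + u * state$momentum
  step <- fmb_step(metric = diag(eta * (1 - u), length(g)), force = g,
                   intrinsic_bias = eta * u * state$momentum,
                   step = eta * m_new, method = "polyak")
  state$momentum <- m_new
  state$position <- state$position + step$step
  state$step_index <- state$step_index + 1L
  list(state = state, step = step)
}

#' Adaptive-metric momentum step (printed-form Adam)
#'
#' Combines the momentum average `m_t = (1 - u) g_t + u m_{t-1}` with the
#' squared-gradient average `v_t = (1 - s) g_t^2 + s v_{t-1}` and steps by
#' the closed form `eta * m_t / ((v_t + c) (1 - u))` elementwise.  The FMB
#' reading is `M = diag(eta / (v_t + c))`, `f = g_t`, and a
#' performance-correlated bias `C beta = M u m_{t-1} / (1 - u)`; the
#' decomposition reproduces the closed form exactly.  Note the metric
#' divides by `v_t + c` directly (no square root and no bias correction);
#' set `standard = TRUE` for comparison against the conventional
#' `sqrt(v_t)` variant.
#'
#' @inheritParams polyak_step
#' @param s second-moment retention in `[0, 1)`.
#' @param c small positive metric regularizer.
#' @param standard logical; use the conventional `eta / (sqrt(v_t) + c)`
#'   metric with bias-corrected averages instead of the primary form.  The
#'   FMB audit is still exact in that mode.
#' @return list with updated `state` and the audited `step`.
#' @export
adam_paper_step <- function(state, surface, eta, u, s, c = 1e-8,
                            standard = FALSE) {
  stopifnot(inherits(state, "optimizer_state"),
            eta > 0, u >= 0, u < 1, s >= 0, s < 1, c > 0)
  g <- eff_gradient(surface, state$position)
  m_new <- (1 - u) * g + u * state$momentum
  v_new <- (1 - s) * g^2 + s * state$second_moment
  t_new <- state$step_index + 1L
  if (!standard) {
    Mdiag <- eta / (v_new + c)
    step <- fmb_step(metric = diag(Mdiag, length(g)), force = g,
                     bias_metric_part = Mdiag * u * state$momentum / (1 - u),
                     step = eta * m_new / ((v_new + c) * (1 - u)),
                     method = "adam")
  } else {
    mhat <- m_new / (1 - u^t_new)
    vhat <- v_new / (1 - s^t_new)
    Mdiag <- eta / (sqrt(vhat) + c)
    step <- fmb_step(metric = diag(Mdiag, length(g)), force = g,
                     bias_metric_part = Mdiag * (mhat - g),
                     step = Mdiag * mhat, method = "adam (standard)")
  }
  state$momentum <- m_new
  state$second_moment <- v_new
  state$position <- state$position + step$step
  state$step_index <- t_new
  list(state = state, step = step)
}

#' Stochastic Langevin step
#'
#' Discretized Langevin dynamics on a performance surface: deterministic
#' drift `eta M grad U` plus Gaussian exploration noise
#' `xi = sqrt(2 eta) M^(1/2) epsilon` with standard normal `epsilon`, so
#' that `Cov(xi) = 2 eta M`.  The matrix square root uses the symmetric
#' eigendecomposition, and exactly `n` standard normal draws are consumed
#' from the current RNG state per call (seed with `set.seed` for
#' reproducibility).
#'
#' @inheritParams gd_step
#' @param M symmetric positive definite preconditioning metric.
#' @return an [fmb_step()] whose `noise` field carries the realized draw.
#' @export
sgld_step <- function(surface, theta, M, eta) {
  stopifnot(eta >= 0)
  if (is.null(dim(M))) M <- diag(as.numeric(M), length(theta))
  check_pd(M, "M")
  g <- eff_gradient(surface, theta)
  eps <- stats::rnorm(length(theta))
  xi <- if (eta == 0) numeric(length(theta)) else {
    sqrt(2 * eta) * as.numeric(sym_sqrt(M) %*% eps)
  }
  fmb_step(metric = eta * M, force = g, noise = xi, method = "langevin")
}

#' Split a minibatch gradient into signal and sampling noise
#'
#' Given the per-datum gradients of a loss over `N` observations and the
#' indices of one minibatch, returns the full-data mean gradient (the
#' signal) and the deviation of the batch mean from it (the sampling
#' noise).  Over random batches drawn without replacement the noise has
#' mean zero and componentwise variance
#' `(1/B) (1 - B/N) * N/(N-1) * Var_pop`, the finite-population law; for
#' batches drawn with replacement the variance is `Var_pop / B`.
#'
#' @param per_datum_gradients `N x n` matrix (or list of length-`n`
#'   vectors) of per-observation gradients.
#' @param batch_indices integer indices of the minibatch (nonempty).
#' @return list with `signal` and `noise` vectors.
#' @export
sgd_split <- function(per_datum_gradients, batch_indices) {
  G <- if (is.list(per_datum_gradients)) {
    do.call(rbind, per_datum_gradients)
  } else {
    as.matrix(per_datum_gradients)
  }
  batch_indices <- as.integer(batch_indices)
  if (length(batch_indices) == 0L) stop("empty batch", call. = FALSE)
  if (any(batch_indices < 1L) || any(batch_indices > nrow(G))) {
    stop("batch indices out of range", call. = FALSE)
  }
  signal <- colMeans(G)
  batch_mean <- colMeans(G[batch_indices, , drop = FALSE])
  list(signal = as.numeric(signal), noise = as.numeric(batch_mean - signal))
}
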