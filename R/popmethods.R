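#' Evolution-strategy search state
#'
#' State of a simplified covariance-adapting evolution strategy: the current
#' target mean, the Gaussian sampling covariance, and the generation
#' counter.  Each generation ([es_generation()]) samples a batch around the
#' mean, converts performance to relative fitness, and moves the mean by the
#' Price selection term of the sampled batch — the population form of the
#' metric-times-force update.
#'
#' @param mean length-`n` target parameter vector.
#' @param sampling_cov symmetric positive definite `n x n` sampling
#'   covariance.
#' @return object of class `es_state` (also carries the most recent sampled
#'   batch as an `fmb_population` after a generation has run).
#' @export
es_state <- function(mean, sampling_cov = diag(length(mean))) {
  if (is.null(dim(sampling_cov))) {
    sampling_cov <- diag(as.numeric(sampling_cov), length(mean))
  }
  check_pd(sampling_cov, "sampling_cov")
  structure(list(mean = as.numeric(mean), sampling_cov = sampling_cov,
                 population = NULL, generation = 0L),
            class = "es_state")
}

#' @export
print.es_state <- function(x, ...) {
  cat(sprintf("Evolution strategy state (generation %d)\n", x$generation))
  cat("  mean:", format_num(x$mean), "\n")
  invisible(x)
}

#' One generation of the Price-consistent evolution strategy
#'
#' Samples `pop_size` parameter vectors from a Gaussian at the current mean
#' and covariance, evaluates the surface, normalizes performance to relative
#' fitness with population mean one, and updates the target mean by the
#' empirical `Cov(w, theta)` of the sample — which is exactly the Price
#' selection term of the sampled batch, uniform prior weights `1/m`.  The
#' sampling covariance is blended toward the fitness-weighted outer products
#' of the sampled deviations (rank-mu style) at rate `alpha`.  No evolution
#' paths or step-size control are maintained; this is the bare
#' metric-times-force core of covariance-adapting strategies.
#'
#' Performance values must be strictly positive to act as fitness; for
#' surfaces that can go nonpositive choose `transform = "shift"` (subtract
#' the minimum and add a small margin) or `"exp"` (exponential ranking).
#' Uses the current RNG state; seed with `set.seed` for reproducibility.
#'
#' @param state an [es_state()].
#' @param surface a [performance_surface()].
#' @param pop_size number of sampled candidates per generation.
#' @param alpha covariance learning rate in `[0, 1]` (default 0.3).
#' @param transform fitness transform: `"none"`, `"shift"`, or `"exp"`.
#' @return updated [es_state()] with the sampled batch attached as
#'   `population`.
#' @export
es_generation <- function(state, surface, pop_size, alpha = 0.3,
                          transform = c("none", "shift", "exp")) {
  stopifnot(inherits(state, "es_state"), pop_size >= 2L)
  transform <- match.arg(transform)
  n <- length(state$mean)
  R <- sym_sqrt(state$sampling_cov)
  Z <- matrix(stats::rnorm(pop_size * n), pop_size, n)
  theta <- sweep(Z %*% R, 2L, state$mean, "+")
  u <- apply(theta, 1L, function(th) surface$evaluate(th))
  if (surface$orientation == "minimize") u <- -u
  u <- switch(transform,
              none = u,
              shift = u - min(u) + 1e-3 * max(1, diff(range(u))),
              exp = exp((u - max(u)) / max(stats::sd(u), .Machine$double.eps)))
  if (any(u <= 0)) {
    stop("nonpositive performance values; choose transform = \"shift\" or \"exp\"",
         call. = FALSE)
  }
  w <- u / mean(u)
  q <- rep(1 / pop_size, pop_size)
  pop <- population(weights = q, traits = theta, fitness = w, normalize = TRUE)
  dmean <- price_partition(pop)$selection
  dev <- sweep(theta, 2L, state$mean, "-")
  Cemp <- crossprod(dev, (q * pop$fitness) * dev)
  state$sampling_cov <- symmetrize((1 - alpha) * state$sampling_cov + alpha * Cemp)
  state$mean <- state$mean + dmean
  state$population <- pop
  state$generation <- state$generation + 1L
  state
}

#' Gaussian-process model over fixed training inputs
#'
#' Squared-exponential kernel `k(x, xt) = sigma_g^2 exp(-||x - xt||^2 /
#' (2 l^2))` evaluated on `N` input points, with observation noise variance
#' `noise_var` and a prior mean vector.  Only the training-input posterior
#' mean update is modelled; see [gp_mean_update()].
#'
#' @param inputs `N x d` matrix (or length-`N` vector) of input locations.
#' @param sigma_g2 kernel baseline variance (`k(x, x)`).
#' @param lengthscale kernel length scale.
#' @param noise_var positive observation noise variance `sigma^2`.
#' @param prior_mean length-`N` prior mean vector (default zero).
#' @return object of class `gp_model` with the kernel matrix `K` attached.
#' @export
gp_model <- function(inputs, sigma_g2 = 1, lengthscale = 1, noise_var = 0.1,
                     prior_mean = NULL) {
  X <- if (is.null(dim(inputs))) matrix(inputs, ncol = 1L) else as.matrix(inputs)
  stopifnot(sigma_g2 > 0, lengthscale > 0, noise_var > 0)
  d2 <- as.matrix(stats::dist(X))^2
  K <- sigma_g2 * exp(-d2 / (2 * lengthscale^2))
  N <- nrow(X)
  if (is.null(prior_mean)) prior_mean <- numeric(N)
  stopifnot(length(prior_mean) == N)
  structure(list(inputs = X, K = symmetrize(K), sigma_g2 = sigma_g2,
                 lengthscale = lengthscale, noise_var = noise_var,
                 prior_mean = prior_mean, jittered = FALSE),
            class = "gp_model")
}

#' Gaussian-process posterior mean update in metric-force form
#'
#' Computes the change of the posterior mean at the training inputs as
#' metric times force: `M = (K^-1 + sigma^-2 I)^-1` (the inverse of the
#' total Fisher information, prior precision plus data precision) and
#' `f = sigma^-2 (y - mu_0)` (the data deviation weighted by its
#' information).  The product equals the textbook posterior-mean change
#' `K (K + sigma^2 I)^-1 (y - mu_0)`.  If `K` cannot be inverted a jitter
#' of `1e-10 * sigma_g2` is added to its diagonal and the model flag
#' `jittered` is set on the returned attributes.
#'
#' @param model a [gp_model()].
#' @param observations length-`N` vector `y`.
#' @return length-`N` update of the posterior mean, with attributes
#'   `metric`, `force`, and `jittered`.
#' @export
gp_mean_update <- function(model, observations) {
  stopifnot(inherits(model, "gp_model"))
  y <- as.numeric(observations)
  N <- nrow(model$inputs)
  stopifnot(length(y) == N)
  K <- model$K
  jittered <- FALSE
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch) || rcond(K) < 1e-12) {
    K <- K + diag(1e-10 * model$sigma_g2, N)
    ch <- chol(K)
    jittered <- TRUE
  }
  Kinv <- chol2inv(ch)
  M <- solve(symmetrize(Kinv + diag(1 / model$noise_var, N)))
  f <- (y - model$prior_mean) / model$noise_var
  out <- as.numeric(M %*% f)
  attr(out, "metric") <- M
  attr(out, "force") <- f
  attr(out, "jittered") <- jittered
  out
}

#' Linear-Gaussian state-space (Kalman) model
#'
#' Hidden state `x_t = A x_{t-1} + process noise (cov Q)`, observation
#' `y_t = Hobs x_t + observation noise (cov R)`, with current filtered mean
#' `state_mean` and covariance `state_cov`.  The dynamics and observation
#' matrices are named `A` and `Hobs` to keep `F` for the Fisher-Rao step
#' and `H` for Hessians elsewhere in the package.
#'
#' @param dynamics `n x n` state transition matrix `A`.
#' @param process_noise_cov symmetric PSD `n x n` matrix `Q`.
#' @param observation `k x n` observation matrix `Hobs`.
#' @param obs_noise_cov symmetric positive definite `k x k` matrix `R`.
#' @param state_mean length-`n` filtered mean.
#' @param state_cov symmetric PSD `n x n` filtered covariance.
#' @return object of class `kalman_model`.
#' @export
kalman_model <- function(dynamics, process_noise_cov, observation,
                         obs_noise_cov, state_mean, state_cov) {
  A <- as.matrix(dynamics); Q <- as.matrix(process_noise_cov)
  Hobs <- as.matrix(observation); R <- as.matrix(obs_noise_cov)
  n <- length(state_mean)
  stopifnot(nrow(A) == n, ncol(A) == n, nrow(Q) == n,
            ncol(Hobs) == n, nrow(R) == nrow(Hobs))
  if (!is_symmetric_num(Q, 1e-8) || !is_symmetric_num(R, 1e-8)) {
    stop("noise covariances must be symmetric", call. = FALSE)
  }
  check_pd(R, "obs_noise_cov")
  structure(list(dynamics = A, process_noise_cov = symmetrize(Q),
                 observation = Hobs, obs_noise_cov = symmetrize(R),
                 state_mean = as.numeric(state_mean),
                 state_cov = symmetrize(as.matrix(state_cov))),
            class = "kalman_model")
}

#' Kalman filter update in metric-force form
#'
#' One predict-update cycle.  Predict: `xhat- = A xhat`,
#' `P- = A P A' + Q`.  Update: innovation `nu = y - Hobs xhat-`, innovation
#' covariance `S = Hobs P- Hobs' + R`, and the mean update expressed as
#' metric times force with `M = P-` (the prior covariance, the inverse
#' curvature of the estimate error) and `f = Hobs' S^-1 nu` (the innovation
#' rescaled to state coordinates by its information).  This equals the
#' textbook gain form `K_gain nu`.  The posterior covariance uses the
#' Joseph form, which preserves symmetry and positive semidefiniteness.
#'
#' @param model a [kalman_model()].
#' @param observation length-`k` measurement `y`.
#' @return list with the updated `model` and the audited `step`
#'   ([fmb_step()] with `M = P-` and the innovation force).
#' @export
kalman_update <- function(model, observation) {
  stopifnot(inherits(model, "kalman_model"))
  y <- as.numeric(observation)
  A <- model$dynamics; Q <- model$process_noise_cov
  Hobs <- model$observation; R <- model$obs_noise_cov
  stopifnot(length(y) == nrow(Hobs))
  x_prior <- as.numeric(A %*% model$state_mean)
  P_prior <- symmetrize(A %*% model$state_cov %*% t(A) + Q)
  nu <- y - as.numeric(Hobs %*% x_prior)
  S <- symmetrize(Hobs %*% P_prior %*% t(Hobs) + R)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("singular innovation covariance; `obs_noise_cov` must be positive definite",
         call. = FALSE)
  })
  f <- as.numeric(t(Hobs) %*% Sinv %*% nu)
  step <- fmb_step(metric = P_prior, force = f, method = "kalman")
  K_gain <- P_prior %*% t(Hobs) %*% Sinv
  n <- nrow(P_prior)
  IKH <- diag(n) - K_gain %*% Hobs
  P_post <- symmetrize(IKH %*% P_prior %*% t(IKH) +
                         K_gain %*% R %*% t(K_gain))
  model$state_mean <- x_prior + step$step
  model$state_cov <- P_post
  list(model = model, step = step)
}
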