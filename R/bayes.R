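#' Discrete Bayesian update as a selection step
#'
#' Updates a prior `q` over a finite set of parameter states by an
#' unnormalized likelihood vector.  The normalized likelihood
#' `L = Ltilde / (q . Ltilde)` has population mean one under the prior and
#' plays exactly the role of relative fitness: the posterior is
#' `q'_i = q_i L_i`, a replicator (selection) update, and the log evidence is
#' `log(q . Ltilde)`.
#'
#' @param prior simplex vector `q`.
#' @param unnorm_likelihood strictly positive likelihood vector, same length.
#' @return object of class `discrete_bayes`: list with `prior`,
#'   `unnorm_likelihood`, `norm_likelihood`, `posterior`, `log_evidence`.
#' @examples
#' db <- bayes_update(c(0.5, 0.5), c(2, 1))
#' db$posterior      # 2/3, 1/3
#' db$log_evidence   # log(1.5)
#' @export
bayes_update <- function(prior, unnorm_likelihood) {
  check_simplex(prior, "prior")
  lik <- as.numeric(unnorm_likelihood)
  if (length(lik) != length(prior)) {
    stop("`unnorm_likelihood` has wrong length", call. = FALSE)
  }
  if (any(!is.finite(lik)) || any(lik <= 0)) {
    stop("`unnorm_likelihood` must be finite and strictly positive", call. = FALSE)
  }
  evidence <- sum(prior * lik)
  L <- lik / evidence
  structure(list(prior = prior,
                 unnorm_likelihood = lik,
                 norm_likelihood = L,
                 posterior = prior * L,
                 log_evidence = log(evidence)),
            class = "discrete_bayes")
}

#' @export
print.discrete_bayes <- function(x, ...) {
  cat(sprintf("Discrete Bayes update over %d states\n", length(x$prior)))
  cat("  log evidence  :", format_num(x$log_evidence), "\n")
  cat("  direct gain F :", format_num(likelihood_gain(x)), "\n")
  invisible(x)
}

#' Direct likelihood gain of a Bayes update
#'
#' The partial increase in mean normalized likelihood caused by the
#' frequency change from prior to posterior, `dq . L`.  Because the
#' normalized likelihood is the relative fitness of the update, this gain
#' equals the squared Fisher-Rao step length of the prior-to-posterior move.
#'
#' @param db a [bayes_update()] object.
#' @return nonnegative scalar.
#' @export
likelihood_gain <- function(db) {
  stopifnot(inherits(db, "discrete_bayes"))
  sum((db$posterior - db$prior) * db$norm_likelihood)
}

#' Evidence lower bound of a candidate posterior
#'
#' For a strictly positive candidate distribution `qhat`, the evidence lower
#' bound is `ELBO = E_qhat(log Ltilde) - D(qhat || q)`: expected
#' log-likelihood under the candidate minus the divergence from the prior.
#' It satisfies `ELBO = log_evidence - D(qhat || q')`, so the bound is tight
#' exactly at the true posterior, and the gap `D(qhat || q')` is the
#' variational free energy.
#'
#' @param db a [bayes_update()] object.
#' @param candidate simplex vector, strictly positive, same length.
#' @return object of class `variational_state`: list with `candidate`,
#'   `elbo`, `kl_to_posterior`, `free_energy` (equal to `kl_to_posterior`).
#' @examples
#' db <- bayes_update(c(0.5, 0.5), c(2, 1))
#' elbo(db, db$posterior)$elbo  # log(1.5): bound is tight at the posterior
#' @export
elbo <- function(db, candidate) {
  stopifnot(inherits(db, "discrete_bayes"))
  check_simplex(candidate, "candidate")
  if (length(candidate) != length(db$prior)) {
    stop("`candidate` has wrong length", call. = FALSE)
  }
  value <- sum(candidate * log(db$unnorm_likelihood)) -
    kl_divergence(candidate, db$prior)
  gap <- kl_divergence(candidate, db$posterior)
  structure(list(candidate = candidate, elbo = value,
                 kl_to_posterior = gap, free_energy = gap),
            class = "variational_state")
}

#' @export
print.variational_state <- function(x, ...) {
  cat("Variational state\n")
  cat("  ELBO        :", format_num(x$elbo), "\n")
  cat("  free energy :", format_num(x$free_energy), "\n")
  invisible(x)
}

#' Price partition of the ELBO change
#'
#' Splits the change in the evidence lower bound, from the baseline at
#' `candidate = prior` to the supplied candidate, into the direct force of
#' the data, `(qhat - q) . log Ltilde`, and the context (inertial) cost of
#' leaving the prior, `-D(qhat || q)`.  The two terms telescope exactly to
#' the ELBO difference.
#'
#' @inheritParams elbo
#' @return list with `direct`, `context`, and their `total`.
#' @export
elbo_price_decomposition <- function(db, candidate) {
  stopifnot(inherits(db, "discrete_bayes"))
  check_simplex(candidate, "candidate")
  direct <- sum((candidate - db$prior) * log(db$unnorm_likelihood))
  context <- -kl_divergence(candidate, db$prior)
  list(direct = direct, context = context, total = direct + context)
}

#' Variational free-energy change of a candidate move
#'
#' `dF = D(qhat || q) - (qhat - q) . log Ltilde`, the complexity cost of
#' moving away from the prior minus the accuracy gained by moving toward the
#' data.  Equal to minus the ELBO change of [elbo_price_decomposition()];
#' negative whenever the candidate improves on the prior, and minimized (most
#' negative) at the true posterior.
#'
#' @inheritParams elbo
#' @return scalar.
#' @export
free_energy_change <- function(db, candidate) {
  -elbo_price_decomposition(db, candidate)$total
}

#' Static force balance of the Bayes update
#'
#' Under conservation of total probability, the direct force of the data
#' (`log Ltilde`) decomposes into the inertial pull of the prior
#' (`log(qhat/q)`) plus the residual potential toward the true posterior
#' (`log(q'/qhat)`), up to an additive constant (the log normalizer).  Since
#' constant vectors do no virtual work on zero-sum displacements, the total
#' virtual work vanishes for every allowable displacement.  This function
#' evaluates the worst-case virtual work over the supplied displacements.
#'
#' @inheritParams elbo
#' @param displacements list of numeric zero-sum vectors (virtual
#'   displacements compatible with probability conservation).
#' @return maximum absolute virtual work over the displacements (zero to
#'   numerical precision).
#' @export
dalembert_balance <- function(db, candidate, displacements) {
  stopifnot(inherits(db, "discrete_bayes"))
  check_simplex(candidate, "candidate")
  if (!is.list(displacements)) displacements <- list(displacements)
  bracket <- log(db$unnorm_likelihood) - log(candidate / db$prior) -
    log(db$posterior / candidate)
  works <- vapply(displacements, function(d) {
    if (length(d) != length(candidate)) stop("displacement has wrong length", call. = FALSE)
    if (abs(sum(d)) > 1e-12 * max(1, max(abs(d)))) {
      stop("displacements must sum to zero", call. = FALSE)
    }
    abs(sum(bracket * d))
  }, numeric(1))
  if (length(works) == 0L) 0 else max(works)
}

#' Mean-field variational projection on a factored state space
#'
#' Coordinate-ascent variational inference for a discrete problem whose
#' states form a Cartesian product grid.  The candidate family is the
#' product of independent marginals over the factors; each sweep updates one
#' marginal in closed form to the exponentiated expected log joint under the
#' other factors, which can never decrease the ELBO.  Iteration stops when
#' the ELBO improves by less than `tol`.
#'
#' @param db a [bayes_update()] object whose states enumerate a grid in
#'   column-major (first factor fastest) order.
#' @param dims integer vector of factor sizes with `prod(dims)` equal to the
#'   number of states.
#' @param steps maximum number of full coordinate sweeps.
#' @param tol convergence threshold on the ELBO improvement per sweep.
#' @return a `variational_state` (see [elbo()]) with additional fields
#'   `marginals` (list of factor marginals) and `elbo_trace` (monotone
#'   nondecreasing vector of ELBO values after each sweep).
#' @examples
#' # independent 2x2 posterior: the product family contains the truth
#' lik <- as.vector(outer(c(2, 1), c(1, 3)))
#' db <- bayes_update(rep(0.25, 4), lik)
#' fit <- variational_project(db, dims = c(2, 2))
#' fit$free_energy  # ~ 0
#' @export
variational_project <- function(db, dims, steps = 200L, tol = 1e-10) {
  stopifnot(inherits(db, "discrete_bayes"))
  dims <- as.integer(dims)
  if (any(dims < 1L) || prod(dims) != length(db$prior)) {
    stop("`dims` must factor the state space: prod(dims) must equal the number of states",
         call. = FALSE)
  }
  K <- length(dims)
  # log joint (up to the evidence constant): log q + log Ltilde, as an array
  logjoint <- array(log(db$prior) + log(db$unnorm_likelihood), dim = dims)
  marginals <- lapply(dims, function(k) rep(1 / k, k))
  cand <- function() {
    g <- marginals[[1L]]
    if (K > 1L) for (k in 2:K) g <- as.vector(outer(g, marginals[[k]]))
    g
  }
  trace <- elbo(db, cand())$elbo
  for (s in seq_len(steps)) {
    for (k in seq_len(K)) {
      # expected log joint over the other factors, as a function of factor k;
      # apply() flattens the remaining dims first-fastest, matching the nested
      # outer product of the other marginals
      wvec <- if (K == 1L) 1 else {
        Reduce(function(a, b) as.vector(outer(a, b)), marginals[-k])
      }
      other <- apply(logjoint, k, function(slice) sum(slice * wvec))
      other <- other - max(other)
      mk <- exp(other)
      marginals[[k]] <- mk / sum(mk)
    }
    value <- elbo(db, cand())$elbo
    trace <- c(trace, value)
    if (value - trace[length(trace) - 1L] < tol) break
  }
  out <- elbo(db, cand())
  out$marginals <- marginals
  out$elbo_trace <- trace
  out
}
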