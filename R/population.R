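#' Weighted population of parameter vectors
#'
#' Constructs the substrate of the Price equation: a set of `m` classes with
#' strictly positive weights `q` summing to one, an `m x n` matrix of trait
#' (parameter) values `theta`, and relative fitness `w` normalized so that the
#' population mean fitness is one.  Fitness and updated weights are two views
#' of the same change: `q'_i = q_i w_i`.  Optional updated traits `theta'`
#' carry the transmission (value-change) part of an update; when absent the
#' trait values are taken as unchanged.
#'
#' @param weights numeric simplex vector of length `m`; strictly positive,
#'   sums to 1 within `1e-12`.
#' @param traits numeric vector or `m x n` matrix of trait values.
#' @param fitness optional length-`m` relative fitness vector with
#'   `sum(weights * fitness) == 1`.  Exactly one of `fitness` and
#'   `updated_weights` must be supplied unless `normalize = TRUE`, in which
#'   case raw performance values are accepted and renormalized to mean 1
#'   (the raw values are kept in the `"raw_fitness"` attribute).
#' @param updated_weights optional simplex vector `q'`; fitness is then
#'   derived as `q'/q`.  If both `fitness` and `updated_weights` are given
#'   they must agree elementwise (`q'_i = q_i w_i` within `1e-12`).
#' @param updated_traits optional matrix of post-update trait values, same
#'   shape as `traits`.
#' @param labels optional character row identifiers.
#' @param normalize logical; renormalize `fitness` to population mean 1.
#'
#' @return An object of class `fmb_population`: a list with elements
#'   `weights`, `traits`, `fitness`, `updated_weights`, `updated_traits`
#'   (possibly `NULL`), and `labels`.
#'
#' @examples
#' pop <- population(weights = c(0.5, 0.5), traits = c(0, 1),
#'                   updated_weights = c(0.25, 0.75))
#' delta_mean(pop)          # 0.25
#' fmb_decompose(pop)
#' @seealso [fmb_decompose()], [price_partition()], [read_population()]
#' @export
population <- function(weights, traits, fitness = NULL, updated_weights = NULL,
                       updated_traits = NULL, labels = NULL, normalize = FALSE) {
  check_simplex(weights, "weights")
  m <- length(weights)
  traits <- as_trait_matrix(traits, m)
  if (is.null(fitness) && is.null(updated_weights)) {
    stop("supply `fitness` or `updated_weights`", call. = FALSE)
  }
  raw <- NULL
  if (!is.null(fitness)) {
    if (length(fitness) != m) stop("`fitness` has wrong length", call. = FALSE)
    if (any(!is.finite(fitness)) || any(fitness <= 0)) {
      stop("`fitness` must be finite and strictly positive", call. = FALSE)
    }
    wbar <- sum(weights * fitness)
    if (normalize) {
      raw <- fitness
      fitness <- fitness / wbar
    } else if (abs(wbar - 1) > 1e-12) {
      stop(sprintf("mean fitness must be 1 (got %.15g); use normalize = TRUE for raw performance values",
                   wbar), call. = FALSE)
    }
  }
  if (!is.null(updated_weights)) {
    check_simplex(updated_weights, "updated_weights")
    if (length(updated_weights) != m) {
      stop("`updated_weights` has wrong length", call. = FALSE)
    }
    derived <- updated_weights / weights
    if (is.null(fitness)) {
      fitness <- derived
    } else if (max(abs(weights * fitness - updated_weights)) > 1e-12) {
      i <- which.max(abs(weights * fitness - updated_weights))
      stop(sprintf("fitness and updated_weights inconsistent at row %d: q*w = %.15g but q' = %.15g",
                   i, (weights * fitness)[i], updated_weights[i]), call. = FALSE)
    }
  } else {
    updated_weights <- weights * fitness
    # guard against accumulated rounding in the product
    if (abs(sum(updated_weights) - 1) > 1e-12) {
      stop("fitness does not have population mean 1", call. = FALSE)
    }
  }
  if (!is.null(updated_traits)) {
    updated_traits <- as_trait_matrix(updated_traits, m)
    if (ncol(updated_traits) != ncol(traits)) {
      stop("`updated_traits` must match the shape of `traits`", call. = FALSE)
    }
  }
  if (!is.null(labels) && length(labels) != m) {
    stop("`labels` has wrong length", call. = FALSE)
  }
  structure(
    list(weights = weights, traits = traits, fitness = fitness,
         updated_weights = updated_weights, updated_traits = updated_traits,
         labels = labels),
    raw_fitness = raw,
    class = "fmb_population")
}

#' @export
print.fmb_population <- function(x, ...) {
  m <- length(x$weights); n <- ncol(x$traits)
  cat(sprintf("Weighted population: %d classes, %d trait%s%s\n",
              m, n, if (n == 1L) "" else "s",
              if (is.null(x$updated_traits)) "" else " (with updated traits)"))
  cat(sprintf("  mean fitness: %s   Var(w): %s\n",
              format_num(sum(x$weights * x$fitness)),
              format_num(wcov_vec(x$fitness, x$fitness, x$weights))))
  invisible(x)
}

#' @noRd
trait_change <- function(pop) {
  if (is.null(pop$updated_traits)) {
    matrix(0, nrow(pop$traits), ncol(pop$traits))
  } else {
    pop$updated_traits - pop$traits
  }
}

#' Change in the population mean trait vector
#'
#' Computes the total change `q'.theta' - q.theta` of the weighted mean
#' parameter vector across one update.  When updated traits are absent the
#' trait values are held fixed and only reweighting contributes.
#'
#' @param pop an [population()] object.
#' @return numeric length-`n` vector.
#' @examples
#' pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
#' delta_mean(pop)  # 0.25
#' @export
delta_mean <- function(pop) {
  stopifnot(inherits(pop, "fmb_population"))
  thetap <- if (is.null(pop$updated_traits)) pop$traits else pop$updated_traits
  as.numeric(crossprod(pop$updated_weights, thetap) -
               crossprod(pop$weights, pop$traits))
}

#' Price partition of mean change into selection and transmission
#'
#' Splits the total change of the mean trait vector exactly into the
#' frequency-change (selection) term `Cov_q(w, theta)` and the value-change
#' (transmission) term `E_q(w * dtheta)`.  The two terms always sum to
#' [delta_mean()]; this is a notational identity, not an approximation.
#'
#' @param pop an [population()] object.
#' @return list with numeric vectors `selection` and `transmission`.
#' @examples
#' pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75),
#'                   updated_traits = c(0.2, 1.0))
#' price_partition(pop)  # selection 0.25, transmission 0.05
#' @export
price_partition <- function(pop) {
  stopifnot(inherits(pop, "fmb_population"))
  dq <- pop$updated_weights - pop$weights
  selection <- as.numeric(crossprod(dq, pop$traits))
  transmission <- as.numeric(crossprod(pop$updated_weights, trait_change(pop)))
  list(selection = selection, transmission = transmission)
}

#' Trait covariance from the deviation / inverse-frequency-metric form
#'
#' Builds the matrix of trait deviations `J` (rows `theta_i - theta_bar`) and
#' the diagonal frequency information metric `S = diag(1/q)`, and returns
#' `t(J) S^-1 J`.  The result equals the weighted trait covariance
#' `Cov_q(theta, theta)`, linking the metric geometry of frequency space to
#' the covariance metric of trait space.
#'
#' @param pop an [population()] object.
#' @return `n x n` numeric matrix.
#' @export
covariance_from_deviations <- function(pop) {
  stopifnot(inherits(pop, "fmb_population"))
  thetabar <- as.numeric(crossprod(pop$weights, pop$traits))
  J <- sweep(pop$traits, 2L, thetabar, "-")
  crossprod(J, pop$weights * J)   # t(J) %*% diag(q) %*% J, S^-1 = diag(q)
}
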