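#' Frequency change between two points on the simplex interior
#'
#' Packages a pair of strictly positive probability vectors `q -> q'`
#' together with the two canonical descriptions of the change: the
#' Malthusian parameters `m = log(q'/q)` (log relative fitness) and the
#' average excess `a = q'/q - 1 = dq/q` (relative fitness minus one).  These
#' satisfy the conservation identities `q . exp(m) = 1` and `q . a = 0`.
#'
#' @param before simplex vector `q`.
#' @param after simplex vector `q'` of the same length.
#' @return object of class `frequency_change`: list with `before`, `after`,
#'   `malthusian`, `average_excess`.
#' @examples
#' fc <- frequency_change(c(0.5, 0.5), c(0.25, 0.75))
#' fisher_rao_sq(fc)      # 0.25
#' jeffreys_divergence(fc)
#' @export
frequency_change <- function(before, after) {
  check_simplex(before, "before")
  check_simplex(after, "after")
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  w <- after / before
  structure(list(before = before, after = after,
                 malthusian = log(w), average_excess = w - 1),
            class = "frequency_change")
}

#' @export
print.frequency_change <- function(x, ...) {
  cat(sprintf("Frequency change over %d states\n", length(x$before)))
  cat("  F (squared Fisher-Rao step):", format_num(fisher_rao_sq(x)), "\n")
  cat("  Jeffreys divergence       :", format_num(jeffreys_divergence(x)), "\n")
  invisible(x)
}

#' Discrete squared Fisher-Rao step length
#'
#' `F = sum(dq^2 / q)`, the squared length of the frequency step under the
#' Fisher information metric.  Identically equal to the variance in relative
#' fitness `Var_q(w)` with `w = q'/q`, and to the Shahshahani quadratic form
#' in the average excess ([shahshahani_form()]).
#'
#' @param change a [frequency_change()] object.
#' @return nonnegative scalar.
#' @export
fisher_rao_sq <- function(change) {
  stopifnot(inherits(change, "frequency_change"))
  dq <- change$after - change$before
  sum(dq^2 / change$before)
}

#' Kullback-Leibler divergence of discrete distributions
#'
#' `D(p || q) = sum(p * log(p/q))` with natural logarithms; nonnegative and
#' zero only at `p = q`.  Both arguments must lie strictly inside the
#' simplex.
#'
#' @param p,q simplex vectors of equal length.
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(p, q) {
  check_simplex(p, "p")
  check_simplex(q, "q")
  if (length(p) != length(q)) stop("`p` and `q` must have equal length", call. = FALSE)
  # log1p((p - q)/q) equals log(p/q) but keeps full precision when the two
  # distributions are nearly equal, where the naive form loses ~5 digits
  sum(p * log1p((p - q) / q))
}

#' Jeffreys (symmetrized Kullback-Leibler) divergence
#'
#' Returns `D(q'||q) + D(q||q')`.  Through the Price equation this equals the
#' selection term for the Malthusian parameter, `dq . m`: the symmetrized
#' divergence is the partial change in mean log fitness caused by frequency
#' change.
#'
#' @param change a [frequency_change()] object.
#' @return nonnegative scalar.
#' @export
jeffreys_divergence <- function(change) {
  stopifnot(inherits(change, "frequency_change"))
  kl_divergence(change$after, change$before) +
    kl_divergence(change$before, change$after)
}

#' Square-root coordinates for frequencies
#'
#' Maps a simplex vector to `r = sqrt(q)`, which has unit Euclidean norm so
#' that all frequency dynamics live on the positive orthant of the unit
#' sphere.  In these coordinates the squared Fisher-Rao step length of an
#' infinitesimal change is four times the squared Euclidean step.
#'
#' @param q simplex vector with strictly positive entries.
#' @return unit-norm numeric vector.
#' @export
sqrt_coordinates <- function(q) {
  check_simplex(q, "q")
  sqrt(q)
}

#' Shahshahani quadratic form in the average excess
#'
#' Evaluates `a' S^-1 a` where `a = dq/q` is the average excess in fitness
#' and `S = diag(1/q)` is the Fisher information (Shahshahani) metric of
#' frequency space, so `S^-1 = diag(q)`.  Identically equal to
#' [fisher_rao_sq()]: force `a` and metric `S^-1` give the same squared step.
#'
#' @param change a [frequency_change()] object.
#' @return nonnegative scalar.
#' @export
shahshahani_form <- function(change) {
  stopifnot(inherits(change, "frequency_change"))
  a <- change$average_excess
  sum(change$before * a^2)
}

#' Small-step limits of the information-geometric ratios
#'
#' For perturbations `q' = q + eps * direction` along a zero-sum direction,
#' tabulates the discrete squared Fisher-Rao step `F` against (i) the squared
#' Euclidean step in square-root coordinates (ratio converging to 4) and (ii)
#' the Kullback-Leibler divergence `D(q'||q)` (ratio converging to 2), plus a
#' finite-difference residual of the frequency-space force balance (direct
#' Malthusian force plus inertial log-force change dotted with the
#' displacement), evaluated over the two halved sub-steps
#' `q -> q + eps/2 * direction -> q'`; the residual vanishes at order
#' `eps^3`.  A Richardson extrapolation row (`scale = 0`) reports the limits
#' estimated from the three smallest scales.
#'
#' @param q simplex vector.
#' @param direction numeric zero-sum direction vector (`sum = 0` within
#'   `1e-12`); `q + scale * direction` must stay strictly positive.
#' @param scales decreasing positive step scales; default `1e-2 * 2^-(0:6)`.
#' @return `data.frame` with columns `scale`, `F`, `ratio_sqrt`
#'   (`F/||dr||^2`), `ratio_kl` (`F/D`), `dalembert_residual`; the final row
#'   has `scale = 0` and carries the Richardson-extrapolated ratio limits.
#' @examples
#' q <- rep(0.2, 5)
#' d <- c(1, -1, 0.5, -0.25, -0.25)
#' limit_ratio_suite(q, d, scales = 1e-6)
#' @export
limit_ratio_suite <- function(q, direction,
                              scales = 1e-2 * 2^-(0:6)) {
  check_simplex(q, "q")
  if (length(direction) != length(q)) {
    stop("`direction` has wrong length", call. = FALSE)
  }
  if (abs(sum(direction)) > 1e-12 * max(1, max(abs(direction)))) {
    stop("`direction` must sum to zero", call. = FALSE)
  }
  scales <- sort(as.numeric(scales), decreasing = TRUE)
  if (any(scales <= 0)) stop("`scales` must be positive", call. = FALSE)
  rows <- lapply(scales, function(eps) {
    qp <- q + eps * direction
    if (any(qp <= 0)) {
      stop(sprintf("scale %.3g leaves the simplex interior", eps), call. = FALSE)
    }
    fc <- frequency_change(q, qp)  # zero-sum direction keeps qp on the simplex
    Fv <- fisher_rao_sq(fc)
    dr <- sqrt(qp) - sqrt(q)
    Dv <- kl_divergence(qp, q)
    data.frame(scale = eps, F = Fv,
               ratio_sqrt = Fv / sum(dr^2),
               ratio_kl = Fv / Dv,
               dalembert_residual = dalembert_substep_residual(q, direction, eps))
  })
  out <- do.call(rbind, rows)
  # Richardson extrapolation on the last three scales (error is O(eps), so
  # halving the scale halves the error: limit ~ 2 r(eps/2) - r(eps))
  k <- nrow(out)
  extrap <- function(v) {
    if (k >= 2L) 2 * v[k] - v[k - 1L] else v[k]
  }
  out <- rbind(out,
               data.frame(scale = 0, F = 0,
                          ratio_sqrt = extrap(out$ratio_sqrt),
                          ratio_kl = extrap(out$ratio_kl),
                          dalembert_residual = 0))
  rownames(out) <- NULL
  out
}

# Finite-difference force-balance residual over two halved sub-steps:
# |(m + dlog m) . dq| with m the Malthusian of the first sub-step and
# dlog m the change in elementwise log magnitude of the Malthusian between
# sub-steps.  Entries with zero direction component carry no displacement
# and contribute zero.  Taylor expansion shows the residual is O(eps^3).
#' @noRd
dalembert_substep_residual <- function(q, direction, eps) {
  qh <- q + (eps / 2) * direction
  qp <- q + eps * direction
  live <- direction != 0
  m1 <- log(qh[live] / q[live])
  m2 <- log(qp[live] / qh[live])
  dq <- (eps / 2) * direction[live]
  abs(sum((m1 + log(m2 / m1)) * dq))
}

#' Conservation of normalized likelihood across a Bayes update
#'
#' Normalizes a positive likelihood vector to population mean one under the
#' prior (`L`, with `q . L = 1`), forms the posterior `q' = q * L`, and
#' renormalizes the same raw likelihoods under the posterior (`L'`).  The
#' direct gain `dq . L` and the inertial decay `q' . (L' - L)` then cancel
#' exactly: the mean normalized likelihood is conserved at 1, so its total
#' change telescopes to zero.
#'
#' @param q prior simplex vector.
#' @param unnorm_likelihood strictly positive likelihood vector.
#' @return list with `direct_term`, `inertial_term`, `total` (zero to
#'   machine precision).
#' @export
conserved_likelihood_check <- function(q, unnorm_likelihood) {
  check_simplex(q, "q")
  lik <- as.numeric(unnorm_likelihood)
  if (length(lik) != length(q)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(lik)) || any(lik <= 0)) {
    stop("`unnorm_likelihood` must be strictly positive", call. = FALSE)
  }
  L <- lik / sum(q * lik)
  qp <- q * L
  Lp <- lik / sum(qp * lik)
  direct <- sum((qp - q) * L)
  inertial <- sum(qp * (Lp - L))
  list(direct_term = direct, inertial_term = inertial,
       total = direct + inertial)
}
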