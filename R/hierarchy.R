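#' Two-level grouped population
#'
#' Nests member populations inside groups for the recursive Price equation.
#' Group weights `q_g` form a simplex; within each group the member weights
#' `q_{j|g}` form their own simplex and member fitness has within-group mean
#' one (the ordinary [population()] convention).  The global scale is
#' carried by the group mean fitness `wbar_g`, which must satisfy
#' `sum(q_g * wbar_g) = 1`; a member's globally scaled fitness is
#' `wbar_g * w_{j|g}`.  Flattening multiplies weights (`q_g * q_{j|g}`) and
#' fitnesses (`wbar_g * w_{j|g}`) and yields an ordinary valid
#' [population()].
#'
#' Members built with `population(..., normalize = TRUE)` from raw,
#' globally comparable performance values carry those raw values in their
#' `"raw_fitness"` attribute; when `group_fitness` is omitted it is
#' recovered from them (`wbar_g` proportional to the raw within-group mean,
#' rescaled so the global mean is one).
#'
#' @param group_weights simplex vector over groups.
#' @param members list of [population()] objects, one per group, sharing a
#'   common trait dimension.
#' @param group_fitness optional vector `wbar_g` with
#'   `sum(group_weights * group_fitness) = 1`.
#' @return object of class `fmb_grouped_population`.
#' @seealso [flatten_population()], [hierarchical_partition()],
#'   [hierarchical_fmb()]
#' @export
grouped_population <- function(group_weights, members, group_fitness = NULL) {
  check_simplex(group_weights, "group_weights")
  if (!is.list(members) || length(members) != length(group_weights)) {
    stop("`members` must be a list of populations, one per group", call. = FALSE)
  }
  ok <- vapply(members, inherits, logical(1), "fmb_population")
  if (!all(ok)) stop("every member must be an fmb_population", call. = FALSE)
  n <- ncol(members[[1L]]$traits)
  if (!all(vapply(members, function(p) ncol(p$traits), integer(1)) == n)) {
    stop("all groups must share the trait dimension", call. = FALSE)
  }
  if (is.null(group_fitness)) {
    raw <- lapply(members, attr, "raw_fitness")
    if (any(vapply(raw, is.null, logical(1)))) {
      group_fitness <- rep(1, length(members))
    } else {
      rawbar <- mapply(function(p, r) sum(p$weights * r), members, raw)
      group_fitness <- rawbar / sum(group_weights * rawbar)
    }
  }
  if (length(group_fitness) != length(members) || any(group_fitness <= 0)) {
    stop("`group_fitness` must be positive, one value per group", call. = FALSE)
  }
  gbar <- sum(group_weights * group_fitness)
  if (abs(gbar - 1) > 1e-10) {
    stop(sprintf("global mean fitness must be 1 (got %.12g)", gbar), call. = FALSE)
  }
  structure(list(group_weights = group_weights, members = members,
                 group_fitness = as.numeric(group_fitness)),
            class = "fmb_grouped_population")
}

#' @export
print.fmb_grouped_population <- function(x, ...) {
  sizes <- vapply(x$members, function(p) length(p$weights), integer(1))
  cat(sprintf("Grouped population: %d groups (sizes %s)\n",
              length(sizes), paste(sizes, collapse = ", ")))
  cat("  group mean fitness:", format_num(x$group_fitness), "\n")
  invisible(x)
}

#' Flatten a grouped population
#'
#' Produces the ordinary single-level population whose class weights are the
#' products `q_g * q_{j|g}` and whose fitness, traits, and updated traits
#' are the members' own.  The flat Price partition of this population is the
#' conservation oracle for [hierarchical_partition()].
#'
#' @param gpop an [grouped_population()] object.
#' @return an [population()].
#' @export
flatten_population <- function(gpop) {
  stopifnot(inherits(gpop, "fmb_grouped_population"))
  qs <- unlist(lapply(seq_along(gpop$members), function(g) {
    gpop$group_weights[g] * gpop$members[[g]]$weights
  }))
  traits <- do.call(rbind, lapply(gpop$members, `[[`, "traits"))
  w <- unlist(lapply(seq_along(gpop$members), function(g) {
    gpop$group_fitness[g] * gpop$members[[g]]$fitness
  }))
  any_dtheta <- any(!vapply(gpop$members, function(p) is.null(p$updated_traits),
                            logical(1)))
  thetap <- if (any_dtheta) {
    do.call(rbind, lapply(gpop$members, function(p) {
      if (is.null(p$updated_traits)) p$traits else p$updated_traits
    }))
  } else NULL
  population(weights = qs, traits = traits, fitness = w,
             updated_traits = thetap, normalize = TRUE)
}

# Group-level summaries under the module's weighting convention:
# within-group moments use q_{j|g} and within-group-normalized fitness;
# the global scale wbar_g multiplies each group's Price terms (Cov and E
# under global fitness are wbar_g times the within-normalized versions).
#' @noRd
group_summaries <- function(gpop) {
  members <- gpop$members
  list(
    wbar = gpop$group_fitness,
    thetabar = do.call(rbind, lapply(members, function(p) {
      as.numeric(crossprod(p$weights, p$traits))
    })),
    # wbar_g * dthetabar_g = Cov_j(w, theta) + E_j(w dtheta) on global scale
    within_terms = Map(function(wb, p) {
      pp <- price_partition(p)
      wb * (pp$selection + pp$transmission)
    }, as.list(gpop$group_fitness), members))
}

#' Recursive (two-level) Price partition
#'
#' Splits the total change of the global mean trait vector into the
#' between-group selection term, `Cov_g(wbar_g, thetabar_g)`, and the
#' within-group remainder, `E_g(wbar_g * dthetabar_g)`, with each group's
#' contribution expanded by its own Price equation into within-group
#' selection plus transmission.  The two levels sum exactly to the flat
#' Price total of the flattened population.
#'
#' @param gpop an [grouped_population()] object.
#' @return list with numeric vectors `between` and `within`.
#' @export
hierarchical_partition <- function(gpop) {
  stopifnot(inherits(gpop, "fmb_grouped_population"))
  gs <- group_summaries(gpop)
  qg <- gpop$group_weights
  between <- as.numeric(crossprod(qg * (gs$wbar - sum(qg * gs$wbar)),
                                  gs$thetabar))
  within <- Reduce(`+`, Map(function(qgg, term) qgg * term,
                            as.list(qg), gs$within_terms))
  list(between = between, within = within)
}

#' Hierarchical force-metric-bias decomposition
#'
#' The two-level FMB law: between-group metric `M_B = Cov_g(thetabar)` and
#' force `f_B` (group-level fitness regression), within-group metrics `M_g`
#' and forces `f_g` per group, within-group biases `b_g = E_j(w dtheta)`
#' centered as `b_g = b_B + btilde_g` with `b_B = E_g(b_g)` so the residuals
#' average to zero.  The reconstruction
#' `M_B f_B + b_B + E_g(M_g f_g + btilde_g)` equals the flat total change;
#' the total metric obeys the law of total covariance
#' `M = M_B + E_g(M_g)`, and the composite force
#' `f = M^-1 (M_B f_B + E_g(M_g f_g))` equals the flat pooled regression
#' force whenever `M` is nonsingular.
#'
#' @param gpop an [grouped_population()] object.
#' @return object of class `hierarchical_fmb`: list with `between_metric`,
#'   `between_force`, `between_bias`, `within_metrics`, `within_forces`,
#'   `within_bias_residuals`, `total_metric`, `composite_force`,
#'   `reconstruction`, and `singular` flags.
#' @export
hierarchical_fmb <- function(gpop) {
  stopifnot(inherits(gpop, "fmb_grouped_population"))
  qg <- gpop$group_weights
  gs <- group_summaries(gpop)
  G <- length(qg)

  MB <- symmetrize(wcov(gs$thetabar, gs$thetabar, qg))
  fB_fit <- weighted_regression(gs$wbar, gs$thetabar, qg)

  # global-scale within-group force and bias: regression of wbar_g * w on
  # theta scales the within-normalized coefficients by wbar_g, as does the
  # transmission expectation
  per_group <- Map(function(wb, p) {
    d <- fmb_decompose(p)
    list(M = d$metric, f = wb * d$force,
         b = wb * d$transmission_term, singular = any(d$singular["metric"]))
  }, as.list(gpop$group_fitness), gpop$members)
  Mg <- lapply(per_group, `[[`, "M")
  fg <- lapply(per_group, `[[`, "f")
  bg <- lapply(per_group, `[[`, "b")

  bB <- Reduce(`+`, Map(function(q, b) q * b, as.list(qg), bg))
  btilde <- lapply(bg, function(b) b - bB)

  EMg <- Reduce(`+`, Map(function(q, M) q * M, as.list(qg), Mg))
  EMgfg <- Reduce(`+`, Map(function(q, M, f) q * as.numeric(M %*% f),
                           as.list(qg), Mg, fg))
  Ebt <- Reduce(`+`, Map(function(q, b) q * b, as.list(qg), btilde))

  total_metric <- MB + EMg
  MBfB <- as.numeric(MB %*% fB_fit$coefficients)
  reconstruction <- MBfB + bB + EMgfg + Ebt

  n <- ncol(total_metric)
  rk <- qr(total_metric, tol = 1e-10)$rank
  composite_force <- if (rk == n) {
    as.numeric(solve(total_metric, MBfB + EMgfg))
  } else {
    as.numeric(MASS::ginv(total_metric) %*% (MBfB + EMgfg))
  }

  structure(
    list(between_metric = MB,
         between_force = fB_fit$coefficients,
         between_bias = bB,
         within_metrics = Mg,
         within_forces = fg,
         within_bias_residuals = btilde,
         total_metric = total_metric,
         composite_force = composite_force,
         reconstruction = reconstruction,
         singular = c(between = fB_fit$singular,
                      total = rk < n,
                      within = any(vapply(per_group, `[[`, logical(1), "singular")))),
    class = "hierarchical_fmb")
}

#' @export
print.hierarchical_fmb <- function(x, ...) {
  cat("Hierarchical FMB decomposition\n")
  cat("  between M_B f_B :",
      format_num(as.numeric(x$between_metric %*% x$between_force)), "\n")
  cat("  bias b_B        :", format_num(x$between_bias), "\n")
  cat("  reconstruction  :", format_num(x$reconstruction), "\n")
  if (any(x$singular)) {
    cat("  note: singular", paste(names(x$singular)[x$singular], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Analytic hit probability of the bit-flip learning trial
#'
#' Probability that at least one of `trials` independent learning trials,
#' each flipping every bit independently with probability `flip_prob`,
#' converts a string at Hamming distance `d` from the target into an exact
#' match: `1 - (1 - flip_prob^d (1 - flip_prob)^(L - d))^trials`.  Strictly
#' decreasing in `d` when `flip_prob < 1/2`, which is what turns the
#' needle-in-a-haystack match into a smooth fitness gradient.
#'
#' @param d Hamming distance(s) to the target.
#' @param L string length.
#' @param flip_prob per-bit flip probability in `(0, 1/2)`.
#' @param trials number of learning trials per lifetime.
#' @return hit probability, vectorized over `d`.
#' @export
baldwin_hit_prob <- function(d, L, flip_prob, trials) {
  stopifnot(flip_prob > 0, flip_prob < 0.5, L >= 1, trials >= 0)
  p_one <- flip_prob^d * (1 - flip_prob)^(L - d)
  # -expm1(trials * log1p(-p)) keeps full precision for the tiny hit
  # probabilities at large Hamming distance
  -expm1(trials * log1p(-p_one))
}

#' Baldwin-effect simulation: nonheritable learning smooths selection
#'
#' A population of binary strings evolves toward a fixed target.  Each
#' generation every individual runs `trials_G` learning trials (independent
#' per-bit flips of its inherited string at rate `flip_prob`); effective
#' fitness is `1 + bonus` on a hit and `1` otherwise (`mode = "sampled"`),
#' or `1 + bonus * P(hit | d)` with the analytic hit probability
#' (`mode = "expectation"`).  Selection resamples *seed* strings in
#' proportion to effective fitness; what an individual learned is never
#' transmitted.  With `trials_G = 0` fitness rewards only an exact match,
#' whose probability for a random string is `2^-L` — learning converts that
#' spike into a gradient that selection can climb.  Uses the current RNG
#' state; seed with `set.seed`.
#'
#' @param L string length (target is fixed; strings are compared by Hamming
#'   distance so the target can be taken as all-ones without loss).
#' @param pop_size number of individuals.
#' @param flip_prob per-bit learning flip probability in `(0, 1/2)`.
#' @param trials_G learning trials per individual per generation.
#' @param bonus fitness bonus for hitting the target.
#' @param generations number of generations to run.
#' @param mode `"expectation"` (analytic hit probability, default) or
#'   `"sampled"` (simulate the trials).
#' @return `data.frame` trace with columns `generation`, `mean_hamming`
#'   (mean distance of seed strings to the target), `max_fitness` (largest
#'   effective fitness in the population).
#' @export
baldwin_simulation <- function(L = 20L, pop_size = 200L, flip_prob = 0.05,
                               trials_G = 10L, bonus = 19, generations = 50L,
                               mode = c("expectation", "sampled")) {
  stopifnot(L >= 1L, pop_size >= 2L, flip_prob > 0, flip_prob < 0.5,
            trials_G >= 0L, generations >= 1L)
  mode <- match.arg(mode)
  # genomes: pop_size x L logical, target = all TRUE
  genomes <- matrix(stats::runif(pop_size * L) < 0.5, pop_size, L)
  trace <- vector("list", generations)
  for (gen in seq_len(generations)) {
    d <- L - rowSums(genomes)
    if (trials_G == 0L) {
      hit <- as.numeric(d == 0L)
    } else if (mode == "expectation") {
      hit <- baldwin_hit_prob(d, L, flip_prob, trials_G)
    } else {
      hit <- vapply(seq_len(pop_size), function(i) {
        for (tr in seq_len(trials_G)) {
          flips <- stats::runif(L) < flip_prob
          if (all(xor(genomes[i, ], flips))) return(1)
        }
        0
      }, numeric(1))
    }
    fitness <- 1 + bonus * hit
    trace[[gen]] <- data.frame(generation = gen,
                               mean_hamming = mean(d),
                               max_fitness = max(fitness))
    parents <- sample.int(pop_size, pop_size, replace = TRUE,
                          prob = fitness / sum(fitness))
    genomes <- genomes[parents, , drop = FALSE]  # seeds only: learning not inherited
  }
  do.call(rbind, trace)
}

#' Two-timescale lookahead wrapper
#'
#' Runs any inner step rule for `inner_steps_k` fast steps from the current
#' slow parameters, then blends the slow parameters toward the inner result:
#' `theta_slow <- theta_slow + blend_alpha * (theta_fast - theta_slow)`.
#' With `blend_alpha = 1` the wrapper reduces to plain inner optimization.
#' The fast inner loop plays the role of within-group learning and the
#' blend the role of between-level selection-and-transmission in the
#' hierarchical decomposition.
#'
#' @param inner_step function `theta -> theta` performing one inner update.
#' @param theta0 starting parameter vector.
#' @param inner_steps_k inner steps per outer round.
#' @param blend_alpha blending rate in `(0, 1]`.
#' @param outer_steps number of outer rounds.
#' @return matrix of slow-parameter iterates, `(outer_steps + 1) x n`, first
#'   row `theta0`.
#' @export
lookahead_wrap <- function(inner_step, theta0, inner_steps_k, blend_alpha,
                           outer_steps) {
  stopifnot(is.function(inner_step), inner_steps_k >= 1L,
            blend_alpha > 0, blend_alpha <= 1, outer_steps >= 1L)
  slow <- as.numeric(theta0)
  out <- matrix(NA_real_, outer_steps + 1L, length(slow))
  out[1L, ] <- slow
  for (r in seq_len(outer_steps)) {
    fast <- slow
    for (k in seq_len(inner_steps_k)) fast <- inner_step(fast)
    slow <- slow + blend_alpha * (fast - slow)
    out[r + 1L, ] <- slow
  }
  out
}
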