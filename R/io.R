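#' Read a population table
#'
#' Reads a delimited text table (TSV by default; comma-separated accepted
#' via `sep` or a `.csv` extension) describing a weighted population.
#' Required columns: `q` and one of `w` or `q_prime`; trait columns
#' `theta_1 .. theta_n`; optional `theta_prime_1 .. theta_prime_n`,
#' optional `group`, optional `id`.  All invariants of [population()] are
#' validated and violations are reported with the offending row.  When a
#' `group` column is present a [grouped_population()] is returned: member
#' weights are renormalized within groups and the group weights are taken
#' proportional to the summed raw weights.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return an [population()] or [grouped_population()].
#' @seealso [write_population()]
#' @export
read_population <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  build_population_from_table(tab, source = path)
}

#' @noRd
build_population_from_table <- function(tab, source = "table") {
  cols <- names(tab)
  if (!"q" %in% cols) stop(sprintf("%s: missing required column `q`", source), call. = FALSE)
  has_w <- "w" %in% cols
  has_qp <- "q_prime" %in% cols
  if (!has_w && !has_qp) {
    stop(sprintf("%s: need column `w` or `q_prime`", source), call. = FALSE)
  }
  theta_cols <- grep("^theta_[0-9]+$", cols, value = TRUE)
  if (length(theta_cols) == 0L) {
    stop(sprintf("%s: no trait columns `theta_1..theta_n`", source), call. = FALSE)
  }
  theta_cols <- theta_cols[order(as.integer(sub("^theta_", "", theta_cols)))]
  tp_cols <- grep("^theta_prime_[0-9]+$", cols, value = TRUE)
  tp_cols <- tp_cols[order(as.integer(sub("^theta_prime_", "", tp_cols)))]
  if (length(tp_cols) > 0L && length(tp_cols) != length(theta_cols)) {
    stop(sprintf("%s: %d theta_prime columns for %d theta columns", source,
                 length(tp_cols), length(theta_cols)), call. = FALSE)
  }
  labels <- if ("id" %in% cols) as.character(tab$id) else NULL

  make_pop <- function(rows, renorm_q = FALSE) {
    q <- as.numeric(rows$q)
    if (any(!is.finite(q)) || any(q <= 0)) {
      stop(sprintf("%s: nonpositive or missing weight at row %d", source,
                   which(!is.finite(q) | q <= 0)[1L]), call. = FALSE)
    }
    if (renorm_q) q <- q / sum(q)
    if (abs(sum(q) - 1) > 1e-8) {
      stop(sprintf("%s: weights sum to %.12g, not 1", source, sum(q)), call. = FALSE)
    }
    q <- q / sum(q)
    theta <- as.matrix(rows[theta_cols])
    thetap <- if (length(tp_cols) > 0L) as.matrix(rows[tp_cols]) else NULL
    w <- if (has_w) as.numeric(rows$w) else NULL
    qp <- if (has_qp) as.numeric(rows$q_prime) else NULL
    if (has_w && has_qp) {
      bad <- abs(q * w - qp) > 1e-8
      if (any(bad)) {
        stop(sprintf("%s: `w` and `q_prime` inconsistent at row %d (q*w = %.12g, q' = %.12g)",
                     source, which(bad)[1L], (q * w)[which(bad)[1L]],
                     qp[which(bad)[1L]]), call. = FALSE)
      }
    }
    if (!is.null(qp)) qp <- qp / sum(qp)
    population(weights = q, traits = theta,
               fitness = if (is.null(qp)) w else NULL,
               updated_weights = qp, updated_traits = thetap,
               labels = if (is.null(labels)) NULL else as.character(rows$id),
               normalize = is.null(qp))
  }

  if ("group" %in% cols) {
    groups <- split(tab, tab$group)
    qg_raw <- vapply(groups, function(g) sum(as.numeric(g$q)), numeric(1))
    qg <- unname(qg_raw / sum(qg_raw))
    members <- unname(lapply(groups, make_pop, renorm_q = TRUE))
    # global scale: raw fitness (or q'/q) is comparable across groups; the
    # per-group mean of the raw values sets wbar_g
    raw <- lapply(members, function(p) {
      r <- attr(p, "raw_fitness"); if (is.null(r)) p$fitness else r
    })
    rawbar <- unname(mapply(function(p, r) sum(p$weights * r), members, raw))
    grouped_population(qg, members, group_fitness = rawbar / sum(qg * rawbar))
  } else {
    make_pop(tab)
  }
}

#' Write a population table
#'
#' Writes the delimited format read by [read_population()], with numbers at
#' 12 significant digits so that a read-write round trip is value-identical
#' at printed precision.
#'
#' @param pop an [population()] object.
#' @param path output path; extension `.csv` selects comma separation.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, sep = NULL) {
  stopifnot(inherits(pop, "fmb_population"))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  n <- ncol(pop$traits)
  out <- data.frame(q = pop$weights, w = pop$fitness)
  theta <- as.data.frame(pop$traits)
  names(theta) <- paste0("theta_", seq_len(n))
  out <- cbind(out, theta)
  if (!is.null(pop$updated_traits)) {
    tp <- as.data.frame(pop$updated_traits)
    names(tp) <- paste0("theta_prime_", seq_len(n))
    out <- cbind(out, tp)
  }
  if (!is.null(pop$labels)) out <- cbind(id = pop$labels, out)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a random valid population
#'
#' Seeded synthetic fixture generator used by the identity test suites and
#' examples.  Weights are symmetric Dirichlet (concentration
#' `dirichlet_alpha`), traits are standard Gaussian, and fitness comes from
#' the chosen model, renormalized to population mean one:
#'
#' * `"linear"`: `w` proportional to `1 + slope . (theta - thetabar) +
#'   noise`, clamped away from zero — the regression force recovers `slope`
#'   when `noise_sd = 0`.
#' * `"boltzmann"`: `w` proportional to `exp(-||theta||^2 / 4)`.
#' * `"constant"`: `w = 1`, no selection.
#'
#' Optional trait updates: `delta = "none"` (no transmission), `"gamma"`
#' (a shared constant shift — pure intrinsic bias), or `"correlated"`
#' (shifts correlated with fitness — nonzero `C beta`).  Uses the current
#' RNG state; seed with `set.seed`.
#'
#' @param m number of classes (at least 2).
#' @param n trait dimension.
#' @param fitness_model `"linear"`, `"boltzmann"`, or `"constant"`.
#' @param slope length-`n` slope of the linear fitness map (default all
#'   0.5).
#' @param noise_sd fitness noise standard deviation (default 0.1).
#' @param delta trait-update structure: `"none"`, `"gamma"`, `"correlated"`.
#' @param dirichlet_alpha Dirichlet concentration for the weights.
#' @return an [population()].
#' @export
generate_population <- function(m, n = 1L,
                                fitness_model = c("linear", "boltzmann", "constant"),
                                slope = rep(0.5, n), noise_sd = 0.1,
                                delta = c("none", "gamma", "correlated"),
                                dirichlet_alpha = 2) {
  stopifnot(m >= 2L, n >= 1L)
  fitness_model <- match.arg(fitness_model)
  delta <- match.arg(delta)
  g <- stats::rgamma(m, shape = dirichlet_alpha, rate = 1)
  q <- g / sum(g)
  theta <- matrix(stats::rnorm(m * n), m, n)
  u <- switch(fitness_model,
              linear = {
                tc <- sweep(theta, 2L, as.numeric(crossprod(q, theta)), "-")
                raw <- 1 + as.numeric(tc %*% slope) + stats::rnorm(m, sd = noise_sd)
                pmax(raw, 0.05)
              },
              boltzmann = exp(-rowSums(theta^2) / 4),
              constant = rep(1, m))
  thetap <- switch(delta,
                   none = NULL,
                   gamma = theta + matrix(stats::rnorm(n, sd = 0.3),
                                          m, n, byrow = TRUE),
                   correlated = theta + 0.2 * (u / sum(q * u) - 1) +
                     matrix(stats::rnorm(m * n, sd = 0.05), m, n))
  population(weights = q, traits = theta, fitness = u,
             updated_traits = thetap, normalize = TRUE)
}

#' Generate a random valid grouped population
#'
#' Builds a two-level fixture: `G` groups with Dirichlet group weights,
#' each group an independent [generate_population()] draw, and positive
#' group mean fitnesses normalized to global mean one.
#'
#' @param G number of groups.
#' @param members_per_group classes per group.
#' @param n trait dimension.
#' @param ... passed to [generate_population()].
#' @return an [grouped_population()].
#' @export
generate_grouped_population <- function(G = 3L, members_per_group = 4L,
                                        n = 1L, ...) {
  gw <- stats::rgamma(G, shape = 2)
  gw <- gw / sum(gw)
  members <- lapply(seq_len(G), function(i) {
    generate_population(members_per_group, n, ...)
  })
  wbar <- stats::rgamma(G, shape = 4, rate = 4) + 0.2
  grouped_population(gw, members, group_fitness = wbar / sum(gw * wbar))
}
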