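---
title: "The force-metric-bias decomposition of selection and learning updates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The force-metric-bias decomposition of selection and learning updates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmblaw)
```

## The model

Consider a weighted population of `m` classes with frequencies `q` (strictly
positive, summing to one), trait vectors `theta_i` of dimension `n`, and
relative fitness `w_i = q'_i / q_i` normalized so that mean fitness is one.
The change in the mean trait vector partitions exactly into

    delta theta_bar = Cov_q(w, theta) + E_q(w * delta theta),

a frequency-change (selection) term plus a value-change (transmission) term.
This is the Price equation: a notational identity, true for any valid
population, with no modelling assumptions.

Writing the fitness-trait covariance through the weighted regression of `w`
on `theta` (coefficients `f`, trait covariance `M`) and the transmission
term through the regression of `w` on the trait changes (coefficients
`beta`, change covariance `C`, mean change `gamma`) turns the same identity
into the force-metric-bias (FMB) law

    delta theta_bar = M f + C beta + gamma  (+ xi for stochastic updates).

`M` is a metric: in populations it is the trait covariance (no variation in
a direction means no movement along it); in local optimizers it is an
inverse curvature — the inverse negative Hessian (Newton), an inverse Fisher
information matrix (natural gradient), the inverse Hessian of a convex
potential (mirror descent), or a running diagonal estimate (adaptive-metric
momentum).  `f` is the force: a fitness regression in populations, a
performance gradient in local methods.  `b = C beta + gamma` is bias —
momentum, shrinkage toward a prior, frame-of-reference change — and `xi` is
exploration noise.  Every update rule in this package returns its step
*together with* these components, and the `fmb_step()` constructor refuses
any step that its own decomposition does not reproduce to machine
precision.

## Conventions that the identities require

* **Initial-weight population moments.**  All covariances and expectations
  are weighted by the *initial* `q` and use population (divisor `m`-free)
  moments.  The exact identities fail under sample (`m/(m-1)`) moments.
  One visible consequence: the mean update of the evolution strategy has
  expectation `slope * sigma^2 * (m - 1) / m` on a linear surface, because
  the sample covariance of `m` draws carries that factor.
* **Fitness normalized to mean one.**  Constructors either require
  `sum(q * w) = 1` (tolerance `1e-12`) or renormalize raw performance with
  `normalize = TRUE`, keeping the raw values in an attribute.
* **Regression with intercept.**  The force `f` is defined by the
  `q`-weighted least squares of fitness on traits *with* an intercept; only
  then does `Cov_q(w, theta) = M f` hold for uncentered predictors.  (The
  intercept itself is `1 - theta_bar . f` and never enters the law.)
* **Strict simplex interior.**  Zero weights are rejected everywhere:
  `delta q / q`, Malthusian parameters, and KL divergences all divide by
  `q`.  Extinct classes must be pruned upstream.
* **Maximization is primary.**  Performance `U` is a benefit; minimizers
  negate `U`, which flips the sign conventions of gradient and Hessian.

## Degenerate inputs and numerical choices

* **Singular covariances.**  When the centered trait (or trait-change)
  covariance is rank-deficient, `f` (or `beta`) is the minimum-norm
  Moore-Penrose solution and a `singular` flag is set — never silently.
  `M f` still reproduces `Cov_q(w, theta)` because that covariance lies in
  the column space of `M`.
* **Identity tolerances.**  Exact identities are asserted at `1e-10`
  absolute / `1e-8` relative; pure rearrangements (conservation of
  normalized likelihood, the static force balance) at `1e-12`.
* **KL near equality.**  `kl_divergence()` evaluates
  `sum(p * log1p((p - q)/q))`; the naive `log(p/q)` form loses about five
  digits when the distributions differ at relative scale `1e-6`, which
  matters for the small-step limit ratios below.
* **Langevin noise.**  The matrix square root for `xi = sqrt(2 eta) M^(1/2)
  eps` uses the symmetric eigendecomposition, not Cholesky, so the root is
  symmetric and the draw order (exactly `n` standard normals per step) is
  reproducible.
* **Kalman covariance.**  The posterior covariance uses the Joseph form,
  which preserves symmetry and positive semidefiniteness over long runs.
* **Gaussian-process conditioning.**  The FMB metric
  `(K^-1 + sigma^-2 I)^-1` requires inverting the kernel matrix; when `K`
  has reciprocal condition number below `1e-12` a jitter of
  `1e-10 * sigma_g^2` is added to its diagonal and flagged.  Smooth kernels
  at long length scales are intrinsically ill-conditioned; the oracle
  equivalence with `K (K + sigma^2 I)^-1` is then limited by conditioning,
  not by the identity.
* **Newton on indefinite curvature.**  A `MetricNotPD` condition is raised;
  callers may pass a damping `lambda` to use `(-H + lambda I)^-1`.
* **BFGS orientation.**  The inverse-metric estimate approximates
  `(-H)^-1` under maximization, so the secant pair is `(s, -dgrad)`;
  updates are skipped (with a flag) when the curvature condition fails.
  On a quadratic with exact line searches the estimate reaches the true
  inverse after `n` steps — the finite-termination oracle used in the
  tests; arbitrary probe steps do not have this property.
* **Adaptive-metric momentum.**  The primary form divides by `v_t + c`
  directly, with no square root and no bias correction, and decomposes as
  `M = diag(eta/(v_t + c))`, `f = g_t`, `C beta = M u m_{t-1}/(1 - u)`;
  the conventional `sqrt(v_t)` variant sits behind `standard = TRUE` for
  comparison only.

## Information geometry and the small-step limits

For a frequency change `q -> q'` the squared Fisher-Rao step
`F = sum(dq^2/q)` equals the variance in relative fitness and the
Shahshahani quadratic form `a' diag(q) a` in the average excess
`a = dq/q`; the Jeffreys divergence equals the Price selection term of the
Malthusian parameter `log(q'/q)`.  In the small-step limit along a zero-sum
direction, `F` is four times the squared Euclidean step in square-root
coordinates and twice the KL divergence.  `limit_ratio_suite()` tabulates
both ratios over a ladder of step scales together with a two-sub-step
finite-difference residual of the continuous force balance (direct
Malthusian force plus inertial log-force change), which vanishes at third
order in the scale; the discrete, exactly assertable counterparts of that
balance are the conserved-likelihood identity and the variational
static-balance check.  A final extrapolated row reports the Richardson
limit from the two smallest scales.  The package evaluates the ratios at
scale `1e-6` on a uniform five-state distribution; far below that scale the
divergences (order `1e-12`) hit the floating-point noise floor, so
convergence is confirmed against a coarser step rather than an even finer
one.

```{r limits}
limit_ratio_suite(rep(0.2, 5), c(1, -1, 0.5, -0.25, -0.25),
                  scales = c(1e-3, 1e-6))
```

## Bayesian updating as selection

With normalized likelihood `L = Ltilde/(q . Ltilde)` playing the role of
fitness, the posterior is a replicator update and the direct gain in mean
likelihood equals `F`.  The ELBO of a candidate `qhat` is
`E_qhat(log Ltilde) - D(qhat || q)`, and its change from the prior splits
into the direct data force `(qhat - q) . log Ltilde` and the context cost
`-D(qhat || q)`; the free-energy change is the negative of that sum.  The
variational family parameter is identified with the candidate distribution
itself — the decompositions need nothing more — and a concrete mean-field
family over factored state spaces is provided so that constrained optima
are exercisable.  `variational_project()` uses coordinate ascent with a
deterministic sweep order and stops when an entire sweep improves the ELBO
by less than `1e-10`; each coordinate update is the exact closed-form
optimum, so the trace is monotone by construction.

## The synthetic generators: what they emulate, what they do not

`generate_population()` draws weights from a symmetric Dirichlet
(concentration 2 — moderately even classes), standard Gaussian traits, and
fitness from a linear map (slope 0.5 per trait, Gaussian noise sd 0.1,
clamped at 0.05 and renormalized), a Boltzmann weighting of a quadratic
performance, or a constant.  Trait updates are absent, a shared constant
shift (pure intrinsic bias), or fitness-correlated shifts (nonzero
`C beta`).  These sizes — tens of classes, a handful of traits — are the
desk scale at which every identity in the package is exact, and the
identities are dimension-free, so passing at this scale is not a weaker
statement about larger populations.  What the generators do *not* emulate
is any real biology or learning benchmark: no linkage or inheritance
structure, no heavy-tailed fitness, no model-misspecified likelihoods.
Tests built on them certify the mathematics of the decomposition, not the
behaviour of any empirical system.

The bit-string learning demonstration uses a length-20 target by default
(an unaided random match has probability `2^-20`, below one in a million),
with ten learning trials per lifetime, per-bit flip probability 0.05, and a
fitness bonus of 19 for a hit; a learning trial is defined as independent
per-bit flips, chosen because it admits the closed-form hit probability
`1 - (1 - p^d (1-p)^(L-d))^G` that serves as the analytic oracle and is
strictly decreasing in the Hamming distance `d` for `p < 1/2`.  Only the
seed string is ever transmitted — learning is nonheritable — so selection
climbs the gradient that learning creates.  The trend test in the suite
runs a shorter string (L = 10) with a stronger flip rate (0.2, 20 trials)
so that the gradient is steep over the standing variation of a
200-individual population within 25 generations; at the default settings
the hit probability at typical initial distances is too small for selection
to act on a desk-scale run, which is precisely the original point of the
demonstration.

## Hierarchical recursion

A two-level population keeps member weights and member fitness normalized
within each group and carries the global scale in the group mean fitnesses
`wbar_g` (`sum(q_g wbar_g) = 1`); flattening multiplies weights and
fitnesses.  This is the only convention under which the recursion is exact:
between-group selection `Cov_g(wbar, thetabar)` plus the group-weighted
within-group terms reproduce the flat Price total identically, the total
metric obeys the law of total covariance `M = M_B + E_g(M_g)`, and the
composite force `M^-1(M_B f_B + E_g(M_g f_g))` equals the flat pooled
regression force whenever `M` is nonsingular.  The between-group bias is
centered as the group-weighted mean of the within-group biases, so the
residuals average exactly to zero.  Two levels are implemented; deeper
recursion is a mechanical extension of the same convention.

## Stochastic contracts and problem sizes

The stochastic claims are tested at fixed seeds and sizes chosen so that a
three-standard-error band is decisive: Langevin noise covariance
`2 eta M` at `1e5` draws; minibatch noise variance proportional to `1/B`
(log-log slope within 0.1 of -1 over batch sizes 5-80 from 4000 data, 2000
resamples each, drawn without replacement — hence the finite-population
correction `(1 - B/N) N/(N-1)` in the exact law, with a with-replacement
mode available); and 2000 evolution-strategy generations of 50 samples on a
linear surface.  The full test suite runs in about a minute on one CPU.

## Known limitations

* Traits are abstract real vectors: no genetic bookkeeping, no sampling
  error for `f` or `M` (population quantities are treated as exact).
* The evolution strategy is deliberately bare — no evolution paths,
  step-size control, or rank-based recombination weights beyond
  fitness-proportional weighting (an exponential ranking transform is the
  one alternative offered).
* Gaussian-process support covers the training-input mean update only; no
  out-of-sample prediction and no kernel hyperparameter learning.
* Continuous-time force balances appear only through their discrete
  counterparts and the small-step residual; policy-level free-energy
  selection is out of scope.
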