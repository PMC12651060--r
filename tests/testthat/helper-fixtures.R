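# Shared fixtures, all generated in code under fixed seeds inside the tests.

# simplex draw strictly inside the interior
rand_simplex <- function(m, alpha = 2) {
  g <- rgamma(m, shape = alpha)
  g / sum(g)
}

# random valid frequency change
rand_change <- function(m) {
  frequency_change(rand_simplex(m), rand_simplex(m))
}

# random discrete Bayes problem
rand_bayes <- function(m) {
  bayes_update(rand_simplex(m), rgamma(m, shape = 2) + 0.1)
}

# concave quadratic surface -1/2 t' A t with known A
quad_surface <- function(A) {
  A <- as.matrix(A)
  performance_surface(
    evaluate = function(t) -0.5 * sum(t * (A %*% t)),
    gradient = function(t) as.numeric(-A %*% t),
    hessian = function(t) -A,
    name = "quad")
}

rand_spd <- function(n, jitter = 0.5) {
  B <- matrix(rnorm(n * n), n, n)
  crossprod(B) / n + diag(jitter, n)
}

# surface with a fixed constant gradient (zero curvature), for stateful steps
const_grad_surface <- function(g) {
  g <- as.numeric(g)
  performance_surface(
    evaluate = function(t) sum(g * t),
    gradient = function(t) g,
    hessian = function(t) matrix(0, length(g), length(g)),
    name = "linear")
}
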