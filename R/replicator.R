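#' Finite-variant population
#'
#' A population of K unique variants: each has a continuous multivariate
#' phenotype (a row of `X`), a fitness value, and a base frequency. A variant
#' stands for all organisms sharing a phenotype, not an individual.
#'
#' @param X numeric K x D matrix of phenotypes (rows are variants).
#' @param f numeric K-vector of fitness values, f\[i\] = fitness of row i.
#' @param p0 numeric K-vector of base frequencies; default uniform. Must be
#'   nonnegative and sum to 1 (tolerance 1e-12; renormalized exactly).
#' @return An object of class `population`.
#' @export
population <- function(X, f, p0 = NULL) {
  X <- as.matrix(X)
  f <- as.numeric(f)
  K <- nrow(X)
  stopifnot(K >= 1, length(f) == K)
  if (anyNA(f) || any(!is.finite(f))) stop("fitness values must be finite")
  if (is.null(p0)) p0 <- rep(1 / K, K)
  stopifnot(length(p0) == K)
  if (any(p0 < 0)) stop("base frequencies must be nonnegative")
  if (abs(sum(p0) - 1) > 1e-12) stop("base frequencies must sum to 1")
  structure(list(X = X, f = f, p0 = p0 / sum(p0), K = K, D = ncol(X)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> K = %d variants, D = %d, fitness in [%g, %g]\n",
              x$K, x$D, min(x$f), max(x$f)))
  invisible(x)
}

# Boltzmann weights from log-weights, via the log-sum-exp shift. The
# normalizer is never formed un-shifted: t grows exponentially during runs.
softmax_weights <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

# Shannon entropy in bits with the 0 log 0 = 0 convention. The single place
# where the log base is fixed.
entropy_bits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Boltzmann selection weights
#'
#' Integrated replicator dynamics: after selection of scale t the frequency of
#' variant i is p_i(t) = p_i(0) exp(t f_i) / Z_t. Larger t concentrates weight
#' on high-fitness variants; at t = 0 the base frequencies are returned.
#' Computed stably by subtracting max(log p_i(0) + t f_i) before
#' exponentiation.
#'
#' @param pop a [population()].
#' @param t nonnegative selection scale (units of inverse fitness).
#' @return An object of class `selection_state`: list with `t`, weights `p`
#'   (normalized), `entropy_bits`, and effective variant count
#'   `K_eff` = 2^entropy_bits.
#' @export
boltzmann_weights <- function(pop, t) {
  stopifnot(inherits(pop, "population"), is.numeric(t), length(t) == 1)
  if (is.na(t) || t < 0) stop("selection scale t must be nonnegative")
  logp0 <- ifelse(pop$p0 > 0, log(pop$p0), -Inf)
  p <- softmax_weights(logp0 + t * pop$f)
  S <- entropy_bits(p)
  structure(list(t = t, p = p, entropy_bits = S, K_eff = 2^S),
            class = "selection_state")
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("<selection_state> t = %g, entropy = %.4f bits, K_eff = %.3f\n",
              x$t, x$entropy_bits, x$K_eff))
  invisible(x)
}

#' Population entropy and effective number of variants
#'
#' Diversity of a frequency vector: Shannon entropy S = -sum p_i log2 p_i (in
#' bits) and the effective number of variants K_eff = 2^S, which lies between
#' 1 (monomorphic) and K (uniform).
#'
#' @param p normalized weight vector (sum within 1e-9 of 1).
#' @return List with `entropy_bits` and `K_eff`.
#' @export
entropy_and_diversity <- function(p) {
  p <- check_weights(p)
  S <- entropy_bits(p)
  list(entropy_bits = S, K_eff = 2^S)
}

check_weights <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("weights must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("weights must sum to 1 (tolerance 1e-9)")
  p / sum(p)
}

#' Weighted population moments
#'
#' The weighted mean and covariance of the phenotypes, and the mean and
#' variance of fitness, under selection weights `p`. These are the natural
#' parameters of the implicit normal approximation to the population.
#'
#' @param pop a [population()].
#' @param p normalized weight vector (e.g. `boltzmann_weights(pop, t)$p`).
#' @return List with `mu` (D-vector), `Sigma` (D x D), `F_mean` (weighted mean
#'   fitness), `varF` (weighted fitness variance).
#' @export
weighted_moments <- function(pop, p) {
  stopifnot(inherits(pop, "population"))
  p <- check_weights(p)
  stopifnot(length(p) == pop$K)
  mu <- as.numeric(crossprod(pop$X, p))
  dev <- sweep(pop$X, 2, mu)
  Sigma <- crossprod(dev, p * dev)
  F_mean <- sum(p * pop$f)
  varF <- sum(p * (pop$f - F_mean)^2)
  list(mu = mu, Sigma = Sigma, F_mean = F_mean, varF = varF)
}

#' Scaled genetic load and scaled fitness variance
#'
#' The genetic load is the gap between the maximum observed fitness and the
#' weighted mean fitness. Fitness has units 1/t, so multiplying by t (load) or
#' t^2 (variance) gives unit-less diagnostics; both vanish as the population
#' concentrates on the best variant and peak at intermediate selection.
#'
#' @param pop a [population()].
#' @param state a `selection_state` computed from `pop`.
#' @return List with `scaled_load` = t (max f - mean f) and
#'   `scaled_varF` = t^2 var f.
#' @export
load_diagnostics <- function(pop, state) {
  stopifnot(inherits(pop, "population"), inherits(state, "selection_state"))
  m <- weighted_moments(pop, state$p)
  list(scaled_load = state$t * (max(pop$f) - m$F_mean),
       scaled_varF = state$t^2 * m$varF)
}

#' Replicator flow
#'
#' Instantaneous change of frequencies under selection,
#' dp_i/dt = p_i (f_i - F) with F the mean fitness; always sums to zero.
#'
#' @param p normalized frequency vector.
#' @param f fitness vector, same length.
#' @return Numeric vector dp/dt.
#' @export
replicator_flow <- function(p, f) {
  p <- check_weights(p)
  stopifnot(length(f) == length(p))
  F_mean <- sum(p * f)
  p * (f - F_mean)
}

#' Natural-gradient identity check
#'
#' Replicator flow is natural-gradient ascent of mean fitness on the simplex:
#' dp/dt = g^{-1} grad_p F, where g is the Fisher information metric of the
#' categorical distribution in the K-1 free coordinates
#' (g_ij = delta_ij / p_i + 1 / p_K). This function builds the metric
#' explicitly, solves for the natural gradient, and returns the maximum
#' absolute deviation from [replicator_flow()] on the free coordinates.
#'
#' @param p frequency vector, all entries strictly positive, K >= 2.
#' @param f fitness vector.
#' @return Scalar: max abs deviation between the two flows.
#' @export
natural_gradient_check <- function(p, f) {
  p <- check_weights(p)
  K <- length(p)
  stopifnot(K >= 2, length(f) == K)
  if (any(p <= 0)) stop("Fisher metric is singular: all frequencies must be positive")
  free <- seq_len(K - 1)
  g <- diag(1 / p[free], K - 1) + 1 / p[K]
  grad <- f[free] - f[K]          # dF/dp_i with p_K = 1 - sum of the rest
  nat <- solve(g, grad)
  max(abs(nat - replicator_flow(p, f)[free]))
}

#' Serialize a weighted population to a data frame
#'
#' One row per variant: phenotype coordinates, fitness, and current weight.
#'
#' @param pop a [population()].
#' @param p optional weight vector (defaults to base frequencies).
#' @return A data.frame with columns x1..xD, fitness, weight.
#' @export
as.data.frame.population <- function(x, row.names = NULL, optional = FALSE,
                                     p = NULL, ...) {
  df <- as.data.frame(x$X)
  names(df) <- paste0("x", seq_len(x$D))
  df$fitness <- x$f
  df$weight <- if (is.null(p)) x$p0 else check_weights(p)
  df
}
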