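#' Recombination configuration
#'
#' Settings for the variant-generating operators.
#'
#' @param mode `"population"` (stochastic sum over the whole population, the
#'   default) or `"pairwise"` (difference of two weighted-sampled parents).
#' @param center_policy `"best_observed"` (center recombinants on the best
#'   variant ever evaluated, the mean at infinite selection) or
#'   `"weighted_mean"` (center on the current weighted mean).
#' @param unbiased logical; if TRUE (default) the population-operator
#'   coefficients are inflated by 1/(1 - sum p_i^2) so the conditional
#'   covariance is unbiased for the implicit normal despite the finite number
#'   of variants.
#' @param coef_form `"sqrt"` (default; coefficients sqrt(p_i), the unique
#'   choice whose conditional covariance equals the weighted population
#'   covariance exactly) or `"linear"` (coefficients p_i, retained for
#'   fidelity experiments).
#' @return An object of class `recombination_config`.
#' @export
recombination_config <- function(mode = c("population", "pairwise"),
                                 center_policy = c("best_observed", "weighted_mean"),
                                 unbiased = TRUE,
                                 coef_form = c("sqrt", "linear")) {
  structure(list(mode = match.arg(mode),
                 center_policy = match.arg(center_policy),
                 unbiased = isTRUE(unbiased),
                 coef_form = match.arg(coef_form)),
            class = "recombination_config")
}

#' Pairwise covariance-preserving recombination
#'
#' Samples two distinct parents by weighted sampling with the selection
#' weights and returns center + (x1 - x2)/sqrt(2). With sampling *with*
#' replacement this recombinant has mean `center` and covariance equal to the
#' weighted population covariance; the distinct-parent constraint introduces
#' an O(sum p^2) covariance bias, accepted for the sake of producing a new
#' variant.
#'
#' @param pop a [population()].
#' @param state a `selection_state` for `pop`.
#' @param center D-vector about which the recombinant is centered.
#' @param replace logical; sample parents with replacement (used by the
#'   statistical oracle; default FALSE, distinct parents).
#' @return Numeric D-vector, the recombinant phenotype.
#' @export
recombine_pair <- function(pop, state, center, replace = FALSE) {
  stopifnot(inherits(pop, "population"), inherits(state, "selection_state"),
            length(center) == pop$D)
  if (sum(state$p > 0) < 2)
    stop("degenerate population: need at least two variants with positive weight")
  idx <- sample.int(pop$K, 2, replace = replace, prob = state$p)
  center + (pop$X[idx[1], ] - pop$X[idx[2], ]) / sqrt(2)
}

#' Recombination coefficients for the population operator
#'
#' The stochastic-sum operator draws one standard normal per variant and
#' combines deviations from the weighted mean with coefficients c_i. With
#' c_i = sqrt(p_i) (default) the conditional covariance of the recombinant is
#' exactly the weighted population covariance Sigma_t. Because a finite
#' population's sample covariance about its own mean underestimates the
#' implicit normal's covariance by the factor (1 - sum p_i^2), the unbiased
#' mode divides the radicand by that factor.
#'
#' @param p normalized weight vector.
#' @param unbiased logical, apply the finite-population correction.
#' @param coef_form `"sqrt"` or `"linear"` (see [recombination_config()]).
#' @return Numeric coefficient vector c.
#' @export
recombination_coefficients <- function(p, unbiased = TRUE,
                                       coef_form = c("sqrt", "linear")) {
  p <- check_weights(p)
  coef_form <- match.arg(coef_form)
  base <- if (coef_form == "sqrt") sqrt(p) else p
  if (!unbiased) return(base)
  p2 <- sum(p^2)
  if (p2 >= 1 - 1e-12)
    stop("degenerate population: a single effective variant (sum p^2 ~ 1)")
  base / sqrt(1 - p2)
}

#' Whole-population covariance-preserving recombination
#'
#' Generates one new phenotype as a stochastic sum over the entire population,
#' x' = center + sum_i eta_i c_i (x_i - mu_t), with eta_i independent standard
#' normals, c_i from [recombination_coefficients()], and mu_t the *weighted
#' mean* — deviations are always taken about mu_t even when the recombinant is
#' centered on the best observed variant. Conditional on the parents the
#' recombinant is normal with mean `center` and covariance
#' sum_i c_i^2 (x_i - mu_t)(x_i - mu_t)'; with biased sqrt coefficients that
#' is exactly the weighted population covariance, so recombination samples the
#' implicit normal without ever estimating a covariance matrix.
#'
#' @param pop a [population()].
#' @param state a `selection_state` for `pop`.
#' @param cfg a [recombination_config()].
#' @param center D-vector about which the recombinant is centered.
#' @param eta optional K-vector of normal variates (for deterministic checks);
#'   drawn internally when NULL.
#' @return Numeric D-vector, the recombinant phenotype.
#' @export
recombine_population <- function(pop, state, cfg = recombination_config(),
                                 center, eta = NULL) {
  stopifnot(inherits(pop, "population"), inherits(state, "selection_state"),
            inherits(cfg, "recombination_config"),
            length(state$p) == pop$K, length(center) == pop$D)
  if (pop$K < 2) stop("degenerate population: need K >= 2")
  cc <- recombination_coefficients(state$p, unbiased = cfg$unbiased,
                                   coef_form = cfg$coef_form)
  mu_t <- as.numeric(crossprod(pop$X, state$p))
  if (is.null(eta)) eta <- stats::rnorm(pop$K)
  stopifnot(length(eta) == pop$K)
  dev <- sweep(pop$X, 2, mu_t)
  as.numeric(center + crossprod(dev, eta * cc))
}

# conditional covariance of recombine_population given the parents
recombinant_covariance <- function(pop, state, cfg = recombination_config()) {
  cc <- recombination_coefficients(state$p, unbiased = cfg$unbiased,
                                   coef_form = cfg$coef_form)
  mu_t <- as.numeric(crossprod(pop$X, state$p))
  dev <- sweep(pop$X, 2, mu_t)
  crossprod(dev, cc^2 * dev)
}
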