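#' Gaussian population
#'
#' Parameterizes an (infinite) normally distributed population of phenotypes
#' by its mean vector and covariance matrix, the setting of classical
#' multivariate quantitative genetics. Used by the closed-form selection
#' theory; the optimizer itself never stores a covariance matrix.
#'
#' @param mu numeric D-vector, population mean.
#' @param Sigma D x D symmetric positive-definite covariance matrix.
#' @return An object of class `gaussian_population`.
#' @export
gaussian_population <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  D <- length(mu)
  stopifnot(nrow(Sigma) == D, ncol(Sigma) == D)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("Sigma must be symmetric")
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("Sigma must be positive-definite")
  structure(list(mu = mu, Sigma = Sigma, D = D, chol = ch),
            class = "gaussian_population")
}

#' @export
print.gaussian_population <- function(x, ...) {
  cat(sprintf("<gaussian_population> D = %d, mean = (%s)\n", x$D,
              paste(signif(x$mu, 4), collapse = ", ")))
  invisible(x)
}

# gradient/curvature of the fitness at a point, from the landscape
landscape_local <- function(land, x) {
  if (is.null(land$gradient) || is.null(land$curvature))
    stop("landscape must provide analytic gradient and curvature")
  list(grad = as.numeric(land$gradient(x)), C = as.matrix(land$curvature(x)))
}

#' Closed-form selection dynamics of a Gaussian population
#'
#' On a quadratic fitness landscape, phenotypes stay normally distributed
#' under replicator dynamics, and a selection interval of scale t maps
#' (mu0, Sigma0) to
#' \deqn{\Sigma_t = (\Sigma_0^{-1} + t C)^{-1}, \quad
#'       \mu_t = \mu_0 + (\Sigma_0^{-1}/t + C)^{-1} \nabla f,}
#' with the fitness gradient and curvature evaluated at mu0. The mean shift is
#' a finite natural-gradient step; the precision accumulates curvature. For
#' non-quadratic landscapes this is a local approximation: gradient and
#' curvature are frozen at mu0 for the whole call. All solves use Cholesky
#' factorizations; no explicit inverse is formed.
#'
#' @param g0 a [gaussian_population()].
#' @param land a quadratic `fitness_landscape` (analytic gradient/curvature).
#' @param t nonnegative selection scale.
#' @return The propagated `gaussian_population`.
#' @export
propagate <- function(g0, land, t) {
  stopifnot(inherits(g0, "gaussian_population"),
            inherits(land, "fitness_landscape"),
            is.numeric(t), length(t) == 1, t >= 0)
  if (t == 0) return(g0)
  loc <- landscape_local(land, g0$mu)
  prec0 <- chol2inv(g0$chol)                 # Sigma0^{-1}
  A <- prec0 + t * loc$C                     # Sigma_t^{-1}
  chA <- tryCatch(chol(A), error = function(e)
    stop("Sigma0^{-1} + t C is not positive-definite: invalid landscape/time combination"))
  Sigma_t <- chol2inv(chA)
  Sigma_t <- (Sigma_t + t(Sigma_t)) / 2
  # mu_t - mu_0 = (Sigma0^{-1}/t + C)^{-1} grad f = t * A^{-1} grad f
  shift <- t * backsolve(chA, forwardsolve(t(chA), loc$grad))
  gaussian_population(g0$mu + shift, Sigma_t)
}

#' Newton-step limit of selection
#'
#' As the selection scale grows, the mean shift of [propagate()] tends to
#' C^{-1} grad f, one iteration of Newton's method; on a quadratic landscape
#' the landing point mu0 + C^{-1} grad f is the optimum itself.
#'
#' @param g0 a [gaussian_population()] (supplies the expansion point mu0).
#' @param land a quadratic `fitness_landscape` with positive-definite
#'   curvature.
#' @return D-vector, the asymptotic mean shift.
#' @export
newton_limit <- function(g0, land) {
  stopifnot(inherits(g0, "gaussian_population"))
  loc <- landscape_local(land, g0$mu)
  ch <- tryCatch(chol(loc$C), error = function(e)
    stop("curvature C must be positive-definite for the Newton limit"))
  backsolve(ch, forwardsolve(t(ch), loc$grad))
}

#' Genetic load of a Gaussian population on a quadratic landscape
#'
#' The gap between the maximum fitness f* and the expected fitness of the
#' population, F* - F = (1/2) \[ (mu - x*)' C (mu - x*) + tr(C Sigma) \].
#' When the population sits at the optimum with covariance C^{-1}/t the load
#' is D/(2t): the continuous-limit asymptote of the scaled load t(F* - F) is
#' D/2.
#'
#' @param g a [gaussian_population()].
#' @param land a quadratic `fitness_landscape` with known optimum.
#' @return Scalar load F* - F (nonnegative on PSD quadratics).
#' @export
continuous_load <- function(g, land) {
  stopifnot(inherits(g, "gaussian_population"),
            inherits(land, "fitness_landscape"))
  if (is.null(land$optimum)) stop("landscape must have a known optimum")
  loc <- landscape_local(land, g$mu)
  d <- g$mu - land$optimum$x
  0.5 * (sum(d * (loc$C %*% d)) + sum(loc$C * g$Sigma))
}

#' Expected fitness cost of random mutation
#'
#' For a zero-mean Gaussian phenotype perturbation with covariance M applied
#' on a quadratic landscape, the expected fitness change is -tr(C M)/2:
#' proportional to the number of directions in which the perturbation is
#' deleterious, weighted by their curvature. This is why undirected mutation
#' is an inefficient variant generator on high-dimensional ridges.
#'
#' @param land a quadratic `fitness_landscape`.
#' @param M D x D symmetric positive semi-definite mutation covariance.
#' @return Scalar expected fitness change (<= 0 on PSD quadratics).
#' @export
expected_mutation_cost <- function(land, M) {
  stopifnot(inherits(land, "fitness_landscape"))
  M <- as.matrix(M)
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("mutation covariance M must be symmetric")
  C <- as.matrix(land$curvature(if (is.null(land$optimum)) rep(0, land$dim)
                                else land$optimum$x))
  -0.5 * sum(C * M)
}
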