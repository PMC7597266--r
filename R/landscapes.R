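#' Fitness landscapes
#'
#' A fitness landscape maps a D-dimensional phenotype (candidate solution) to
#' a scalar fitness. The optimizer always *maximizes* fitness; benchmark
#' objectives are *minimized*, so every built-in landscape applies the sign
#' convention fitness = -objective in exactly one place, at construction.
#' All reporting (traces, summaries, convergence checks) is on the objective
#' scale.
#'
#' @param objective function of a numeric D-vector returning the scalar
#'   objective value (to be minimized).
#' @param dim positive integer, phenotype dimension D.
#' @param gradient optional function returning the D-vector gradient of the
#'   *fitness* (i.e. minus the objective gradient).
#' @param curvature optional function returning the D x D fitness curvature
#'   matrix C, the negative of the fitness Hessian (equivalently the objective
#'   Hessian).
#' @param optimum optional list with elements `x` (a D-vector attaining the
#'   optimum) and `objective` (its objective value).
#' @param name short identifier used in logs and the registry.
#' @param init optional list with `mean` and `sd` giving a sensible default
#'   initial sampling distribution for this landscape.
#'
#' @return An object of class `fitness_landscape`: a list with elements
#'   `dim`, `fitness`, `objective`, `gradient`, `curvature`, `optimum`,
#'   `name`, `init`.
#' @export
as_landscape <- function(objective, dim, gradient = NULL, curvature = NULL,
                         optimum = NULL, name = "custom", init = NULL) {
  stopifnot(is.function(objective), dim >= 1, dim == round(dim))
  if (!is.null(optimum)) {
    stopifnot(is.list(optimum), length(optimum$x) == dim,
              is.numeric(optimum$objective))
    optimum$fitness <- -optimum$objective
  }
  structure(list(
    dim       = as.integer(dim),
    objective = objective,
    fitness   = function(x) -objective(x),
    gradient  = gradient,
    curvature = curvature,
    optimum   = optimum,
    name      = name,
    init      = init
  ), class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("<fitness_landscape '%s'> D = %d", x$name, x$dim))
  if (!is.null(x$optimum))
    cat(sprintf(", known optimum objective = %g", x$optimum$objective))
  cat("\n")
  invisible(x)
}

#' Quadratic fitness landscape
#'
#' Constructs the landscape f(x) = f* - (1/2) (x - x*)' C (x - x*), the
#' canonical local model of selection theory: fitness is maximal at `x_star`
#' with curvature matrix `C` (negative fitness Hessian).
#'
#' @param x_star D-vector, location of the fitness maximum.
#' @param C D x D symmetric positive semi-definite curvature matrix.
#' @param f_star scalar fitness at the maximum (default 0).
#' @param name identifier.
#' @return A `fitness_landscape` with exact gradient and curvature.
#' @export
make_quadratic <- function(x_star, C, f_star = 0, name = "quadratic") {
  x_star <- as.numeric(x_star)
  C <- as.matrix(C)
  D <- length(x_star)
  stopifnot(nrow(C) == D, ncol(C) == D)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("curvature matrix C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("curvature matrix C must be positive semi-definite")
  as_landscape(
    objective = function(x) {
      d <- x - x_star
      0.5 * sum(d * (C %*% d)) - f_star
    },
    dim       = D,
    gradient  = function(x) as.numeric(-C %*% (x - x_star)),
    curvature = function(x) C,
    optimum   = list(x = x_star, objective = -f_star),
    name      = name
  )
}

#' Rank-one test ellipsoid, D = 5
#'
#' Objective (x1 + 2 x2 + 3 x3 + 4 x4 + 5 x5)^2, minimized (value 0) on the
#' whole hyperplane sum(i * x_i) = 0. The quadratic form is rank one, so the
#' optimum is degenerate; see [random_quadratic_instance()] for full-rank
#' quadratic test surfaces. Default initialization: mean and variance all one,
#' so the population does not start centered on the optimum.
#'
#' @return A `fitness_landscape`.
#' @export
test_ellipsoid <- function() {
  w <- as.numeric(1:5)
  C <- 2 * tcrossprod(w)
  as_landscape(
    objective = function(x) sum(w * x)^2,
    dim       = 5L,
    gradient  = function(x) -2 * sum(w * x) * w,
    curvature = function(x) C,
    optimum   = list(x = rep(0, 5), objective = 0),
    name      = "ellipsoid5",
    init      = list(mean = rep(1, 5), sd = rep(1, 5))
  )
}

#' Two-dimensional Rosenbrock landscape
#'
#' Objective (1 - x1)^2 + 100 (x2 - x1^2)^2, the classic banana-valley
#' benchmark, minimized at (1, 1) with value 0. Default initialization:
#' mean (0, 1), standard deviation (0.25, 0.25).
#'
#' @return A `fitness_landscape`.
#' @export
rosenbrock2d <- function() {
  as_landscape(
    objective = function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2,
    dim       = 2L,
    gradient  = function(x) {
      # gradient of fitness = -(objective gradient)
      g1 <- -2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2)
      g2 <- 200 * (x[2] - x[1]^2)
      -c(g1, g2)
    },
    curvature = function(x) {
      # objective Hessian = fitness curvature
      h11 <- 2 - 400 * (x[2] - 3 * x[1]^2)
      h12 <- -400 * x[1]
      matrix(c(h11, h12, h12, 200), 2, 2)
    },
    optimum   = list(x = c(1, 1), objective = 0),
    name      = "rosenbrock2",
    init      = list(mean = c(0, 1), sd = c(0.25, 0.25))
  )
}

#' Random full-rank quadratic instance
#'
#' A reproducible randomized quadratic landscape: eigenvalues of the curvature
#' log-spaced from 1 to `condition_spread`, a random rotation, and an optimum
#' drawn uniformly from the box \[-4, 4\]^D with optimal objective 0. Used for
#' convergence benchmarking where an ensemble of instances with randomized
#' optima is wanted. Default initialization: mean 0, standard deviation 3 in
#' every dimension.
#'
#' @param D dimension (>= 1).
#' @param condition_spread ratio of largest to smallest curvature eigenvalue
#'   (default 100).
#' @param seed integer seed; the same seed always yields the same instance.
#' @return A `fitness_landscape`.
#' @export
random_quadratic_instance <- function(D, condition_spread = 100, seed = 1L) {
  stopifnot(D >= 1, condition_spread >= 1)
  dat <- with_preserved_seed(seed, {
    lambda <- exp(seq(0, log(condition_spread), length.out = D))
    Q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
    list(C = Q %*% (lambda * t(Q)), x_star = stats::runif(D, -4, 4))
  })
  C <- (dat$C + t(dat$C)) / 2  # symmetrize rounding error
  land <- make_quadratic(dat$x_star, C, f_star = 0,
                         name = sprintf("quad:D=%d,seed=%d", D, seed))
  land$init <- list(mean = rep(0, D), sd = rep(3, D))
  land
}

#' Resolve a landscape by name
#'
#' Registry used by the command line and benchmark harness. Recognized names:
#' `"ellipsoid5"`, `"rosenbrock2"`, and `"quad:D=<d>,seed=<k>"` (optionally
#' `,cond=<c>` for the condition spread).
#'
#' @param name character landscape identifier.
#' @return A `fitness_landscape`.
#' @export
get_landscape <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  if (name == "ellipsoid5") return(test_ellipsoid())
  if (name == "rosenbrock2") return(rosenbrock2d())
  if (startsWith(name, "quad:")) {
    spec <- strsplit(sub("^quad:", "", name), ",", fixed = TRUE)[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- as.numeric(vapply(kv, `[`, "", 2))
    names(vals) <- keys
    if (!all(c("D", "seed") %in% keys) || anyNA(vals))
      stop("quad landscape spec must look like 'quad:D=5,seed=3[,cond=100]'")
    cond <- if ("cond" %in% keys) vals[["cond"]] else 100
    return(random_quadratic_instance(as.integer(vals[["D"]]),
                                     condition_spread = cond,
                                     seed = as.integer(vals[["seed"]])))
  }
  stop("unknown landscape: ", name)
}

#' Count objective evaluations
#'
#' Wraps a landscape so that every call to its `fitness`/`objective` functions
#' increments a counter, making evaluation budgets enforceable.
#'
#' @param land a `fitness_landscape`.
#' @return A `fitness_landscape` (subclass `counted_landscape`) sharing all
#'   fields, whose evaluation count is read with [n_evaluations()].
#' @export
counted_landscape <- function(land) {
  stopifnot(inherits(land, "fitness_landscape"))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  obj <- land$objective
  wrapped <- land
  wrapped$objective <- function(x) {
    counter$n <- counter$n + 1L
    obj(x)
  }
  wrapped$fitness <- function(x) -wrapped$objective(x)
  wrapped$counter <- counter
  class(wrapped) <- c("counted_landscape", "fitness_landscape")
  wrapped
}

#' @rdname counted_landscape
#' @export
n_evaluations <- function(land) {
  stopifnot(inherits(land, "counted_landscape"))
  land$counter$n
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
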