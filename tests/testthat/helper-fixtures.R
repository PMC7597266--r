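# Fixture builders shared across test files. All randomness is seeded at the
# call site through with_seed().

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# random finite-variant population: K phenotypes in D dimensions with fitness
# from a random full-rank quadratic (or standard normal fitness if quad=FALSE)
random_population <- function(K, D, seed, quad = TRUE) {
  with_seed(seed, {
    X <- matrix(rnorm(K * D), K, D)
    f <- if (quad) {
      A <- crossprod(matrix(rnorm(D * D), D, D)) + diag(D)
      -0.5 * rowSums((X %*% A) * X)
    } else rnorm(K)
    population(X, f)
  })
}

# random normalized weight vector
random_weights <- function(K, seed) {
  with_seed(seed, {
    w <- rexp(K)
    w / sum(w)
  })
}

# entropy in bits computed directly (independent of package internals)
entropy_bits_direct <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}
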