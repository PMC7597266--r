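#' Moran birth-death extinction simulation
#'
#' Simulates the fate of mutants in a haploid Moran model of constant size N:
#' at each event one individual reproduces (chosen proportionally to fitness)
#' and one dies (uniformly). A single mutant with a small selective advantage
#' is still overwhelmingly likely to be lost to drift — with relative fitness
#' 1.01 and N = 1000 about 99% of lineages go extinct — which is why
#' stochastic fitness-proportionate selection is so wasteful as an
#' optimization operator.
#'
#' Implementation: only events that change the mutant count matter for
#' absorption, and conditional on a change the count increases with
#' probability r/(1+r) regardless of its current value. The simulation
#' therefore runs the embedded birth-death jump chain, retiring each replicate
#' the moment it is absorbed at 0 (extinction) or N (fixation).
#'
#' @param N population size.
#' @param fitness_ratio relative fitness r of the mutant (r > 0).
#' @param replicates number of independent lineages to simulate.
#' @param initial initial number of mutants (default 1).
#' @param seed optional RNG seed.
#' @return List with `extinct_fraction`, `fixed_fraction`, `replicates`.
#' @seealso [moran_extinction_prob()] for the closed-form probability.
#' @export
moran_extinction <- function(N = 1000, fitness_ratio = 1.01, replicates = 1e5,
                             initial = 1, seed = NULL) {
  stopifnot(N >= 2, fitness_ratio > 0, replicates >= 1,
            initial >= 1, initial < N)
  if (!is.null(seed)) set.seed(seed)
  q_up <- fitness_ratio / (1 + fitness_ratio)
  replicates <- as.integer(replicates)
  extinct <- logical(replicates)
  active <- seq_len(replicates)
  j <- rep(as.integer(initial), replicates)
  while (length(active)) {
    n <- length(active)
    j <- j + 2L * (stats::runif(n) < q_up) - 1L
    dead <- j == 0L
    fixed <- j == N
    fin <- dead | fixed
    if (any(fin)) {
      extinct[active[dead]] <- TRUE
      keep <- !fin
      active <- active[keep]
      j <- j[keep]
    }
  }
  list(extinct_fraction = mean(extinct),
       fixed_fraction = 1 - mean(extinct),
       replicates = replicates)
}

#' Closed-form Moran extinction probability
#'
#' Gambler's-ruin solution of the Moran birth-death chain: starting from `i`
#' mutants of relative fitness r in a population of N, the extinction
#' probability is (r^{-i} - r^{-N}) / (1 - r^{-N}) for r != 1 and 1 - i/N for
#' the neutral case.
#'
#' @inheritParams moran_extinction
#' @param initial initial number of mutants.
#' @return Scalar extinction probability.
#' @export
moran_extinction_prob <- function(N = 1000, fitness_ratio = 1.01, initial = 1) {
  stopifnot(N >= 2, fitness_ratio > 0, initial >= 0, initial <= N)
  if (fitness_ratio == 1) return(1 - initial / N)
  s <- 1 / fitness_ratio
  (s^initial - s^N) / (1 - s^N)
}
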