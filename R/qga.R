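#' Quantitative genetic algorithm (QGA)
#'
#' Derivative-free optimization by deterministic natural selection. A fixed
#' population of `K0 = round(2^(S+1))` phenotypes carries Boltzmann selection
#' weights `p_i(t)` proportional to `exp(t f_i)`. Each iteration (i) solves for
#' the selection scale t at which the population entropy equals the target `S`
#' bits, so diversity is held constant and selection strengthens on its own as
#' better variants are found; (ii) generates a single recombinant by a
#' covariance-preserving stochastic sum over the whole population, centered by
#' default on the best variant observed so far; (iii) evaluates its objective
#' and replaces the variant with the smallest weight. No covariance matrix is
#' stored and no linear algebra beyond vector sums is performed.
#'
#' The run stops when the best objective is within `fitness_tolerance` of a
#' known optimum (`converged`), the evaluation budget is exhausted
#' (`budget_exhausted`), two distinct phenotypes carry bit-identical fitness —
#' a symptom of numerical exhaustion under diverging selection
#' (`duplicate_fitness`) — or the entropy target becomes unreachable
#' (`degenerate_population`).
#'
#' @param landscape a `fitness_landscape` (see [get_landscape()],
#'   [make_quadratic()], [as_landscape()]).
#' @param target_entropy target population entropy S in bits (> 0). The only
#'   substantive hyper-parameter: small S converges fast but risks premature
#'   convergence; large S costs more evaluations.
#' @param init_mean,init_sd D-vectors (or scalars, recycled): mean and
#'   standard deviation of the diagonal normal from which the initial
#'   population is drawn. Defaults come from the landscape's `init` hint.
#' @param max_evaluations total objective-evaluation budget (>= K0).
#' @param fitness_tolerance convergence gap to the known optimum objective;
#'   ignored when the landscape has no known optimum.
#' @param seed integer seed making the entire run reproducible; NULL leaves
#'   the RNG stream alone.
#' @param recombination a [recombination_config()].
#' @param entropy_match_tol tolerance (bits) for the entropy solver.
#' @return An object of class `qga`: list with `best` (phenotype), `best_objective`,
#'   `best_fitness`, `evaluations`, `termination`, `trace` (data frame with
#'   one row per iteration: `evals`, `t`, `best_objective`, `entropy_bits`,
#'   `K_eff`, `mean_fitness`), `K0`, `target_entropy`, `landscape`,
#'   `config`, `seed`.
#' @seealso [solve_selection_scale()], [recombine_population()],
#'   [qga_benchmark()]
#' @examples
#' fit <- qga(rosenbrock2d(), target_entropy = 4, max_evaluations = 20000,
#'            seed = 1)
#' fit
#' coef(fit)
#' @export
qga <- function(landscape,
                target_entropy = 4,
                init_mean = NULL,
                init_sd = NULL,
                max_evaluations = 5e4,
                fitness_tolerance = 1e-8,
                seed = NULL,
                recombination = recombination_config(),
                entropy_match_tol = 1e-6) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(recombination, "recombination_config"))
  S <- target_entropy
  if (!is.numeric(S) || length(S) != 1 || S <= 0)
    stop("target_entropy S must be a positive scalar (bits)")
  K0 <- as.integer(round(2^(S + 1)))
  if (max_evaluations < K0)
    stop(sprintf("max_evaluations (%d) must be at least K0 = %d", max_evaluations, K0))
  D <- landscape$dim
  if (is.null(init_mean)) init_mean <- landscape$init$mean
  if (is.null(init_sd)) init_sd <- landscape$init$sd
  if (is.null(init_mean) || is.null(init_sd))
    stop("init_mean and init_sd are required (landscape has no defaults)")
  init_mean <- rep_len(as.numeric(init_mean), D)
  init_sd <- rep_len(as.numeric(init_sd), D)
  if (any(init_sd <= 0)) stop("init_sd must be positive")
  if (!is.null(seed)) set.seed(seed)

  cland <- counted_landscape(landscape)
  has_opt <- !is.null(landscape$optimum)
  opt_obj <- if (has_opt) landscape$optimum$objective else NA_real_

  # -- initialization: K0 draws from the diagonal normal, uniform weights
  X <- matrix(stats::rnorm(K0 * D, mean = rep(init_mean, each = K0),
                           sd = rep(init_sd, each = K0)), K0, D)
  f <- apply(X, 1, cland$fitness)
  if (any(!is.finite(f))) stop("non-finite fitness at initialization")

  ib <- which.max(f)
  best_x <- X[ib, ]
  best_f <- f[ib]

  n_rows <- max_evaluations - K0 + 1L
  trace <- matrix(NA_real_, n_rows, 6)
  colnames(trace) <- c("evals", "t", "best_objective", "entropy_bits",
                       "K_eff", "mean_fitness")
  trace[1, ] <- c(K0, 0, -best_f, log2(K0), K0, mean(f))
  row <- 1L

  termination <- NULL
  if (has_opt && -best_f - opt_obj <= fitness_tolerance) termination <- "converged"
  else if (has_duplicate_fitness(X, f)) termination <- "duplicate_fitness"
  else if (n_evaluations(cland) >= max_evaluations) termination <- "budget_exhausted"

  t_prev <- 1
  use_best_center <- recombination$center_policy == "best_observed"

  while (is.null(termination)) {
    sol <- solve_t_for_entropy(f, S, tol = entropy_match_tol, t_init = t_prev)
    if (sol$flag %in% c("ceiling", "below_target", "flat")) {
      termination <- "degenerate_population"
      break
    }
    t_prev <- sol$t
    p <- sol$p

    cc <- recombination_coefficients(p, unbiased = recombination$unbiased,
                                     coef_form = recombination$coef_form)
    mu_t <- as.numeric(crossprod(X, p))
    center <- if (use_best_center) best_x else mu_t
    eta <- stats::rnorm(K0)
    x_new <- center + as.numeric(crossprod(X, eta * cc)) - sum(eta * cc) * mu_t
    f_new <- cland$fitness(x_new)
    if (!is.finite(f_new)) stop("non-finite fitness during optimization")

    if (f_new > best_f) {
      best_f <- f_new
      best_x <- x_new
    }
    j <- which.min(p)            # lowest index among ties
    X[j, ] <- x_new
    f[j] <- f_new

    row <- row + 1L
    evals <- n_evaluations(cland)
    trace[row, ] <- c(evals, sol$t, -best_f, sol$entropy_bits, 2^sol$entropy_bits,
                      sum(p * f))

    if (has_opt && -best_f - opt_obj <= fitness_tolerance) termination <- "converged"
    else if (evals >= max_evaluations) termination <- "budget_exhausted"
    else if (has_duplicate_fitness(X, f)) termination <- "duplicate_fitness"
  }

  structure(list(
    best = best_x,
    best_objective = -best_f,
    best_fitness = best_f,
    evaluations = n_evaluations(cland),
    termination = termination,
    trace = as.data.frame(trace[seq_len(row), , drop = FALSE]),
    K0 = K0,
    target_entropy = S,
    landscape = landscape$name,
    optimum_objective = opt_obj,
    config = list(target_entropy = S, init_mean = init_mean, init_sd = init_sd,
                  max_evaluations = max_evaluations,
                  fitness_tolerance = fitness_tolerance,
                  recombination = unclass(recombination), seed = seed),
    seed = seed
  ), class = "qga")
}

# TRUE when two variants with differing phenotypes share a bit-identical
# fitness value (numerical-exhaustion check).
has_duplicate_fitness <- function(X, f) {
  if (!anyDuplicated(f)) return(FALSE)
  for (v in unique(f[duplicated(f)])) {
    idx <- which(f == v)
    sub <- X[idx, , drop = FALSE]
    first <- sub[rep(1L, nrow(sub)), , drop = FALSE]
    if (any(sub != first)) return(TRUE)
  }
  FALSE
}

# Entropy-targeted selection-scale solver on raw fitness values with uniform
# base frequencies. Entropy(t) is monotone non-increasing (dS/dt = -t varF),
# so a geometric bracketing scan followed by bisection finds the unique t with
# entropy = S_target. Warm-started from t_init.
solve_t_for_entropy <- function(f, S_target, tol = 1e-6, t_init = 1,
                                t_max = 1e30) {
  K <- length(f)
  if (max(f) == min(f)) {
    p <- rep(1 / K, K)
    return(list(t = 0, p = p, entropy_bits = log2(K), flag = "flat"))
  }
  ent <- function(t) {
    p <- softmax_weights(t * f)
    list(p = p, S = entropy_bits(p))
  }
  e0 <- log2(K)
  if (e0 < S_target - tol)
    return(list(t = 0, p = rep(1 / K, K), entropy_bits = e0,
                flag = "below_target"))
  if (e0 <= S_target + tol)
    return(list(t = 0, p = rep(1 / K, K), entropy_bits = e0, flag = "ok"))

  # geometric bracketing: find lo (entropy > S) < hi (entropy <= S)
  t1 <- max(t_init, 1e-12)
  a <- ent(t1)
  if (a$S > S_target) {
    lo <- t1
    hi <- t1 * 4
    repeat {
      b <- ent(hi)
      if (b$S <= S_target) break
      lo <- hi
      hi <- hi * 4
      if (hi > t_max)
        return(list(t = hi, p = b$p, entropy_bits = b$S, flag = "ceiling"))
    }
  } else {
    hi <- t1
    lo <- t1 / 4
    repeat {
      b <- ent(lo)
      if (b$S > S_target) break
      hi <- lo
      lo <- lo / 4
      if (lo < 1e-300) { lo <- 0; break }
    }
  }

  mid <- hi
  res <- ent(mid)
  for (i in 1:300) {
    mid <- if (lo > 0) sqrt(lo * hi) else (lo + hi) / 2
    res <- ent(mid)
    if (abs(res$S - S_target) <= tol) break
    if (res$S > S_target) lo <- mid else hi <- mid
  }
  list(t = mid, p = res$p, entropy_bits = res$S, flag = "ok")
}

#' Solve for the selection scale matching a target entropy
#'
#' Finds t >= 0 such that the entropy of the Boltzmann weights equals
#' `S_target_bits`, by geometric bracketing plus bisection on the monotone
#' entropy-versus-t map. Requires uniform base frequencies (which is what the
#' optimizer maintains); with non-uniform p0 the map need not be monotone.
#'
#' Conventions: if all fitness values are equal, or the entropy at t = 0
#' already equals (or falls below) the target, t = 0 is returned; the `flag`
#' attribute records which case occurred (`"ok"`, `"flat"`, `"below_target"`,
#' or `"ceiling"` when the entropy floor of a near-degenerate population sits
#' above the target).
#'
#' @param pop a [population()] with uniform base frequencies.
#' @param S_target_bits target entropy in bits, < log2(K).
#' @param tol entropy-matching tolerance in bits (default 1e-6).
#' @return A `selection_state` with an additional attribute `"flag"`.
#' @export
solve_selection_scale <- function(pop, S_target_bits, tol = 1e-6) {
  stopifnot(inherits(pop, "population"))
  if (max(abs(pop$p0 - 1 / pop$K)) > 1e-9)
    stop("solve_selection_scale requires uniform base frequencies")
  sol <- solve_t_for_entropy(pop$f, S_target_bits, tol = tol)
  state <- boltzmann_weights(pop, sol$t)
  attr(state, "flag") <- sol$flag
  state
}

#' @export
print.qga <- function(x, ...) {
  cat(sprintf("Quantitative genetic algorithm run on '%s'\n", x$landscape))
  cat(sprintf("  target entropy S = %g bits (K0 = %d variants)\n",
              x$target_entropy, x$K0))
  cat(sprintf("  termination: %s after %d evaluations\n",
              x$termination, x$evaluations))
  cat(sprintf("  best objective: %.10g\n", x$best_objective))
  if (!is.na(x$optimum_objective))
    cat(sprintf("  gap to known optimum: %.3e\n",
                x$best_objective - x$optimum_objective))
  invisible(x)
}

#' @export
summary.qga <- function(object, ...) {
  structure(list(fit = object), class = "summary.qga")
}

#' @export
print.summary.qga <- function(x, ...) {
  fit <- x$fit
  print(fit)
  tr <- fit$trace
  cat(sprintf("  final selection scale t = %.4g, entropy = %.4f bits\n",
              tr$t[nrow(tr)], tr$entropy_bits[nrow(tr)]))
  cat(sprintf("  iterations recorded: %d\n", nrow(tr)))
  cat("  best phenotype:\n")
  print(signif(fit$best, 6))
  invisible(x)
}

#' @export
coef.qga <- function(object, ...) object$best

#' Trace plot for a QGA run
#'
#' Two panels on the objective scale: the gap of the best objective to the
#' known optimum (or the best objective itself if the optimum is unknown), and
#' the selection scale t, both against evaluations and on log axes. On
#' landscapes where the run converges, the gap shrinks and t grows roughly
#' exponentially with evaluations.
#'
#' @param x a `qga` fit.
#' @param ... passed to [plot()].
#' @export
plot.qga <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  gap <- if (!is.na(x$optimum_objective))
    pmax(tr$best_objective - x$optimum_objective, .Machine$double.xmin)
  else tr$best_objective
  ylab <- if (!is.na(x$optimum_objective)) "objective gap" else "best objective"
  graphics::plot(tr$evals, gap, type = "l", log = "y",
                 xlab = "evaluations", ylab = ylab, ...)
  pos <- tr$t > 0
  graphics::plot(tr$evals[pos], tr$t[pos], type = "l", log = "y",
                 xlab = "evaluations", ylab = "selection scale t", ...)
  invisible(x)
}

#' Write a QGA run record to disk
#'
#' Writes the per-iteration trace as tab-delimited text (columns `evals`, `t`,
#' `best_objective`, `entropy_bits`, `K_eff`, `mean_fitness`) and, optionally,
#' a JSON summary (termination reason, best phenotype and objective, seed,
#' configuration echo).
#'
#' @param fit a `qga` object.
#' @param path output path for the trace table.
#' @param summary_path optional path for the JSON summary.
#' @return `fit`, invisibly.
#' @export
write_run_record <- function(fit, path, summary_path = NULL) {
  stopifnot(inherits(fit, "qga"))
  utils::write.table(fit$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(summary_path)) {
    summary <- list(
      landscape = fit$landscape,
      termination = fit$termination,
      evaluations = fit$evaluations,
      best_objective = fit$best_objective,
      best_phenotype = fit$best,
      seed = fit$seed,
      config = fit$config
    )
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(fit)
}
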