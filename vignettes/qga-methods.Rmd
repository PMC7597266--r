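---
title: "Selection, recombination, and entropy control: the methods behind qga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection, recombination, and entropy control: the methods behind qga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qga)
```

## The model

`qga` treats derivative-free optimization as natural selection on a fitness
landscape. A *variant* is a phenotype vector $x_i \in \mathbb{R}^D$ with
fitness $f(x_i)$ and frequency $p_i$; it stands for all organisms sharing that
phenotype, so the population is conceptually infinite and selection is
deterministic. Replicator dynamics
$\dot p_i = p_i (f_i - \bar F)$, with $\bar F = \sum_i p_i f_i$, integrates to
the Boltzmann form
$$p_i(t) = \frac{p_i(0)\, e^{t f_i}}{Z_t},$$
and this flow is natural-gradient ascent of $\bar F$: writing the population
as a categorical distribution with the Fisher information metric
$g_{ij} = \delta_{ij}/p_i + 1/p_K$ on the $K-1$ free frequencies, one has
$\dot p = g^{-1}\nabla_p \bar F$ (`natural_gradient_check()` verifies the
identity to $10^{-10}$). Two classical consequences anchor the theory layer:

* **Fisher's theorem.** $d\bar F/dt = \mathrm{Var}_p(f)$, tested by central
  finite differences at relative tolerance $10^{-4}$.
* **Gaussian closure on quadratics.** If phenotypes are normal
  $(\mu_0, \Sigma_0)$ and fitness is quadratic with gradient $\nabla f$ and
  curvature $C$ (the negative fitness Hessian) at $\mu_0$, they remain normal
  with
  $$\Sigma_t = (\Sigma_0^{-1} + tC)^{-1}, \qquad
    \mu_t - \mu_0 = \left(\tfrac{1}{t}\Sigma_0^{-1} + C\right)^{-1} \nabla f .$$
  As $t \to \infty$ the mean shift tends to the Newton step $C^{-1}\nabla f$;
  at finite $t$ selection is a regularized Newton method whose implicit
  trust region is the current population. `propagate()` implements this with
  Cholesky solves; gradient and curvature are frozen at $\mu_0$ for a call,
  so on non-quadratic landscapes it is a local approximation.

Selection buys fitness with diversity. Diversity is measured by the entropy
$S_t = -\sum_i p_i \log_2 p_i$ (bits) and the effective variant count
$K_t = 2^{S_t} \in [1, K]$. The genetic load $F^\dagger - \bar F$ (gap between
best observed and mean fitness) times $t$ is unit-less; for a Gaussian
population sitting at the optimum of a quadratic with $\Sigma = C^{-1}/t$ it
equals exactly $D/2$ (`continuous_load()`), while in finite populations the
scaled load peaks at intermediate selection and collapses at strong selection,
where the normal approximation fails. That tension — select too weakly and
nothing moves, too strongly and the population degenerates — motivates the
algorithm's control rule.

## The optimizer

`qga()` holds the population at a **target entropy** $S$, its only substantive
hyper-parameter:

1. With uniform base frequencies, entropy is monotone non-increasing in $t$
   (indeed $dS/dt = -t \,\mathrm{Var}_p(f)\,/\ln 2 \le 0$), so the scale $t^*$
   with $S_{t^*} = S$ is unique. We find it by geometric bracketing (factor 4,
   warm-started from the previous iteration's $t$) followed by bisection —
   geometric in $t$ once a positive lower bracket exists — to a default
   tolerance of $10^{-6}$ bits. The fixed point is identical to scanning $t$
   up and down by small geometric increments; bisection just reaches it in
   fewer entropy evaluations. Holding entropy fixed makes selection
   self-adaptive: a newly found high-fitness variant concentrates weight,
   so the solved $t$ can *decrease* as well as increase.
2. One recombinant per iteration is generated by the whole-population
   stochastic sum
   $$x' = \mathrm{center} + \sum_i \eta_i\, c_i\, (x_i - \mu_t), \qquad
     \eta_i \sim \mathcal N(0,1),$$
   with deviations always taken about the weighted mean $\mu_t$. Conditional
   on the parents, $x'$ is normal with covariance
   $\sum_i c_i^2 (x_i-\mu_t)(x_i-\mu_t)^\top$.
3. The recombinant is evaluated (one objective call) and replaces the variant
   with the smallest current weight (lowest index on ties), keeping the
   population size at $K_0 = \mathrm{round}(2^{S+1})$ — initial entropy
   $S+1$ bits, one bit above target, so the entropy equation is solvable from
   the first iteration.

**Coefficient form.** $c_i = \sqrt{p_i(t)}$ is the default because it is the
unique choice making the conditional covariance equal the weighted population
covariance $\Sigma_t$ *exactly* (an algebraic identity, tested to machine
precision, not a sampling statement). A literal $c_i = p_i$ variant is kept
behind `coef_form = "linear"` for comparison experiments. Because a finite
population's scatter about its own weighted mean underestimates the implicit
normal's covariance by the factor $1 - \sum_j p_j^2$, the default **unbiased**
mode divides the radicand by that factor; it is undefined (and errors) when a
single variant carries essentially all weight.

**Center policy.** `best_observed` (default) centers recombinants on the best
variant ever evaluated — the mean at infinite selection — tracked in a
register that survives eviction from the working population; benchmarks in
the harness compare it against `weighted_mean`, which is the covariance-exact
classical choice but takes smaller steps.

**Stopping.** Four termination reasons: `converged` (best objective within
`fitness_tolerance`, default $10^{-8}$, of a known optimum — only available on
benchmark landscapes), `budget_exhausted`, `duplicate_fitness`, and
`degenerate_population` (entropy target unreachable). The duplicate check
fires when two phenotypes that differ in some coordinate carry bit-identical
fitness, which in practice signals that $t$ has diverged and the objective
has been exhausted to the last ulp — the expected failure mode on plateaued
or quantized objectives (a floor-quantized quadratic reliably triggers it).
It is evaluated over the current working population each iteration, not over
run history: history would accumulate false positives from evicted variants
while the working population is exactly the set whose weights must stay
distinguishable.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `target_entropy` (S) | bits | 4 | diversity held during search; $K_0 = 2^{S+1}$ variants. Small S converges fast but can converge prematurely on a slope; large S costs evaluations. |
| `init_mean`, `init_sd` | phenotype units | landscape hint | initial diagonal normal; built-in landscapes carry the conventional values (ellipsoid: mean = var = 1; Rosenbrock: mean (0,1), sd 0.25; random quadratics: mean 0, sd 3). |
| `max_evaluations` | objective calls | 5×10⁴ | the standard benchmark budget. |
| `fitness_tolerance` | objective units | 10⁻⁸ | the standard success criterion against a known optimum. |
| `entropy_match_tol` | bits | 10⁻⁶ | solver tolerance; far below any behaviorally relevant scale. |

The selection scale $t$ has units of inverse fitness; fitness is the negated
objective, the one sign convention, applied at landscape construction.

## What the generators emulate — and what they do not

`random_quadratic_instance()` plays the role of a randomized benchmark
ensemble: curvature eigenvalues log-spaced over a condition spread of 100
(moderately ill-conditioned, enough to separate covariance-aware methods from
isotropic search without making runs expensive), a random rotation so no axis
is privileged, optimum uniform in $[-4,4]^D$, initialization mean 0 / sd 3.
The printed 5-variable test ellipsoid is kept verbatim even though its
quadratic form is rank one (its optimum is a whole hyperplane); full-rank
convergence claims therefore use the random instances. Test populations for
the theory layer are standard-normal phenotype clouds with quadratic fitness.
None of these exhibit multimodality, noise, discontinuities (beyond the
deliberately quantized floor landscape), or non-quadratic ridges other than
the 2-D Rosenbrock valley — so passing tests demonstrate correctness of the
operators and convergence on benign convex-ish terrain, not performance on
rugged real objectives.

Problem sizes in the tests and acceptance script — 20 seeded runs per
condition, $10^5$ Monte-Carlo draws, $10^5$ Moran replicates, populations of
up to 100 variants — were chosen as the smallest sizes at which the
qualitative claims are statistically unambiguous.

## Numerical choices

* Boltzmann weights use the log-sum-exp shift by $\max_i(t f_i)$ everywhere;
  $t$ grows exponentially during convergent runs, so the unshifted $Z_t$
  would overflow almost immediately. Entropy uses the $0\log 0 = 0$
  convention; base 2 is fixed in exactly one function.
* Input weight vectors are accepted when they sum to 1 within $10^{-9}$ and
  renormalized exactly; base frequencies are validated at $10^{-12}$.
* The entropy solver warm-starts from the previous $t$, expands brackets by
  factor 4, caps $t$ at $10^{30}$ (beyond which the population is reported
  degenerate), and handles the conventions: all-equal fitness returns $t = 0$
  flagged `flat`; a target at or above $\log_2 K$ returns $t = 0$.
* The Moran simulator runs the embedded birth–death jump chain: conditional
  on the mutant count changing, it increases with probability $r/(1+r)$
  independent of the count, so skipping no-change events leaves absorption
  probabilities untouched and each replicate retires the moment it is
  absorbed. The closed-form gambler's-ruin probability is the independent
  oracle in tests.
* Pairwise recombination samples *distinct* parents, which biases the
  conditional covariance by $O(\sum_i p_i^2)$; the conservation test
  therefore runs the with-replacement variant, and the distinct-parent form
  is what the optimizer's ancestor used before the population operator
  superseded it.

## Known limitations

* Convergence certification needs a known optimum; on real problems only the
  budget and duplicate-fitness stops apply.
* The duplicate-fitness check makes the algorithm fail deliberately on
  step-quantized objectives.
* One recombinant per iteration is inherently serial; there is no parallel
  evaluation mode.
* The entropy target is a genuine hyper-parameter: too small and runs
  converge prematurely on slopes (at $S = 1$ on 5-D quadratics, success
  collapses relative to $S = 5$ — the acceptance suite measures this), too
  large and evaluations are wasted. No automatic tuning is attempted.

```{r example}
fit <- qga(rosenbrock2d(), target_entropy = 4, max_evaluations = 5e4, seed = 11)
fit
plot(fit)
```
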