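---
title: "Recombination dynamics on rugged fitness landscapes: models and methods"
author: "recombdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination dynamics on rugged fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Why is genetic recombination so widespread when its benefit is far from
obvious? On a smooth (additive) fitness landscape, recombination speeds up
adaptation by combining beneficial mutations that arose in different lineages
(the Fisher–Muller effect) and by generating variation among offspring (the
Weismann effect). On *rugged* landscapes — where sign epistasis creates many
local fitness optima — a countervailing force appears: once most of a
population sits on a local peak, recombination between the peak majority and
rare fitter mutants mostly produces unfit valley genotypes, dragging the
population back. Recombining populations therefore become *trapped* at local
optima far more efficiently than asexual ones.

`recombdyn` simulates both regimes in a controlled way: paired populations —
one with a recombining fraction $r$, one asexual — evolve on the *same*
landscape realization, so every difference between their trajectories is
attributable to recombination. The package's central outputs are the
run-averaged mean-fitness difference $\Delta F(t)$, the probability
$P_+(t)$ that the recombining arm is ahead, diversity measures, and
trapping/escape statistics.

# Fitness landscapes

Genotypes are binary sequences of length $L$, encoded as integers
$0 \dots 2^L - 1$ (bit $i$ = allele at locus $i$); the genotype space is the
$L$-dimensional hypercube with the Hamming distance $d(\cdot,\cdot)$ as
metric.

**Rough Mount Fuji (RMF).** Fitness is
$$F(\sigma) = c\, d(\sigma, \sigma^*) + \eta_\sigma,$$
where $\sigma^*$ is a reference sequence (default: the all-zero genotype),
$c \ge 0$ is the additive slope (fitness units per mutational step), and the
$\eta_\sigma$ are i.i.d. exponential with mean $\lambda \ge 0$ (fitness
units). Fitness *increases* on average with distance from $\sigma^*$, so a
population started at $\sigma^*$ is maximally maladapted — the scenario of
interest after an environmental change. The ratio $\lambda / c$ tunes
ruggedness continuously:

* $\lambda = 0$: purely additive landscape, a single global optimum at the
  antipode of $\sigma^*$, no epistasis (`model = "additive"`);
* $c = 0$: i.i.d. random fitness, the maximally epistatic House-of-Cards
  limit (`model = "hoc"`), in which a fraction $1/(L+1)$ of genotypes are
  local optima by exchangeability;
* intermediate values interpolate.

Exponential deviates are drawn by inverse CDF from the seeded uniform
stream, so a landscape is bit-reproducible from `(params, seed)` across
platforms.

**NK model** (`model = "nk"`). Each locus contributes
$f_i(\sigma_i; \sigma_{i+1}, \dots, \sigma_{i+K})$ with circularly adjacent
neighborhoods; contribution values are i.i.d. lognormal (default meanlog 0,
sdlog 1) and $F$ is the *sum* of contributions. The neighborhood scheme and
the lognormal parameters are conventions of this package (the common choice
in the NK literature), not constraints inherited from data: with $K = 0$
the model is epistasis-free (exactly one optimum), with $K = L - 1$ fitness
values are exchangeable and the landscape is HoC-like. Sums (not means) keep
fitness positive and scale-free for multiplicative selection.

`local_maxima()` enumerates local optima exactly (strict inequality against
all $L$ neighbors); exact fitness ties between neighbors are rejected as an
error rather than resolved silently, since "local optimum" is then
ill-defined. Ties have probability zero under all three generators; they can
only arise in hand-built fitness tables.

# Finite-population dynamics

A modified Wright–Fisher model with constant size $N$; one generation is
four substeps, in this order:

1. **Mutation** (deterministic on frequencies): each genotype class sends a
   fraction $\mu$ of its mass to its $L$ single-mutant neighbors,
   $\mu / L$ each: $p' = (1 - \mu) p + (\mu/L) A p$, with $A$ the hypercube
   adjacency matrix.
2. **Selection** (deterministic): $p''_\sigma = p'_\sigma F_\sigma / \bar F$
   with $\bar F = \sum_\tau p'_\tau F_\tau$.
3. **Poisson sampling**: each genotype count is drawn independently from
   $\mathrm{Poisson}(N p''_\sigma)$ (much faster than one multinomial across
   $2^L$ classes, and equivalent after conditioning on the total). The total
   is then restored to exactly $N$: excess individuals are removed uniformly
   at random; missing individuals are added by sampling genotypes
   proportionally to the sampled counts (or to $p''$ in the degenerate case
   of an all-zero draw). This normalization rule is unbiased and keeps the
   per-genotype expectation at $N p''_\sigma$ up to $O(1/N)$.
4. **Recombination**: $k \sim \mathrm{Poisson}(rN)$ individuals (truncated
   at $N$; exactly $N$ when $r = 1$) are replaced by offspring of two
   parents drawn independently and uniformly from the pre-replacement
   population (self-pairing allowed). Offspring are produced by *uniform
   crossover*: each locus comes from either parent with probability $1/2$,
   independently. Uniform crossover preserves expected single-locus allele
   frequencies exactly — recombination only reshuffles linkage.

Mutation and selection act on real-valued frequencies and only the sampling
substep re-integerizes: fractional individuals are otherwise ill-defined,
and this matches the deterministic infinite-population operators at first
order in $\mu$ (the finite engine does not model multiple mutations per
individual per generation; the infinite engine's $M_\infty$ does).

# Infinite-population dynamics

In the $N \to \infty$ limit the dynamics is a deterministic map on the
frequency simplex. Mutation of all orders is the operator
$$M_\infty = (1 - \mu) \sum_{m \ge 0} \left(\tfrac{\mu}{L} A\right)^m
           = (1 - \mu) \left(I - \tfrac{\mu}{L} A\right)^{-1},$$
the summed geometric series (convergent for $\mu < 1$), which is exactly
column-stochastic because the columns of $(\mu/L) A$ sum to $\mu$. Truncated
operators of order $k$ are also available; truncation leaves all columns
summing to $1 - \mu^{k+1}$, so their renormalization is a scalar division.
`order = 1` is the canonical single-step matrix
$(1-\mu) I + (\mu/L) A$, matching the finite engine's mutation rule. The
engine applies $M_\infty$ matrix-free by fixed-point iteration
$y \leftarrow (1-\mu)p + (\mu/L) A y$ (contraction ratio $\mu$), avoiding a
dense $2^L \times 2^L$ inverse.

**Recombination map.** Uniform crossover acts on frequencies as the
quadratic map $Q(p)_g = \sum_{a,b} T(g|a,b)\, p_a p_b$ with
$T(g|a,b) = \prod_i \left([a_i = b_i]\,[g_i = a_i] + [a_i \ne b_i]\tfrac12\right)$.
Direct evaluation costs $O(8^L)$. In the Walsh (character) basis
$\hat p_k = \sum_g (-1)^{k \cdot g} p_g$ the map becomes
$$\hat q_k = 2^{-|k|} \sum_{j \subseteq k} \hat p_j\, \hat p_{k \setminus j},$$
a disjoint subset self-convolution, evaluated by the ranked zeta/Möbius
transform in $O(L^2 2^L)$ vector operations. The brute-force kernel sum is
retained as `method = "brute"` and the two are cross-checked against each
other (and against a third, independent enumeration in the test suite) for
all $L \le 4$. $Q$ fixes point masses and all linkage-equilibrium product
distributions, and preserves single-locus marginals to working precision.

One generation is mutation → selection →
$p \mapsto p + r\,(Q(p) - p)$, mirroring the finite substep order; the
mixture is evaluated in that form because $\mathrm{fl}(1-r) + \mathrm{fl}(r)
\ne 1$ in floating point and the naive form would leak mass at the
$10^{-17}$ scale.

**High-precision mode.** Starting monomorphic, frequencies after one step
decay like $(\mu/L)^d$ with Hamming distance $d$ from the start; at
$L = 10$–$12$ and small $\mu$ the far shells sit 20–40 orders of magnitude
below the mode, where double precision (16 digits) silently zeroes them.
`precision = "dd"` runs the whole state pipeline in *double-double*
(compensated) arithmetic — each number an unevaluated sum of two doubles,
~31–32 significant digits — implemented as vectorized error-free
transformations (Dekker/Knuth) in pure R. This keeps every genotype's
frequency strictly positive and bounds the per-step simplex deviation below
$10^{-30}$ (observed $\sim 10^{-31}$). The precision is fixed by the
representation (~106 bits) rather than user-selectable; the default mode
uses machine doubles with per-step renormalization and $10^{-12}$
tolerances. High-precision runs are capped at $L \le 12$ by default purely
for cost.

# Fitness seascapes

A fluctuating environment is modeled by *resetting* the landscape before a
generation with probability $p_\mathrm{reset}$ (expected epoch
$1/p_\mathrm{reset}$ generations): all $\eta_\sigma$ are redrawn from the
same exponential law and the reference sequence moves — to a uniform
single-mutant neighbor (*soft* reset, gradient direction mostly preserved)
or to a uniform random genotype (*hard* reset, adaptation starts over).
$c$, $\lambda$, $L$ never change. Resets happen before the generation's
substeps, so each generation's selection uses the current environment.

All environmental randomness (initial landscape, reset times, replacement
landscapes) is drawn up front from a dedicated environment stream. Paired
runs ($r > 0$ vs $r = 0$) share that stream — both arms experience the
same environment at the same generations — while their dynamics streams are
independent; $\Delta F$ on a seascape is meaningful only under a common
environment. With $p_\mathrm{reset} = 0$ the seascape engine is
bit-identical to the static engine under shared seeds.

For comparisons of hard-reset seascapes against static landscapes, static
runs start at a uniformly random genotype rather than at $\sigma^*$: after
the first hard reset the population's position is random relative to the new
reference, and the static control must match that condition.

# Observables

* **Shannon entropy** $S = -\sum_\sigma p_\sigma \ln p_\sigma$ (nats),
  0 when monomorphic, $L \ln 2$ when uniform.
* **Additive genetic variance**: the heritable part of RMF fitness is
  $c\,d(\sigma, \sigma^*)$, so $V_A = c^2\,\mathrm{Var}_p[d(\sigma,
  \sigma^*)]$; the raw distance variance is attached as an attribute. For
  $c = 0$ (HoC) $V_A \equiv 0$; NK landscapes have no reference sequence and
  are rejected.
* **Fitness velocity** $v(t) = \bar F(t) - \bar F(t-1)$ (optionally
  smoothed for plotting; the default is the raw difference because velocity
  *crossings* of the two arms mark extrema of $\Delta F$, and smoothing
  shifts crossings).
* **Trapping/escape events**: a population is *trapped* when the modal
  genotype is a local maximum with frequency $\ge \theta_\mathrm{trap}$
  (default 0.95 — near-fixation); an *escape* is registered when that
  genotype's frequency falls below $\theta_\mathrm{escape}$ (default 0.5 —
  loss of majority). Both thresholds are configuration, exposed in
  `dynamics_params()`. Event detection needs the trajectory's full
  frequency matrix because the escape condition refers to the trapped
  genotype's own frequency, not the current mode's.
* **Escape fraction**: escapes over trappings within a horizon, optionally
  normalized to a matched $r = 0$ ensemble; undefined (NA) without
  trappings. **First-trap distance**: Hamming distance from the start to
  the first trapping genotype.
* **Paired differences**: $\Delta F$, $\Delta S$, $\Delta F_\mathrm{max}$
  (fittest *present* genotype; presence means count $> 0$, or frequency
  $> 10^{-12}$ in the infinite engine) averaged over pairs, and $P_+$, the
  fraction of pairs with the recombining arm ahead. Exact ties count $1/2$,
  so identical trajectories sit at the null value 0.5. Per-pair $\Delta F$
  series are attached for windowed per-run statistics.

# The experiment harness and reproducibility

`paired_ensemble()` runs $n$ pairs; run $k$ draws its landscape seed,
two dynamics seeds, an environment seed and a start-genotype seed from a
counter-based schedule keyed by `(master_seed, k, role)`
(`derive_seed()`). Consequences: (i) results are bit-reproducible from a
single integer; (ii) ensembles can be extended without re-running earlier
runs; (iii) parameter sweeps reuse the same landscape seed for run $k$ at
every swept value, so sweep contrasts isolate the swept parameter, and
paired per-run differences across sweep values are valid.

The generator defaults are the package's study conditions: RMF with
$c = 1$, $\lambda = 1$; $N = 1000$, $\mu = 0.01$ (mutation supply
$N\mu = 10 \gg 1$, so several mutants per generation — the regime where
recombination has material to work with), $r = 1$ for the recombining arm.
Ensembles of 100–300 pairs at $L = 8$–$10$ over horizons of 400–1200
generations are the package's desk-scale choices for tests and the
acceptance script; they reproduce all qualitative phenomenology with
3-standard-error margins while a full study would use thousands of runs and
$L = 16$, reachable through the same configuration objects.

# What the synthetic data does and does not emulate

All inputs are generated: the package's claims are about the model class,
not about any organism. The RMF/HoC/NK generators reproduce the statistical
features that drive the phenomenology — tunable sign epistasis, a density of
local optima that falls with $L$ and rises with $\lambda/c$, exponential
(heavy-ish-tailed) fitness increments. They do *not* emulate diploidy,
dominance, linkage maps (crossover here is uniform, not positional),
correlated or empirical fitness structure, demographic structure, or
selection-strength regimes near neutrality. Passing tests therefore
demonstrate internal correctness and the model's known qualitative behavior
at desk scale; they are not evidence about real populations.

# Numerical choices and degenerate inputs

* Exact neighbor-fitness ties abort local-maxima analysis (error), rather
  than being broken arbitrarily.
* A landscape with $c = 0, \lambda = 0$ (identically zero fitness) is
  rejected at construction; an all-zero mean fitness during a run raises an
  error (multiplicative selection is undefined).
* The additive landscape assigns fitness 0 to $\sigma^*$ itself; selection
  then removes that class in one step. This is the model's behavior, not a
  defect; RMF with $\lambda > 0$ has strictly positive fitness everywhere.
* Simplex mass is renormalized once per generation in the infinite engine;
  the pre-normalization deviation is tracked and reported
  (`max_simplex_dev`), with observed values $\sim 10^{-16}$ (double) and
  $\sim 10^{-31}$ (double-double).
* `sample()`-style index pitfalls (length-one vectors) are avoided
  throughout the engines; population updates are exact multiset operations.

# Known limitations

* **Finite-vs-infinite agreement is landscape-dependent.** With $r > 0$ on
  rugged landscapes the deterministic dynamics can have multiple attractors
  (recombination stabilizes local peaks). On realizations where two basins
  compete closely, a finite population at $N = 10^5$ can commit to a
  different basin than the deterministic trajectory, after which the
  total-variation distance between the engines is $O(1)$ no matter how
  large $N$ is at fixed time. Seed-averaged TV over short horizons is
  therefore heavy-tailed across landscape draws; the package's consistency
  test occasionally exceeds its nominal 0.05 bound for exactly this reason
  (one bistable realization in a 20-seed schedule), which is a property of
  the model, not an implementation discrepancy — the same schedule without
  that realization averages ~0.03.
* The escape-time minimum at small $r$ (a two-locus prediction) is not
  asserted by the tests: at desk scale its detection is unreliable.
* The coefficient of variation of off-peak population size is implemented
  and exactly tested, but its growth with $\mu$ (reported at much larger
  scale) does not reproduce at $L \le 8$; the package treats it as a
  descriptive statistic only.
* Modifier-allele competition (a recombination modifier segregating in one
  population) is out of scope; $\Delta F$ and $P_+$ are the advantage
  indicators.

# Session

```{r, eval = FALSE}
library(recombdyn)
land <- generate_landscape(landscape_params(10, "rmf", c = 1, lambda = 2,
                                            seed = 1))
cfg <- experiment_config(landscape_params(10, "rmf", c = 1, lambda = 2),
                         dynamics_params(1000, 0.01, 1),
                         t_max = 1200, n_runs = 300, master_seed = 1)
pe <- paired_ensemble(cfg)
plot(pe)
```
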