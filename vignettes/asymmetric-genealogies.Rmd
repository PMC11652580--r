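---
title: "Genealogies with non-heritable asymmetric reproductive success: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogies with non-heritable asymmetric reproductive success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymcoal)
```

## The model class

A neutral population of constant size $N$ evolves in discrete generations.
Neutrality is imposed not through exchangeable offspring numbers (the
Cannings assumption) but through two weaker conditions: the one-generation
reproduction law is drawn i.i.d. across generations (*static environment*),
and children choose parents exchangeably (*non-heritability*). Reproductive
success may therefore be arbitrarily skewed within a generation — a random
individual sweeping half the population, a bottleneck in which only $k$
individuals reproduce — as long as the skew is not inherited.

Two parametrizations are implemented.

* **Asymmetric Wright–Fisher (AWF)**: a random probability vector
  $\eta = (\eta_1,\dots,\eta_N)$ is drawn; each child independently picks
  parent $i$ with probability $\eta_i$. Grouping $n$ sampled children by
  parent is exactly the paint-box construction directed by $\eta$, so the
  one-generation coagulation probabilities are
  $$P(\tilde\pi) = \mathbb E\Big[\sum_{i_1,\dots,i_j\ \text{distinct}}
  \eta_{i_1}^{b_1}\cdots\eta_{i_j}^{b_j}\Big],$$
  with $b_1,\dots,b_j$ the block sizes of $\tilde\pi$, and the
  pair-coalescence probability is $c_N = \mathbb E[\sum_i \eta_i^2]$.
* **Asymmetric Cannings (AC)**: an integer offspring vector $\xi$ with
  $\Sigma = \sum_i\xi_i \ge N$ is drawn and the next generation (or the
  sampled $n$ children) is a uniform sample *without replacement* from the
  $\Sigma$ child slots. The probabilities take the same form with falling
  factorials, $(\xi_{i_k})_{b_k}$ over $(\Sigma)_n$, and
  $\tilde c_N = \mathbb E[\sum_i \xi_i(\xi_i-1)/(\Sigma(\Sigma-1))]$.

The genealogy of a sample of size $n$ is the Markov chain on partitions of
$\{1,\dots,n\}$ started from singletons and driven by i.i.d. exchangeable
coagulation increments with these laws. When
$P(\tilde\pi) = c_N\,Q(\tilde\pi) + o(c_N)$ for the coagulation matrix $Q$
of a $\Xi$-coalescent and $c_N \to 0$, the genealogy on the timescale
$t/c_N$ converges to that coalescent. The package's diagnostics
operationalize this condition empirically; its model zoo supplies families
whose limits span Kingman, Bolthausen–Sznitman, general Beta and
"symmetric/Dirichlet" bottleneck coalescents.

The two parametrizations differ by sampling with versus without
replacement. `ac_awf_discrepancy()` quantifies this: normalizing
$\eta_i = \xi_i/\Sigma$ and comparing the two transition laws row-wise gives
an operator-norm difference of order $\mathbb E[1/\Sigma]$, so whenever
$c_N/\mathbb E[1/\Sigma] \to \infty$ the AC and AWF genealogies share their
limit. The report flags this ratio. Note the converse failure built into the
arithmetic: for $\xi \equiv (1,\dots,1)$ the AC law is coalescence-free
while the induced AWF law is uniform Wright–Fisher, and the row-sum
difference is exactly $2(1-(N)_n/N^n) \approx 2\binom n2/N$ — the
equivalence genuinely requires multiple mergers to dominate the $1/N$ scale.

## Partition calculus

Partitions are stored canonically: blocks sorted internally, ordered by
least elements, 1-based labels; equality is equality of canonical block
lists, and every coagulation re-canonicalizes. The compact string form
`"1,3|2"` is used in JSON-lines traces.

Mass partitions (ranked frequencies with dust $\rho_0 = 1-\sum_i\rho_i$)
enforce their sum constraint to $10^{-12}$ absolute and *reject* violations
rather than renormalizing — silent renormalization has hidden more than one
model bug. Paint-box sampling assigns i.i.d. uniforms to half-open intervals
$[\sum_{j<k}\rho_j, \sum_{j\le k}\rho_j)$ with the dust interval last; dust
hits become singletons. `paintbox_prob()` evaluates the probability of a
given partition exactly: non-singleton blocks are matched injectively to
intervals, and the singleton factor sums over which singletons occupy unused
intervals versus dust, via elementary symmetric polynomials. This exact
kernel is what the $\Xi$ rate matrix integrates; rate matrices switch to
Monte-Carlo paint-box sampling above a configurable ground-set size
(default $n > 8$).

Distinct-index sums $\sum_{\text{distinct}}\prod_k f_k(i_k)$ — the
computational core of both transition formulas — are evaluated by the
augmented-monomial expansion over set partitions of the $j$ blocks with
Möbius weight $\prod_B (-1)^{|B|-1}(|B|-1)!$. Cost is $\mathrm{Bell}(j)\cdot
N$, exact for any per-block functions (powers or falling factorials), which
is what lets "exact given the draw" computations run at $N$ in the tens of
thousands.

## Collision rates

For a finite measure $\Lambda$ on $[0,1]$, a specific group of $b$ of $n$
blocks merges at rate $\lambda_{n,b} = \int_0^1 p^{b-2}(1-p)^{n-b}\,
\Lambda(dp)$: closed form for Beta measures
($\lambda_{n,b} = m\,B(a+b-2, c+n-b)/B(a,c)$) and point masses, adaptive
Gauss–Kronrod quadrature (absolute tolerance $10^{-10}$) otherwise. The
consistency recursion $\lambda_{n,b} = \lambda_{n+1,b} + \lambda_{n+1,b+1}$
is verified to $10^{-10}$ across measure families in the tests, as is the
Bolthausen–Sznitman closed form $\lambda_{b,b} = 1/(b-1)$ for
$\Lambda = \mathrm{Beta}(1,1)$.

$\Xi$ measures are represented as finite atom lists plus a Kingman mass at
the zero mass partition; all the concrete model families here need only
finite support (continuous $\Xi$ is handled by caller-supplied Monte-Carlo
atoms). The rate of a partition is the paint-box probability weighted by
$w/\sum_i\rho_i^2$ — so a $\Lambda$ measure embeds as atoms
$(p;\ \text{dust } 1-p)$ with weight equal to its mass at $p$, the $p^2$
division converting $p^b$ into the collision kernel $p^{b-2}$.

`simulate_lambda_coalescent()` is the continuous-time reference chain: with
$m$ blocks, total jump rate $\sum_b \binom mb \lambda_{m,b}$, group size
chosen proportionally, merging blocks uniform. It exists to cross-check the
forward simulators through the same trace/Newick machinery.

## Convergence diagnostics

**Size-biased moments.** The existence of the limits
$\phi_j(b_1,\dots,b_j) = \lim_N \mathbb E[\prod_i s_i^{b_i-1}\prod_{i<j}
(1-S_i)]/c_N$, where $(s_i)$ is the size-biased reordering of $\eta$,
characterizes convergence of AWF genealogies to some $\Xi$-coalescent. The
identity behind `phi_estimate()`'s default estimator: conditional on
$\eta$, the expectation of the size-biased product equals the distinct-index
sum $\sum_{\text{distinct}}\prod_k \eta_{i_k}^{b_k}$. Using this conditional
expectation per draw (a Rao–Blackwellization) removes all reordering noise;
with $c_N$ estimated on the same draws, $\phi(2) = 1$ holds to machine
precision *identically* and the additivity recursion
$\phi(b_1,\dots,b_j,1) + \sum_k \phi(\dots,b_k+1,\dots) =
\phi(b_1,\dots,b_j)$ becomes an algebraic identity per draw. The raw
sampling estimator is retained and cross-checked against the conditional one
within joint standard errors. A finite-$N$ harness can only certify
consistency of these limits at the tested sizes, never their existence —
reports carry standard errors and z-scores for that reason.

**$\Lambda$ and Kingman criteria.** Convergence to a $\Lambda$-coalescent
follows when a single distinguished family index satisfies
$\mathbb E[\eta_i^b] \sim c_N \lambda_{b,b}/\lambda_{2,2}$ for all $b$;
`lambda_criterion()` estimates these ratios (common random numbers for
numerator and $c_N$) and z-scores them against a candidate measure. The
index defaults to 1 — for the Poisson–Dirichlet families below, the first
*size-biased* pick, which need not be the largest frequency. The Kingman
criterion estimates $\mathbb E[\sum_{i\ge2}\eta_i^3]/c_N$ and
$\mathbb E[\eta_1^\beta]/c_N$ ($\beta>2$). All $o(c_N)$ conditions are
operationalized as monotone-trend/log-log-slope tests across a geometric $N$
grid (default $\{N, 4N, 16N\}$): the theory gives asymptotics, not
finite-$N$ thresholds, so a trend is the honest finite-$N$ statement.
`eq_convergence_harness()` finally compares $P(\tilde\pi)/c_N$ directly with
candidate rates, normalized by the candidate's pair rate so that the $n=2$
ratio is 1 by construction.

## The model zoo and its defaults

**Eldon–Wakeley sweeps.** One uniformly chosen parent leaves
$\lfloor YN\rfloor$ copies, replacing as many randomly chosen individuals;
$Y$ follows the normalized law $y^{-2}\Lambda(dy)$ truncated to
$(N^{(\epsilon-1)/2}, 1]$, $\epsilon\in(0,1)$, which places the model in the
$\Lambda$-coalescent domain with $c_N \sim \mathbb E[Y^2]$. Sampling uses
the exact inverse CDF for the uniform measure and a log-spaced 20 000-point
inverse-CDF grid otherwise (moment error far below Monte-Carlo resolution);
`ew_y_moment()` provides the independent quadrature oracle.
$\lfloor YN\rfloor = 0$ (a generation of singletons) and
$\lfloor YN\rfloor = N$ (a deterministic full merge) are both legal.

**Recurrent bottlenecks.** With probability $\sum_{k\le b_N}F(k)/a_N$ a
generation descends from $k\sim F|_{[b_N]}$ individuals with conditional
frequency law $\bar\nu_k$ (symmetric $1/k$, or normalized i.i.d. Exp(1)
weights, or user-supplied), otherwise from a background model. Fresh
independent $\bar\nu_k$ draws are taken at every bottleneck event. In the
bottleneck-dominated regime the limit rates are the $F(k)$-weighted
paint-box matrix; `classify_bottleneck_regime()` reads the regime off the
trajectory of $\hat c_N a_N$ and assembles the mixed-regime matrix
$\bar Q + \ell Q$ when that product stabilizes at $\ell > 0$. Test and
acceptance runs use $N = 400$, $a_N = \sqrt N$, $F = \delta_2$: bottleneck
probability $0.05$, large enough to dominate the $1/N$ background by a
factor $\approx 10$ while keeping $30\,000$-generation Monte-Carlo runs
cheap; the background still contributes visibly ($\approx 9\%$ of $c_N$) and
the reported ratios show it, which we consider a feature of the diagnostic
rather than noise to hide.

**Poisson–Dirichlet power frequencies.** From a PD($\alpha,\theta$)
size-biased pick via stick breaking ($Y_i \sim \mathrm{Beta}(1-\alpha,
\theta+i\alpha)$, $\tilde V_i = Y_i\prod_{j<i}(1-Y_j)$), set
$\eta_i = \tilde V_i^\gamma / \zeta_{N,\gamma}$,
$\zeta_{N,\gamma} = \sum_{j\le N}\tilde V_j^\gamma$. All weight arithmetic
is in log space; $\gamma = 0$ short-circuits to the exactly uniform vector
without consuming random numbers, so the uniform special case is
bit-identical to Wright–Fisher under a shared seed.

**The $(N,\beta,\kappa)$ exponential model.** Particles at positions $x$
branch into Poisson point processes of intensity $e^{-(s-\kappa x)}ds$; $N$
children survive, sampled without replacement with weights $e^{\beta x}$
($\beta > 1$ makes the weights summable). By superposition the joint
offspring process is a single PPP shifted by $X_{eq} = \log\sum_i
e^{\kappa X_i}$, parents are assigned independently with probabilities
$e^{\kappa X_i}/\sum_j e^{\kappa X_j}$, and the family-frequency vector is
distributed exactly as the PD power family with $(\alpha,\theta,\gamma) =
(1/\beta, 0, \kappa/\beta)$ — `exp_model_reduction()` is that exact
shortcut, and the Kolmogorov–Smirnov comparison of the largest family
frequency between the explicit step and the reduction (2 000 draws per arm,
$p > 0.01$ with a three-seed retry rule against multiple-testing false
alarms) is the distributional check. Implementation notes: selection is
Gumbel-top-$k$ in log space (no overflow of $e^{\beta x}$); PPP atoms
$z_i = -\log(E_1+\dots+E_i)$ are generated to a base truncation of
$\max(40N, 2000)$ atoms and then *extended adaptively* until the last atom's
selection-weight share falls below $10^{-6}$ — a fixed truncation cannot
guarantee that bound because the share scales with
$1/\sum_i e^{\beta z_i}$, which is heavy-tailed through the first arrival.

## Timescale constants of the power family

For $\gamma \in (\alpha/2, \alpha]$ write $u_N = \sum_{i\le N}
i^{-\gamma/\alpha}$. `pd_constants()` assembles, in closed form:

* the compensator $\mu_N = \sum_{i\le N}[\psi(\theta+(i-1)\alpha+1) -
  \psi(\theta+i\alpha)]$ of the log-stick martingale $S_N = \mu_N +
  \sum_{i\le N}\log(1-Y_i)$;
* $\Upsilon_a$, the limit of $\sum_{i\le M}(a+i)^{-1} - \log M$, evaluated
  as $-\psi(a+1)$ (a digamma identity; a test confirms the defining limit),
  with $\Upsilon_0$ the Euler–Mascheroni constant;
* the centering constant $K_{\alpha,\theta}$ defined by $e^{\gamma\mu_N}
  \sim \alpha^{-\gamma}K^\gamma N^{\gamma(1-\alpha)/\alpha}$. Expanding
  $\mu_N$ gives $K = \exp\{\psi(\theta+1) + \Upsilon_{\theta/\alpha}/\alpha\}
  = \exp\{\psi(\theta+1) - \psi(\theta/\alpha+1)/\alpha\}$; we verify this
  against the defining limit numerically, and against the exact product
  formula for $\mathbb E[e^{\gamma S_\infty}]$. (Derivations of this
  constant in the literature differ by the sign of the $\Upsilon$ term;
  the defining limit is unambiguous and is what the package tests.)
* the constant $\ell_{\alpha,\theta,\gamma}$ of the timescale
  $L_N = \ell\, u_N^{1+\theta/\alpha}$, with the $\theta = 0$
  simplification $\ell^{-1} = (\alpha/\gamma)\,\Gamma(2-\gamma/\alpha)\,/\,
  (\Gamma(1+\gamma-\alpha)\Gamma(1+\alpha-\gamma))$ cross-checked against
  the general display to $10^{-12}$.

`zeta_limit_check()` monitors the pathwise law of large numbers
$\zeta_{N,\gamma}/(u_N e^{\gamma S_N}) \to
\Gamma(1+\gamma-\alpha)\Gamma(1-\alpha)^{-1} K^{-\gamma}$. The limit is
deterministic but the fluctuation term is a fixed random variable divided by
the *slowly* diverging $u_N$ (at $(\alpha,\theta,\gamma) = (0.7,0.2,0.6)$,
$u_{10^5} \approx 36$), so individual paths still sit several percent — and
occasionally tens of percent — away at $N = 10^5$; the package therefore
reports the mean ratio over 5 independent paths alongside the per-path
deviations. The mean concentrates markedly better than single paths but
still inherits the heavy upper tail of the fluctuation variable, so
occasional 5-path means land outside a 10% band; the per-path spread in the
report is the honest uncertainty statement.

### Convergence-speed caveats, and where the general-$\gamma$ constants fail

Two caveats matter when comparing Monte-Carlo estimates against these
constants, and both are quantified by `scripts/acceptance.R`:

1. **At $\gamma = \alpha$ convergence is logarithmic.** For
   $(\alpha,\theta,\gamma) = (0.7,0,0.7)$ the moment ratio
   $\mathbb E[\eta_1^3]/c_N$ is $\approx 0.446$ at $N = 5000$ and drifts
   toward its Bolthausen–Sznitman limit $0.5$ like $1/\log N$; likewise
   $c_N u_N$ at $(\beta,\kappa) = (2,1)$ is $\approx 0.87$ at $N = 5000$ on
   its way to $1$. Point estimates at accessible $N$ therefore sit many
   standard errors from the limits even though the limits are correct;
   trend tests across an $N$ grid, not fixed-$N$ bands, are the reliable
   finite-$N$ diagnostic.
2. **For $\gamma < \alpha$ the measured timescale disagrees with the
   $u_N^{1+\theta/\alpha}$ prediction.** At $(\beta,\kappa) = (2,0.75)$ —
   i.e. $(\alpha,\gamma) = (0.5,0.375)$ — the product $c_N u_N$ *decreases*
   through $0.52$ at $N = 5000$ with no sign of stabilizing at either
   closed-form candidate constant ($1.178$ or $1.163$). A saddle-point
   analysis of $\mathbb E[\eta_1^b]$ (the mass concentrates where
   $1-\tilde V_1 \lesssim \zeta^{-1/\gamma}$) instead gives $c_N \asymp
   u_N^{-\alpha/\gamma}$ and moment ratios $B(a, b-a)/B(a, 2-a)$ with $a =
   \alpha/\gamma$ — a $\mathrm{Beta}(2-\alpha/\gamma, \alpha/\gamma)$
   coalescent signature; the acceptance script reports the measured
   low-$\gamma$ ratio ($\approx 0.35$ at $N = 2\times10^4$, against $1/3$
   from the saddle-point form and $0.5$ from $\gamma$-independence). At
   $\gamma = \alpha$
   ($a = 1$) the two analyses coincide and everything is consistent. Until
   this is resolved, treat `pd_constants()` output for $\gamma < \alpha$ as
   the package does: a documented closed form whose empirical support is
   limited to $\gamma = \alpha$.

## Reproducibility and scope

Every simulation entry point consumes R's global RNG; `run_simulation()`
derives one deterministic 32-bit stream seed per replicate from the root
seed (`replicate_seed()`), records the root seed in the resolved
configuration it writes next to every artifact, and produces byte-identical
outputs for identical (configuration, seed). Counter-based per-generation
streams are not used — base R lacks them — so parallel replay *within* a
replicate is not supported; replicates themselves are independent streams.

Problem sizes used by the test suite and acceptance script — $N$ up to
$10^4$–$10^5$ for moment diagnostics, $10^4$ draws for distributional
checks, 5 paths for pathwise limits — were chosen as the smallest sizes at
which the quantities above are resolvable against their Monte-Carlo errors.

What the generators emulate — and what they do not: constant population
size, non-overlapping generations, haploid reproduction, no mutation or
sequence evolution, and reproduction laws drawn i.i.d. across generations.
Passing diagnostics therefore demonstrate that the simulators have the
distributions they claim and that their genealogies behave as the limit
theory predicts at moderate $N$; they say nothing about fit to any real
population, and none of the machinery addresses inference from observed
genetic data.
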