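# asymcoal

Genealogies of neutral discrete-time populations with **non-heritable
asymmetric reproductive success**, and their multiple-merger coalescent
limits.

Classical Cannings models assume the offspring numbers
(ξ₁, …, ξ_N) of the N parents are *exchangeable*. This package works with the
weaker assumption that differences in reproductive success are simply not
heritable: every generation draws a fresh, possibly highly asymmetric,
reproduction law, and children choose parents exchangeably. Two
parametrizations are covered:

* **Asymmetric Cannings (AC)** — an integer offspring vector ξ with
  Σξᵢ ≥ N; the sampled children are drawn *without* replacement from the
  offspring slots. One-generation coagulation probabilities are
  P̃(π̃) = E[ Σ_{distinct i₁…iⱼ} ∏ₖ (ξ_{iₖ})_{bₖ} / (Σξ)ₙ ]
  with falling factorials (a)_b and block sizes bₖ of π̃.
* **Asymmetric Wright–Fisher (AWF)** — children pick parents i.i.d. from a
  random frequency vector η (multinomial offspring); then
  P(π̃) = E[ Σ_{distinct} ∏ₖ (η_{iₖ})^{bₖ} ], and the pair-coalescence
  probability (the coalescent timescale) is c_N = E[ Ση ᵢ² ].

Genealogies of samples are discrete-time coalescents built by iterating the
coagulation operator with i.i.d. exchangeable increments; when
P(π̃) = c_N · Q(π̃) + o(c_N) for the coagulation matrix Q of a Ξ-coalescent,
the rescaled genealogy converges to that coalescent. The package provides
the whole chain from forward simulation to this convergence diagnosis:

* `partitions` — canonical set partitions, the coagulation operator
  `coagulate()`, paint-box sampling `paintbox_sample()` and exact paint-box
  probabilities;
* `rates` — Λ-coalescent collision rates λ_{n,b} = ∫ p^{b−2}(1−p)^{n−b} Λ(dp)
  (Beta / point-mass / quadrature), finite-support Ξ rate matrices, and a
  continuous-time Λ-coalescent reference simulator with Newick export;
* `population` — one-generation increments, exact (enumerated) and
  Monte-Carlo transition matrices, `simulate_genealogy()`, and the
  with/without-replacement comparison `ac_awf_discrepancy()` (the two laws
  differ by O(E[1/Σξ]) in operator norm, so AC models inherit AWF limits);
* `criteria` — size-biased reordering, the moment functionals
  φ(b₁,…,bⱼ) = lim E[∏ sᵢ^{bᵢ−1} ∏(1−Sᵢ)]/c_N whose existence characterizes
  convergence, the Λ-limit moment-ratio criterion
  E[η₁ᵇ]/c_N → λ_{b,b}/λ_{2,2}, the Kingman criterion, and an empirical
  harness comparing P(π̃)/c_N with candidate rates;
* `models` — the model zoo: generalized **Eldon–Wakeley** sweeps (one parent
  replaces a random fraction Y of the population, Y ~ y⁻²Λ(dy) truncated),
  **recurrent bottlenecks** (rare generations descend from k individuals;
  limit rates are F(k)-weighted paint-boxes), **Poisson–Dirichlet power
  frequencies** ηᵢ ∝ Ṽᵢ^γ from PD(α,θ) stick breaking, and the
  **(N,β,κ) exponential model**, a branching-selection particle system whose
  family frequencies reduce exactly to the PD power family with
  (α,θ,γ) = (1/β, 0, κ/β);
* `io` — YAML-configured runs, JSON-lines traces, Newick trees, summary
  TSVs, deterministic seed streams, and a thin CLI (`inst/cli/asymcoal.R`).

## Worked example

An Eldon–Wakeley population of size N = 500 in which the sweeping fraction Y
follows the truncated uniform measure (Λ = Beta(1,1), the Bolthausen–Sznitman
attractor):

```r
library(asymcoal)
set.seed(42)
ew <- eldon_wakeley_model(lambda_beta(1, 1), epsilon = 0.5, N = 500)

pair_coalescence_probability(ew, reps = 2000)
#> c_N = 0.2106 (se 0.0046)

tr <- simulate_genealogy(ew, n = 8)
tr
#> genealogy trace: n = 8, 4 coagulation events, time scale 'generations'
#>   final state: 1,2,3,4,5,6,7,8  (MRCA reached)
trace_to_newick(tr)
#> (1:6,(2:3,((3:1,4:1,5:1,7:1):1,6:2):1,8:3):3);

ac_awf_discrepancy(ew, n = 3, reps = 1000)[c("norm", "ratio")]
#> ||P_ac - P_awf|| = 0.00736   c_N/E[1/Sigma] = 108
```

The pair-coalescence probability is large (multiple mergers: a single draw
of Y ≈ 0.65 merges 42% of sampled pairs), the eight-leaf genealogy finds its
most recent common ancestor in six generations with a simultaneous
four-way merger, and the sampling-with/without-replacement discrepancy is two
orders of magnitude below c_N — the regime in which AC and AWF genealogies
share their limit.

The convergence diagnosis toward the Bolthausen–Sznitman coalescent
(λ_{b,b}/λ_{2,2} = 1/(b−1)):

```r
m <- as_frequency_model(eldon_wakeley_model(lambda_beta(1, 1), 0.5,
                                            N = 10000, big_first = TRUE))
lambda_criterion(m, b_max = 4, lambda_beta(1, 1), reps = 4000)$table
#>   b estimate    se target       z
#> 1 2    0.999 0.000  1.000 -33.886
#> 2 3    0.555 0.008  0.500   6.788
#> 3 4    0.374 0.010  0.333   4.019
```

The ratios land on the finite-N values of the truncated measure (at cutoff
t = N^{−1/4} = 0.1 the third-moment ratio is (1+t)/2 = 0.55) and approach
the Bolthausen–Sznitman targets as N grows; the z-scores make the remaining
finite-size deviation visible rather than hiding it.

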