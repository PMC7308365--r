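# nichesim

Stochastic spatial simulation of metapopulations that construct their own
niche on an ephemeral landscape, together with the matching mean-field
theory and the experiment harness to study the model's phase behavior.

## The problem

Classic metapopulation theory hands the landscape to the population for
free: patches are destroyed and renewed by external rates, and persistence
is a property of that given habitat. Many real systems — siderophore- or
enzyme-secreting microbes, ecosystem engineers — instead *build* the habitat
they need, and pay for it. `nichesim` is for theoretical/spatial ecologists
who want to ask: when a population is the sole generator of its own niche,
how does the spatial scale of niche construction set persistence,
resilience, range expansion, and vulnerability to exploitation?

## The model

An `L x L` periodic lattice; each site is destroyed (`-1`), vacant (`0`),
occupied by a niche constructor (`1`), or by an exploiter (`2`). Reactions in
continuous time:

| reaction | rate |
|---|---|
| occupied → vacant (extinction) | δ |
| any non-destroyed → destroyed (destruction) | e |
| vacant → constructor (colonization) | (1−c)^α · n₊(Z\*) / \|Z\*\| |
| vacant → exploiter (colonization) | n₊₊(Z\*) / \|Z\*\| |
| destroyed → vacant (construction, NC only) | c · n₊(Z) / \|Z\| |

Z\* and Z are Hamming balls of range r\* (colonization, default 1 — four
nearest neighbors) and r (construction), with |Z| = 2r(r+1); construction
can also be global. The allocation c to construction is paid as the
colonization discount (1−c)^α. With c = e = 0 the model is the 2D contact
process (δ_c ≈ 0.6065). The mean-field reduction

    dp₋/dt = e(1 − p₋) − c p₊ p₋
    dp₊/dt = (1−c)^α p₊ (1 − p₊ − p₋) − p₊(δ + e)

has, besides the absorbing state, up to two interior equilibria (a
saddle-node / discontinuous extinction transition at e_crit(c)); with
c = e = 0 it is the Levins equation with equilibrium 1 − δ.

## Worked example

Simulate a constructor strategy near the extinction threshold, measure its
long-run occupancy and spatial structure, and compare with the mean field:

```r
library(nichesim)

p <- model_params(delta = 0.1, e = 0.045, c = 0.25, alpha = 1)
run <- run_ips(p, init_full(128), t_max = 1500, seed = 42)
run
#> <ips_run> {a=1, d=0.1, c=0.25, e=0.045}  t_max=1500  final p+: 0.2167  p++: 0.0000  p-: 0.6266

mean_occupancy(run, t_from = 1000)
#>   p_minus  p_vacant      p_nc      p_ex
#> 0.6243809 0.1557634 0.2198557 0.0000000

connected_clusters(run$final_grid)
#> <cluster_stats> 572 cluster(s), largest fraction 0.028

mf_ecrit(0.25, delta = 0.1, alpha = 1)
#> [1] 0.06899042
```

The population persists at ⟨p₊⟩ ≈ 0.22 while nearly two thirds of the
landscape is destroyed, fragmented into hundreds of small clusters — the
self-organized mosaic typical of the threshold region. This run sits close
to the *spatial* model's extinction threshold even though the mean field
would allow destruction rates up to e_crit(0.25) ≈ 0.069: crowding makes
the lattice model strictly less persistent than its mean field, a gap the
experiment harness quantifies. The allocation that persists in the broadest
range of landscapes:

```r
mf_cstar(delta = 0.1, alpha = 1)
#> $c_star
#> [1] 0.434
#> $e_crit
#> [1] 0.0816
```

Experiment-level functions: `sweep_phase_diagram()` (occupancy over a
{c, e} grid), `estimate_critical_point()` (survival-probability bisection),
`fit_order_parameter_exponent()`, `relaxation_profile()`,
`range_expansion()`, `classify_regime()` (constructor/exploiter competition
outcomes), `transect()` (1D space-time sections). A thin CLI wraps them:

```sh
exec/nichesim simulate --config cfg.yaml --seed 7 --out results/
```

## Acceptance script

`scripts/acceptance.R` recomputes the model's benchmark quantities from
scratch with the installed package: the mean-field contact-process
extinction threshold, the lattice contact-process critical point by
survival bisection (128 x 128, t_max = 2000), the order-parameter exponent
from an 8-point log-log fit below the (refined) critical point, and the
mean-field optimal construction allocation at δ = 0.1, α = 1. Run it from
the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (and the problem size `n`)
per quantity.
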