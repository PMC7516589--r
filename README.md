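# bistable

Tools for modeling **irrational human decision making** as the disagreement
between two cognitive systems: a fast intuitive process (System 1) and a
slow deliberative one (System 2). The package is aimed at computational
cognitive scientists and quantum-cognition researchers who want to
simulate, analyse, and stress-test "two minds" decision models rather than
fit behavioural datasets.

## The model

A binary decision (outcomes A/B) is governed by a *bistable parameter*
`k ∈ [0, 1]` — System 1's propensity to choose A — and a rational
probability `p ∈ [0, 1]` — the chance that System 2 lets that choice stand
instead of overriding it. The final probability of A is the bistable map

    P_k(+) = 1 − p − k + 2kp        P_k(−) = p + k − 2kp

with `k = 1` fully rational (`P = p`), `k = 0` fully inverting
(`P = 1 − p`), and `k = 0.5` maximal ambivalence (`P = 1/2` regardless of
`p`). The map is equivalent to the expectation of an unsharp quantum
measurement: the POVM pair `P±n̂ = (1−k) I ± (2k−1) π±n̂` on the Bloch
sphere, with noise parameter `η = 2k − 1`. On top of this the package
provides:

* **core** — the scalar map, its inversion, regime classification
  (`pk_plus`, `invert_map`, `classify_regime`, `eta_from_k`);
* **povm** — Pauli algebra, sharp/unsharp/bistable projections, decision
  states, expectations, POVM validation;
* **causality** — perceived independence under bistability
  (`factorization_gap`, `independence_verdict`) and causal strength ΔP /
  causal power κ in closed form and by literal operator products;
* **polytope** — Boole's conditions, the accessible-information polytope
  in `(P1, P2, P12)`, exact hull volumes, and the pure irrational
  information volume `Δ(k) = V(k) − V(1)`;
* **bell_wigner** — three-event Boole ("Bell–Wigner") inequalities,
  bistable attenuation, and violation sweeps over `(k1, k2, k3)`;
* **agent_sim** — a seeded Monte Carlo simulator of the two-system agent
  with parameter recovery;
* **cli** — a command-line front end over all of the above.

## Worked example

The classic conjunction-fallacy ("Linda") question — bank teller vs. bank
teller *and* feminist. Intuition favors the simpler option (`k = 0.8`) and
a rationally concurring System 2 is likely to let it stand (`p = 0.9`):

```r
library(bistable)

pk_plus(0.8, 0.9)
#> [1] 0.74
```

A 0.74 probability of the rational choice. With background text priming
the representativeness heuristic (`k = 0.3`) and a skeptical System 2
(`p = 0.2`), `pk_plus(0.3, 0.2)` gives 0.62. The same numbers come out of
the operator route:

```r
expectation(state_from_p(0.9), bistable_projection(0.8, "z", "+"))
#> [1] 0.74
```

How much extra probability space does irrationality open up? The
accessible-information polytope grows as `k` falls:

```r
piiv_curve(seq(0.5, 1, 0.1))
#>     k n_vertices    volume       piiv
#> 1 0.5          8 0.5000000 0.33333333
#> 2 0.6          8 0.4333333 0.26666667
#> 3 0.7          8 0.3666667 0.20000000
#> 4 0.8          8 0.3000000 0.13333333
#> 5 0.9          8 0.2333333 0.06666667
#> 6 1.0          4 0.1666667 0.00000000
```

`volume` is the exact polytope volume at each `k` (1/6 is the rational
Boole tetrahedron, 1/2 the ambivalent box) and `piiv` the excess over the
rational volume. Simulation and recovery:

```r
sim <- simulate_agent(0.8, 0.9, 1e5, seed = 7)
sim
#> Bistable agent simulation: k=0.8 p=0.9 n=100000 seed=7
#>   freq(A) = 0.741920 (expected 0.740000)
estimate_k(sim$freq_A, 0.9, n_trials = 1e5)$k_hat
#> [1] 0.8024
```

The observed frequency sits within sampling error of 0.74 and the
inverted estimate recovers `k = 0.8` to ±3 standard errors.

From a shell:

```sh
Rscript inst/cli/bistable.R prob --k 0.8 --p 0.9
# {"k":0.8,"p":0.9,"p_plus":0.74,"p_minus":0.26,"regime":"partially-irrational","eta":0.6}
```

See `vignettes/bistable-probabilities.Rmd` for the full account of the
model, the operator conventions, the polytope geometry, and the
attenuation schemes for Bell–Wigner sweeps.

## Acceptance script

`scripts/acceptance.R` recomputes the headline worked-example quantities
from scratch with the installed package — the two Linda decision
probabilities and the constant ambivalence value verified over a 101-point
`p` grid — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
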