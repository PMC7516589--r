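---
title: "Bistable probabilities: models, operators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistable probabilities: models, operators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistable)
```

## The model

Dual-process psychology describes human decisions as the interplay of a
fast, intuitive System 1 and a slow, deliberative System 2. `bistable`
models a binary decision (outcomes A/B) by two probabilities:

* `k` in [0, 1] — System 1's propensity to choose A (the *bistable
  parameter*, quantifying the disagreement between the two systems);
* `p` in [0, 1] — the probability that System 2 lets System 1's choice
  stand rather than overriding it.

The final probability of choosing A is the bistable map

$$P_k(+) = 1 - p - k + 2kp, \qquad P_k(-) = p + k - 2kp .$$

At `k = 1` the decision is fully rational (`P = p`); at `k = 0` it is the
converse of the rational judgement (`P = 1 - p`); at `k = 0.5` the agent
is caught between two minds and the decision is a fair coin whatever
System 2 does. The map is affine in `p` with slope `2k - 1` and symmetric
in `(k, p)` — a single outcome frequency can never identify both
parameters, which is why `estimate_k()` requires `p` to be known and the
package deliberately offers no joint fit.

```{r}
pk_plus(0.8, 0.9)   # intuition favors the simple option, System 2 concurs
pk_plus(0.3, 0.2)   # representativeness-driven intuition, skeptical System 2
```

The conjunction-fallacy ("Linda") examples above evaluate to 0.74 and
0.62. A third textbook variant of that example (`k = 0.3`, `p = 0.7`,
option B) is sometimes quoted as 0.62, but `pk_minus(0.3, 0.7)` is 0.58;
we treat the quoted figure as an erratum and do not test against it.

### Numerical boundary convention

The affine formula evaluated in floating point misses the definitional
identities by one ulp (e.g. `1 - p - 0.5 + p` is not bitwise `0.5`).
Because the boundary regimes are definitions rather than estimates,
`pk_plus()`/`pk_minus()` return the exact identity values whenever `k` or
`p` is exactly 0, 0.5 or 1, and use the formula elsewhere. Inputs may
stray outside [0, 1] by at most 1e-12 (they are snapped to the boundary);
anything further is an error, and `invert_map()` likewise refuses — rather
than clips — algebraic solutions outside [0, 1], surfacing model misfit.
Regime classification (`classify_regime()`) uses exact comparison with the
supplied value: no tolerance band exists around `k = 1`, `0.5` or `0`.

## The operator formalism

The same map arises as a quantum expectation value. With the Pauli vector
$\sigma$ and a Bloch direction $\hat n(\vartheta,\varphi)$, the sharp
projectors are $\pi_{\pm\hat n} = \tfrac12(I \pm \sigma\!\cdot\!\hat n)$
and the *bistable projections* are

$$P_{\pm\hat n} = (1-k)\,I + (2k-1)\,\pi_{\pm\hat n},$$

an unsharp POVM with noise parameter $\eta = 2k-1$ extended to
$[-1, 1]$: eigenvalues $\{k, 1-k\}$ in every direction, completing to the
identity, reducing to projective measurement at `k = 1` and to $I/2$ at
`k = 0.5`.

**Amplitude convention (the one consequential gap-fill).** The rational
state is written in the literature as $|\psi\rangle = (p, 1-p)^T$, but the
bilinear form of that literal vector gives $kp^2 + (1-k)(1-p)^2$, which
does not reproduce the bistable map. The map *is* reproduced when the
squared magnitudes of the components equal $(p, 1-p)$, so `state_from_p()`
builds $(\sqrt p, \sqrt{1-p})$ with real nonnegative amplitudes (a real
Hilbert space carries the original probability). The notation is read as
labeling the encoded probabilities. Users comparing against the printed
vector form should be aware of this.

```{r}
expectation(state_from_p(0.9), bistable_projection(0.8, "z", "+"))
```

All matrix-identity checks in the package use a tolerance of 1e-10 on the
maximum absolute entry difference; state norms are checked to 1e-12.

## Causality under bistability

A bistable observer perceives every probability through
$f_k(x) = 1 - x - k + 2kx$, so the independence test they can run is
`factorization_gap()`: $f_k(p_{YZ}) - f_k(p_Y)f_k(p_Z)$. For truly
independent variables this vanishes only at `k = 1` — irrationality
manufactures spurious dependence. `independence_verdict()` classifies the
four possible situations (independent, spuriously-causal, causal,
causality-masked) by comparing the perceived gap against the rational one;
the fourth label ("causal", faithful perception of a real dependence) is
ours, added because a dependent pair viewed rationally fits none of the
other three. The default independence tolerance is 1e-9 on the gap.

For the strength of a perceived cause we provide both measures in two
routes:

* `strength_bistable_closed()` — the closed forms
  $\Delta P_k = k + p - 1$ and $\kappa = (k+p-1)/((1-p)(1-k))$, taken
  verbatim (their conditioning events are not defined operationally, so no
  derivation is imputed; $\kappa$ is undefined at `k = 1` or `p = 1`).
* `strength_bistable_matrix()` — the canonical operator route: X measured
  along `z`, Y along `x`, both at bistability `k`, and
  $\Delta P_k = \langle P^Y_k(+)P^X_k(+)\rangle -
  \langle P^Y_k(+)P^X_k(-)\rangle$ evaluated as literal matrix products.
  This equals $(2k-1)(2p-1)/2$ and vanishes identically at `k = 0.5`:
  maximal ambivalence destroys any cause–effect attribution.

The published closed form for the operator route,
$\tfrac12(1-k-p+2kp)$, gives 1/4 at `k = 0.5` and therefore contradicts
the vanishing-at-ambivalence property that motivates it. We take the
literal operator computation as canonical; `as_printed = TRUE` exposes the
published forms with a warning, for comparison only.
`conditional = TRUE` normalises the correlators by the probability of the
conditioning outcome; the default subtracts joint expectations, matching
the printed derivation.

## Accessible-information polytopes and the PIIV

Boole's conditions for two events and their conjunction carve out a
polytope in $(P_1, P_2, P_{12})$: the tetrahedron with vertices
$(0,0,0), (0,1,0), (1,0,0), (1,1,1)$, volume 1/6. Under bistability the
constraints deform to

$$(2k-1)P_i - P_{12} \ge k-1, \qquad (2k-1)(P_1+P_2) - P_{12} \le 2k-1,$$

plus the base constraints $0 \le P_1, P_2 \le 1$, $P_{12} \ge 0$. The
base constraints are an interpretation we adopt: the deformed
inequalities alone leave the region unbounded, and letting the marginals
range over [0, 1] is the choice forced by the known `k = 0.5` limit
(where $P_{12}$ decouples, $0 \le P_{12} \le 1/2$, a box of volume 1/2).
One rendering of the fourth two-event Boole condition carries a flipped
inequality sign (`>= 1`); we implement the standard `<= 1` direction,
consistent with the three-event conditions.

`bistable_polytope()` computes vertices by exact half-space intersection
(all plane triples, feasibility within 1e-9, tolerance dedup) and the
volume by fan triangulation of the hull faces — deterministic, no Monte
Carlo. A seeded rejection-sampling oracle exists only in the test suite,
where it confirms the exact volumes within 3 binomial standard errors at
$10^6$ points. No qhull binding is available in the supported
environment, and with at most eight half-spaces the $\binom{8}{3}$
enumeration is exact and instantaneous. `k < 0.5` is handled by the same
machinery (the inequalities flip orientation naturally) but is outside
the range we validate.

The *pure irrational information volume* is
$\Delta(k) = V(k) - V(1)$, computed by `piiv()` as a numeric volume
difference. A closed algebraic form for $\Delta(k)$ circulates but is
garbled in our source material and does not match the numeric volumes
under any parsing we tried, so the package exposes no closed form: the
geometry is authoritative.

```{r}
piiv_curve(seq(0.5, 1, 0.1))
```

$\Delta$ decreases strictly to 0 at `k = 1`: irrationality widens the
space of entertainable probability assignments. One geometric subtlety:
the growth is *not* nested. At $P_1 = P_2 = 1$ the deformed constraints
cap $P_{12}$ at `k`, so the rational tetrahedron's apex $(1,1,1)$ lies
outside every `k < 1` region — the bistable region is larger in volume
while clipping extreme conjunctions. Claims that the rational polytope is
contained in the bistable one are false at that apex, and our tests
assert the true geometry.

## Bell–Wigner inequalities and attenuation

For three events, Boole's conditions of possible experience comprise the
range bounds $0 \le p_i \le 1$, $0 \le p_{ij} \le \min(p_i, p_j)$, the
union bounds $p_i + p_j - p_{ij} \le 1$ and
$p_1+p_2+p_3-p_{12}-p_{13}-p_{23} \le 1$, and three triangle conditions
such as $p_1 - p_{12} - p_{13} + p_{23} \ge 0$. Their region is the
Bell–Wigner polytope; any assignment built from a genuine joint
distribution (`assignment_from_joint()`) satisfies all of them, and a
breach certifies that no classical joint exists — quantum-like behaviour.

`bw_attenuate()` applies per-event bistable parameters
$(k_1, k_2, k_3)$. The marginals are unambiguous
($p_i \mapsto f_{k_i}(p_i)$); how the pairwise joints transform is not
specified by the narrative we model, so both defensible readings are
implemented:

* **sequential composition** (default):
  $p_{ij} \mapsto f_{k_i}(f_{k_j}(p_{ij}))$ — each event's bistability
  acts once on the conjunction; the composition is commutative.
* **marginals only** (`marginals_only = TRUE`): joints untouched — the
  literal reading of "attenuate the probabilities $p_1, p_2, p_3$".

Neither is claimed to be the historically intended scheme. A fact we
established while testing decides which one can exhibit violations where:
writing $e_i = 2k_i - 1$, every attenuated inequality value under
sequential composition is multilinear in $(e_1, e_2, e_3)$, and each
vertex of the box $e \in [0,1]^3$ evaluates it to a classically
realizable (hence nonnegative-slack) expression. A multilinear function
attains its extrema at box vertices, so **for $k_i \in [0.5, 1]$ the
composition scheme can never violate any inequality on a realizable
base**. Violations under composition require an inverting event
(`k < 0.5`; witness `k = (0, 0, 1)` on the independent fixture, triangle
value −0.71), whereas the marginals-only scheme violates freely inside
$[0.5, 1]^3$ (value $f_{k_1}(0.9) - 0.81$ for the fixture). Violation
sweeps restricted to $[0.5, 1]^3$ therefore use `marginals_only = TRUE`.

The base assignment for sweeps is not dictated by the source material; the
documented fixture `bw_independent_fixture(0.9)` (three independent events
of probability 0.9) is recorded in sweep output and the CLI metadata.
Violation tolerance is 1e-12; the $\min$ in the pairwise upper bound is
evaluated per pair with no tie-breaking subtleties.

## The synthetic agent

`simulate_agent(k, p, n_trials, seed)` draws the two-coin process
literally: per trial, System 1 chooses A with probability `k`, then
System 2 flips the choice with probability `1 - p`. "Alter the response"
is implemented as a deterministic flip — the only reading whose final-A
probability is $1-p-k+2kp$. No temporal ordering is modelled (the
framework is agnostic to the order of the two systems). The generator
emulates ideal i.i.d. trials: no learning, drift, or response-time
structure of real participants, so a green simulation test establishes
distributional correctness of the model, not behavioural realism.

Reproducibility contract: one Mersenne-Twister stream seeded with `seed`;
trial `i` consumes exactly draws `2i - 1` and `2i`. Identical
configurations give byte-identical trial tables, and every randomised
entry point requires an explicit seed.

`estimate_k()` inverts the map at known `p` (delta-method standard error;
out-of-range estimates flagged, never clipped; `p = 0.5` is singular —
the map is constant in `k` there). `recovery_experiment()` wraps
simulate/estimate replicates and reports bias and RMSE; the estimator is
affine in a binomial frequency and hence unbiased, which the tests verify
at 200 replicates of $10^4$ trials.

## Command line

All functionality is reachable from a thin wrapper:

```
Rscript inst/cli/bistable.R prob --k 0.8 --p 0.9
Rscript inst/cli/bistable.R polytope --k-grid 0.5:1.0:0.1 --format csv --out piiv.csv
Rscript inst/cli/bistable.R bellwigner --grid 0.5:1.0:0.1 --marginals-only --out sweep.csv
Rscript inst/cli/bistable.R simulate --k 0.8 --p 0.9 --n 100000 --seed 7
```

Configs are flat JSON documents with a `"subcommand"` key (flags
override); unknown keys are rejected by name; CSV output carries 17
significant digits so reruns are byte-identical. JSON was chosen over
YAML because no YAML parser is available in the supported R environment.

## Known limitations

* Two-dimensional Hilbert space only; no mixed states, no dynamics of
  the System 1/System 2 interaction, no joint estimation of `(k, p)`
  (provably non-identifiable), no causal structure learning.
* The exact attenuation rule for pairwise joints and the base
  probabilities behind published three-parameter violation surfaces are
  unspecified; those surfaces are reproduced qualitatively (existence and
  location of violations), not numerically.
* `piiv()` is validated on `k` in `[0.5, 1]`; below 0.5 the half-space
  machinery still works but no external reference constrains it.
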