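---
title: "Methods: pathogen evolution in an age-structured SIRS population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathogen evolution in an age-structured SIRS population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesirs)
```

## The model and its assumptions

`agesirs` studies the long-run evolution of a pathogen phenotype in a
host population subdivided into `n` discrete age stages. The
epidemiological substrate is a susceptible–infected–recovered–susceptible
(SIRS) system: stage `i` hosts recover at rate `γ_i`, lose immunity at an
age-invariant rate `ω`, die of background causes at rate `δ_i` and of
disease at rate `d_i`, and age into the next stage at rate `a_i`. The
model makes five structural assumptions:

1. **Constant total population.** Every death (background or disease)
   is balanced by a birth into the first susceptible compartment; there is
   no vertical transmission of either infection or immunity. Densities
   are normalized to total 1, which makes the endemic relation
   `S* = 1/R0` dimensionless.
2. **Terminal stage closed above.** The last stage does not age out
   (`a_n = 0`); its only exits are deaths. This keeps the stationary age
   profile well defined and the birth accounting exact.
3. **Transmission separates host and source.** The infection rate from
   stage `j` into stage `i` is `β_ij = c_ij · β(γ_j)`: a contact
   modulation times an infectivity that depends only on the *infected*
   individual's stage (shedding is a property of the infection, not of
   the contactee). By default `c_ij = x_i y_j`, a rank-1 structure; a
   general nonnegative contact matrix is also supported.
4. **Total cross-immunity between strains.** In the two-strain extension,
   resident and mutant compete for one susceptible pool and recovery from
   either protects against both. Partial cross-immunity is out of scope.
5. **Shared life history except recovery.** Resident and mutant share
   `a_i`, `δ_i`, `d_i` and `ω`; a mutant is a recovery-rate vector
   `γ̃`, with its infectivity induced by the shared trade-off.

All rates are per day by default; nothing in the code pins the time
unit, so any consistent choice works.

The two-strain system as printed for stages `i ≥ 2` leaves the stage-1
susceptible equation implicit; the package closes it by extending the
single-strain birth term with the mutant branch's deaths
(`d_i Ĩ_i`, `δ_i Ĩ_i`, `δ_i R̃_i`), the unique choice consistent with a
constant population. Conservation (all compartment derivatives summing to
zero in exact arithmetic) is enforced by construction and
property-tested for both right-hand sides.

## Reproduction and invasion numbers

Linearizing the infected subsystem at an equilibrium with susceptible
profile `S` gives `dI/dt = (T + Σ) I` with `T_ij = β_ij S_i` and `Σ`
lower bidiagonal (diagonal `−μ_i`, `μ_i = a_i + δ_i + γ_i + d_i`;
subdiagonal `a_i`). The next-generation matrix is `K = −TΣ⁻¹`, and `Σ⁻¹`
has a closed form: `(−Σ⁻¹)_{ji} = (a_i ⋯ a_{j−1})/(μ_i ⋯ μ_j)` for
`j ≥ i`. Two evaluations of the spectral radius are implemented:

* **trace**: when `c_ij = x_i y_j`, `T` and hence `K` have rank 1, so the
  trace — a double sum over infection paths `i ≤ j` — equals the unique
  positive eigenvalue. This is the closed form `r0(..., method =
  "trace")` evaluates.
* **eigen**: the dominant eigenvalue of the dense `K`, valid for any
  contact structure. `n` is small in all intended uses, so no iterative
  eigensolvers are involved.

Requesting the trace for a non-separable matrix is refused with an
error rather than silently returning a wrong number, and the test suite
keeps a counterexample demonstrating that trace ≠ spectral radius for
full-rank `T`. Evaluated at the disease-free profile `Ŝ` the spectral
radius is R0; evaluated at a resident's endemic profile `S*` with the
mutant's `γ̃` in both `β` and `μ̃` it is the invasion number Q0. A clone
of the resident is exactly neutral (`Q0 = 1`), which the package exploits
as a stringent end-to-end consistency check of the equilibrium solver and
the NGM code together.

## Endemic equilibria

Per-stage endemic states are obtained dynamically: integrate from the
disease-free profile seeded with a 0.1% infection until the right-hand
side is small, then polish with damped Newton iterations in which the
redundant stage-1 birth equation is replaced by the conservation
constraint (the RHS Jacobian is singular along the simplex direction).
The polish typically drives the residual max-norm to ~1e-15, which in
turn pins self-invasion neutrality to ~1e-11. Integration uses
`deSolve::lsoda` with `rtol = 1e-9`, `atol = 1e-12`; convergence is
declared below an RHS max-norm of `1e-10`, with a 1e6-day ceiling.
Warm starts from a previous equilibrium (used heavily by the
evolutionary loop, where each fixation only moves `γ` by a few percent)
make the recomputation cheap.

The aggregate closed form (`aggregate_endemic()`) implements the low-CFR
totals `S* = 1/R0`, `I* = δ̄(1 − 1/R0)/(γ̄ + δ̄ − ωγ̄/(ω + δ̄))`,
`R* = γ̄I*/(ω + δ̄)`. The population-level `γ̄`, `δ̄` are averaged with
the *disease-free* stationary age profile as weights — a deliberate
choice, since that profile is the only age structure defined
independently of the endemic state itself. The form is exact for one
stage with `d = 0` and approximate otherwise; in the high-CFR sensitivity
mode it is flagged unreliable and everything goes through integration.

## The trade-off and the ESS

Evolution is driven by a trade-off `β(γ)`: infectivity increasing in the
recovery rate (acuter infections shed more but last shorter). Existence
of an interior optimum requires concavity — otherwise selection runs to
`γ = 0` or `γ = ∞`, the "Darwinian demon". The built-in family is the
power law `β = c γ^p`, concave for `0 < p < 1`; custom `β`, `β′` pairs
are accepted and checked for concavity numerically on a grid (violations
warn rather than fail, so convex counterexamples remain explorable; the
ESS solver, however, rejects `p ≥ 1` outright).

Under the slow-aging approximation (recovery and disease death much
faster than aging), the stages of the invasion gradient decouple and the
per-stage ESS solves

    β′(γ_i*) (a_i + γ_i* + d_i + δ_i) = β(γ_i*),

geometrically the point where a line through `(−(a_i + d_i + δ_i), 0)`
is tangent to the trade-off curve (`tangency_check()` reports the gap
diagnostics). Within-stage contact scalars multiply both sides and
cancel — verified as "rescale contacts by 1e3, the root moves by < 1e-9
relative". The solver (`solve_ess()`) uses bracketed root-finding
(`uniroot`, default bracket `1e-6`–`1e3` per day, tolerance `1e-12`),
chosen over Newton for robustness: under concavity the residual has a
single sign change, and the solver counts sign changes on a log grid and
warns if more than one appears, since uniqueness — unlike existence — is
not guaranteed in general. For the power law the closed form
`γ* = p m/(1 − p)`, `m = a + d + δ`, is exposed separately and serves as
the solver's cross-check.

The solver treats stages independently, matching the slow-aging
derivation; the neglected cross-stage aging terms are *assessed* (via the
full numerically differentiated Q0 gradient) but never solved for. The
gradient uses central differences with relative step `1e-5` — Q0 is
smooth in `γ̃` and the differences of an NGM eigenvalue at that step are
far above cancellation noise. `verify_ess_by_invasion()` closes the
loop dynamically: a battery of stage-wise (factors 0.25–4) and 50 joint
random probe mutants, none of which may exceed `Q0 = 1` beyond a
tolerance that scales with `max_i a_i/(γ_i + d_i)` for `n > 1`.

One subtlety deserves emphasis: whether the ESS is "acute" is itself a
model outcome. With human demographic rates and low CFR,
`m = a + d + δ ~ 1e-4`/day, so the power-law ESS sits at a *chronic*
`γ* ≈ m` — and there the slow-aging decoupling degrades, since `γ*` is
comparable to the aging rates. The decoupling is excellent precisely
when `γ* + d ≫ a`, i.e. when substantial disease mortality (weeks-scale
`d`) keeps the optimum acute. The test suite therefore probes the
gradient bound on a three-stage configuration with
`d = (0.02, 0.03, 0.05)`/day, where `(γ* + d)/a` exceeds 290 in every
stage and the residual gradient at the ESS falls below 5% of its
magnitude at `γ*/2`.

## Evolutionary simulation

`run_evolution()` iterates invasion–replacement: propose a mutant,
score it, replace the resident if it wins, recompute the endemic state,
repeat. Design choices, all package decisions (no external prescription
exists for them):

* **Mutation kernel**: multiplicative log-normal, `γ̃_i = γ_i exp(σz_i)`
  with `σ = 0.1` by default, all stages jointly (optionally one random
  stage per proposal). Multiplicative steps keep rates positive and make
  the kernel scale-free across the many orders of magnitude `γ` spans.
* **Two fixation criteria.** `adaptive_dynamics` fixes iff `Q0 > 1` —
  the fast surrogate. `ode_competition` seeds the mutant at `1e-6` of
  the population (taken proportionally out of the resident infected
  pools, staying on the constant-population simplex) and integrates the
  two-strain system until the mutant's share of infections exceeds 0.99
  (fixation), its density falls below `1e-9` (extinction), or `5e4` days
  elapse (timeout, resident retained). The two criteria agree except in
  a narrow band around `Q0 = 1`, where the mutant's growth time
  `~ 1/((Q0 − 1)(γ + δ))` exceeds any finite horizon — the test suite
  asserts agreement outside that band rather than pretending the ODE can
  resolve near-neutrality.
* **Determinism**: one seeded generator per run (the kernel's `seed`),
  recorded in the trajectory attributes; identical configurations
  reproduce trajectories bit for bit.

For rank-1 transmission at one stage, fixation (`Q0 > 1`) is equivalent
to an increase of `β(γ)/(γ + m)` and hence of R0, so the resident's R0
is nondecreasing across fixations and the phenotype approaches `γ*`
monotonically; the simulation also exhibits the characteristic
adaptive-dynamics slow-down, with the fixation rate falling as the
resident nears the optimum (selection becomes second order there).

Two sensitivity modes break the structural assumptions:

* **Random contacts** (`sensitivity_random_contacts()`): `c_ij`
  replaced by seeded Uniform(0,1) draws; the matrix is generically full
  rank, all reproduction numbers switch to the eigenvalue method. For
  non-separable mixing, `Q0 > 1` at the endemic state *provably does
  not* imply an R0 increase — R0 ranks strains at the disease-free
  profile, Q0 at the endemic one, and the two orderings can disagree.
  Accordingly, the acceptance checks for this mode assert the direction
  of evolution (net R0 growth over the run, a majority of R0-raising
  fixations, overall approach of `γ` to the ESS), not per-fixation
  monotonicity, which the model genuinely violates at the `1e-3`–`1e-1`
  scale. The random-contacts evolutionary scenario uses trade-off
  coefficient 4: the Uniform(0,1) entries reduce mean transmission
  roughly fourfold relative to the outer-product weights, and by the
  contact-cancellation result the scale does not move the ESS, so this
  choice only keeps the probe residents (at `4γ*` and `γ*/4`)
  supercritical.
* **High CFR** (`sensitivity_high_cfr()`): `d_i = 10 δ_i ×` multiplier,
  putting disease mortality far above background. The ESS machinery is
  unaffected (`d` simply enters `m`); the aggregate closed form is not
  to be trusted there, and the predicted optimum shifts to larger `γ*`.

## Synthetic scenarios: what they emulate, and what not

All test inputs come from `generate_scenario()`; there are no external
data. `single_stage` is the textbook scalar SIRS (transmission such that
R0 ≈ 3.6, ten-day infection, hundred-day life expectancy at `δ = 0.01`,
fifty-day immunity). `three_stage_human` sketches a human age pyramid —
20-year young and 45-year adult stages and an open-ended old stage with
15-year remaining life expectancy, mortality rising two orders of
magnitude across stages, a week-long infection, low CFR.
`slow_aging_n` scales the same construction to `n` equal stages.
The templates emulate the *structure* of human demography — stage
ordering of mortality, slow aging relative to recovery, separable
contacts as a first approximation — but none of its texture: no
seasonality, no household or school contact structure, no immune
waning heterogeneity, no stochasticity (the ODE model cannot lose a
rare mutant by drift, which is why neutral clones sit at their seeding
share forever instead of fixing or dying). Passing tests therefore
certify the mathematics of the framework, not the realism of any
particular parameterization.

Problem sizes were chosen to keep the full test suite in seconds on a
single core while still exercising every regime: randomized NGM checks
at `n ≤ 8`, equilibrium/neutrality checks at `n ∈ {1, 2, 3, 5}`,
evolutionary runs of 300 attempts (a few dozen fixations), competition
probes at the scalar model. The evolutionary trajectories approach
`γ*` closely but — like any adaptive-dynamics run with a fixed kernel —
never exactly reach it; the acceptance checks require a final relative
distance under 0.25 from a 4-fold displaced start.

## Degenerate inputs and numerical guards

`n = 1` collapses all stage sums (`a_1 = 0`; every closed form remains
valid and is tested). Zero-exit stages (`a_k + δ_k = 0`) are rejected
when the stationary age profile is requested; `μ_i = 0` is rejected in
the transition matrix; subcritical residents (R0 ≤ 1) return the
disease-free state with a flag instead of a spurious endemic one, and
invasion analysis against them errors. Integrator output is screened
for negativity beyond `1e-8` of the population (tolerated round-off is
clipped at chunk boundaries). The epidemic-threshold locator classifies
runs dynamically (terminal infected density above `1e-8` after `4e5`
days) and bisects the contact scale; critical slowing-down limits its
resolution to a few times `1e-4` in R0, well inside the `1e-3` band it
is asked to certify.

## Known limitations

* Total cross-immunity only; no coexistence or branching analysis. The
  trajectory records would support a pairwise-invasibility treatment,
  but the package does not classify singular strategies beyond the
  Q0-probe check.
* The per-stage ESS is exact only in the slow-aging limit; for chronic
  optima (`γ* ~ a`) the decoupled condition is a first approximation
  and the full-gradient diagnostic should be consulted.
* Deterministic ODEs throughout: no demographic noise, so invasion is
  decided by sign(Q0 − 1) rather than by a fixation probability.
* The aggregate closed-form equilibrium degrades with rising CFR and
  with strong age heterogeneity; it is a diagnostic, not a substitute
  for the integrated per-stage state.
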