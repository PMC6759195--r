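---
title: "From 13C labeling data to a kinetic model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 13C labeling data to a kinetic model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kfitr implements a two-step pipeline for building mechanistic kinetic models
of metabolic networks from isotope labeling data. Step one estimates
intracellular fluxes by 13C metabolic flux analysis (13C-MFA) on an
atom-mapped network; step two fits an elementary-step kinetic model of the
same network to the per-strain flux distributions, anchored exactly to the
wild-type state. This vignette records the models, the numerical choices, and
the reasoning behind the design decisions, in the spirit of a methods
appendix. Everything stated here about behavior is exercised by the test
suite; no empirical claim is made beyond what the tests and the acceptance
script compute.

## The flux-elucidation model (13C-MFA)

A `metabolic_model` carries stoichiometry, per-reaction atom mappings in the
lowercase-letter convention (`A(ab) + B(c) -> C(abc)` becomes three rows with
atom strings `ab`, `c`, `abc`), substrate-level regulations, and
binding/release orders. Mass-balanced (intracellular) metabolites define the
stoichiometric matrix `S`; extracellular species are labeling sources or
sinks. Symmetric metabolites are represented by duplicate complete mappings
with weight 0.5.

`build_emu_network()` decomposes the network into elementary metabolite units
(EMUs): the minimal subsets of carbon atoms whose labeling state must be
known to predict the measured fragments. Tracing runs backwards from each
fragment through every producing mapped reaction; condensation reactions
contribute convolution nodes. The balances are blocked by EMU size, so each
block is a linear system given all smaller blocks, and `simulate_mids()`
solves the cascade. Two properties pin the implementation down and are
enforced by tests against an independent brute-force oracle
(`simulate_mids_isotopomer()`, which enumerates all 2^n positional
isotopomers and solves the pool equations by fixed-point iteration):
simulated fragment distributions always sum to one, and rescaling all fluxes
by a common factor leaves them unchanged.

Fluxes are parameterized on a null-space basis of `S` (so steady state holds
by construction), with a log-parameterized exchange flux for each reversible
reaction; forward/backward fluxes are `max(v,0)+exch` and `max(-v,0)+exch`.
`fit_fluxes()` minimizes the variance-weighted SSR between simulated and
measured fragment MIDs plus measured rates (uptake normalized to 100 flux
units) by Levenberg-Marquardt from randomly initialized multi-starts. The
best solution is accepted only if at least half of the starts converge to it;
two optima count as the same solution when every net flux agrees within
`max(0.1, 1%)` — the convergence rule needs an equality tolerance and this
one is the coarser of an absolute 0.1 flux units and 1%.

Confidence intervals use the profile method: a flux is pinned at a trial
value (implemented by eliminating one free-flux coordinate, not by penalty,
so the constraint is exact), all remaining parameters are re-optimized, and
the 95% bound is where the profile SSR crosses `SSR* + 3.84`
(`qchisq(0.95, 1)`). Structurally unidentifiable fluxes run to the search
bound and are flagged rather than treated as errors. `project_fluxes()`
transfers interval information between networks by minimizing the total
absolute violation of the supplied intervals subject to steady state on the
target network — a linear program with slack variables, solved with an exact
simplex method.

## The kinetic model and its parameterization

`decompose()` rewrites each enzymatic reaction as an ordered-sequential
mechanism: substrates bind in order, a conversion step releases the first
product, remaining products release in order. A reversible uni-uni reaction
is `E + A = EA = E + P` (2 steps, 4 rate constants, 2 complexes); biomass
precursor sinks are single-substrate uni mechanisms (`E + A = EA = E`).
Dead-end inhibition follows the textbook conventions: competitive inhibitors
bind free enzyme, uncompetitive inhibitors bind the terminal substrate-bound
complex, noncompetitive inhibitors bind both. The decomposition reports its
counting — two elementary constants per main-path step, one inhibitor
constant per inhibitor-binding step (a noncompetitive regulation therefore
contributes two) — so structural counts can be checked against any published
model. Only the dissociation ratio of a dead-end step is constrained by
steady states, which is why the inhibitor constant is reported as `k_f/k_r`.

The fitted variables are the wild-type enzyme-complex fractional abundances
`e` (per enzyme, summing to 1, sampled in (1e-3, 1)) and the reverse
elementary fluxes `v_r` (sampled log-uniformly; bounded above by 1e4).
`anchor_wildtype()` converts them to rate constants exactly: every main-path
step of a reaction carries the reaction's wild-type net flux (forced for
dead-end branches, which carry zero), so the forward flux is `v_net + v_r`,
and with wild-type concentrations defined as 1 the constants follow directly.
This guarantees the wild-type distribution is an exact steady state of every
candidate model — the anchoring identity is tested to 1e-8 and below.

`steady_state()` evaluates a mutant state by iterative decomposition: at
fixed metabolite concentrations each enzyme's complex balance is linear and
solved exactly; concentrations are then updated by a damped Newton step on
the metabolite balances, with the Jacobian obtained analytically by implicit
differentiation through the per-enzyme solves. Two numerical points deserve
emphasis:

* **Conserved moieties.** When several metabolites enter the balances
  identically (the cleavage products of our toy networks are an example), the
  balance system is rank-deficient and the steady state depends on the
  initial condition through a conserved quantity. The solver detects the
  conservation basis from the elementary stoichiometry and anchors the
  conserved quantities at the initial state, exactly as an integrated
  trajectory would conserve them. Without this the root found by Newton is an
  arbitrary point on a solution line.
* **Basins.** Mutant systems can be multistable. Far from any attractor the
  solver first relaxes along the true dynamics (short stiff-ODE segments)
  and only then polishes with Newton, so the reported state is the one the
  trajectory from the given start actually approaches. Inside fitting loops
  this relaxation is disabled (`relax_on_stall = FALSE`, `newton_gate = Inf`):
  there, any exact steady state is acceptable and failed evaluations are
  simply discarded, which is much cheaper. The solver-vs-ODE agreement
  (`steady_state_ode()`, `deSolve::lsoda` over adaptively extended horizons,
  with tolerances scaled so slowly equilibrating high-concentration states
  remain integrable) is enforced to 1e-6 and observed at 1e-8 or better on
  the fixture networks.

Convergence demands `max |dc/dt| < 1e-6` flux units (the solver polishes to
1e-9 by default); concentrations are capped at 1e9 to convert divergence into
a clean unstable verdict. `stability_check()` linearizes the full dynamics
(metabolites and complexes), projects out the conserved subspace (enzyme
totals and moieties), and requires all remaining eigenvalues to have negative
real part; the test suite includes a constructed bistable system where the
verdict is checked against the sign of the analytically computed slope.

The outer estimation (`kfit()`) minimizes the variance-weighted SSR between
predicted and training mutant fluxes over transformed variables (per-enzyme
logits for `e`, shifted logs for `v_r`) by Levenberg-Marquardt with forward
finite differences, warm-starting each strain's steady state from its last
converged state. Weighting SDs follow `max(1.0, 0.05 |v|, SD_MFA)`; training
fluxes are scaled onto the wild-type basis by the ratio of absolute uptakes.
Non-convergent or unstable inner evaluations return a large constant
residual, so the line search backs away from failing regions, and a start is
kept only if every strain's final state converges. On the shipped fixtures
the multistart draws reverse elementary fluxes over the generator's own
(1, 100) range rather than the full admissible (0, 1e4): the admissible
bounds still constrain the optimization, but initializing orders of
magnitude away from any physically sampled reversibility mostly seeds
basins of unstable kinetics, and the recovery rate per start collapses. A second LM round from
each promising optimum resets the damping schedule and finishes off shallow
basins; in our end-to-end recovery runs this polishes SSR from ~1e-4 to
~1e-20. Acceptance requires another local minimum within 10% of the best SSR
and stable states under the supplied validation perturbations; the recovery
rate counts starts whose mean squared flux deviation from the best model is
at most 0.05 per reaction flux.

## Downstream analyses

`king_altman()` derives each reaction's steady-state rate law by enumerating
the spanning trees of the enzyme-complex graph (a multigraph — parallel
edges from distinct steps are kept apart) and orienting each tree toward each
complex in turn; inhibitor complexes are ordinary nodes. The law is
normalized so that the all-substrates denominator term has coefficient 1;
every other distinct denominator term is one Km parameter and the forward
numerator yields Vmax. The tests check the uni-uni and competitive-inhibition
closed forms exactly and random reversible bi-bi mechanisms against a
numeric complex-balance solve to 1e-8.

`sensitivity()` differentiates the weighted residual vector with respect to
every elementary rate constant (central differences, relative step 1e-5,
validated against the closed-form linear-model covariance), forms
`H = J'WJ`, and inverts it on the identifiable subspace (singular values
below 1e-10 of the maximum are null directions; parameters loading on them
are flagged — dead-end inhibitor pairs are the expected example, since only
their ratio is constrained). `CV(%) = 100 SD / value`. The covariance is
computed with respect to the elementary constants `k`, not the optimization
variables; both views exist, and `k` is the one in which Km/Vmax
uncertainties are naturally expressed.

A regulation is dispensable when the one-SD range of its inhibitor constant
reaches zero (`value - SD <= 0`), essential otherwise. Km/Vmax ranges across
the accepted model set are evaluated at concentrations one SD above and one
SD below their means (rescaling the anchored constants from the wild-type
concentration basis to absolute units); the reported range is the min/max
over the models-by-corners grid.

`apply_perturbation()` models an x-fold expression change as an x-fold change
in that reaction's total enzyme (fold 0 is a knockout; all other enzymes stay
at wild type), and `predict_yield()` reports target flux over uptake flux in
the perturbed state, with proxy targets always named explicitly by the user —
the package never guesses a pathway for a product outside the network.

## What the synthetic generator emulates — and what it does not

`make_toy_network()` builds carbon-balanced toy networks with a 3-carbon
substrate, two routes that scramble carbon differently (direct isomerization
versus cleavage to a 2-carbon and a 1-carbon piece followed by reordering
condensation), an optional second branch point with a secretion/storage split
and a biomass-precursor sink, and one regulation of each inhibition mode
placed by a seeded draw. The default fragment panel mixes whole- and
sub-molecule fragments so the route split is identifiable from MIDs of a
substrate labeled at carbon 1. Knockout strains of either route re-route
flux, mimicking upper-glycolysis/pentose-phosphate deletion phenotypes, and
the two cleavage-route knockouts are deliberate phenotypic twins (the analog
of knocking either step of a linear two-step pathway), which is what makes
leave-one-out cross-validation informative.

`sample_ground_truth()` draws a wild-type flux distribution on the null
space (uptake 100, all irreversible fluxes comfortably positive), enzyme
fractions from a flat Dirichlet clipped into (1e-3, 1), and reverse
elementary fluxes log-uniform on (1, 100) — within the broad admissible
bounds but concentrated where reversibilities produce well-conditioned,
stable kinetics, which is what "realistic" means for a fixture; it resamples
until the wild type and all planned knockouts are stable. Datasets carry
multiplicative Gaussian flux noise (truncated at 4 sigma) with the wild-type
anchor kept noise-free, since the anchor must satisfy steady state exactly;
each mutant is re-normalized to its own 100-unit uptake basis and the
absolute uptake is emitted alongside, exactly the shape a flux-elucidation
step would deliver.

What passing on these toys does *not* show: real networks are far larger
(tens of reactions rather than six to nine), real MID measurement error is
correlated and fragment-specific rather than i.i.d. Gaussian, real biomass
composition constraints couple many sinks, and real regulation networks are
dense. The toys exercise every code path — convolution nodes, reversibility,
all three inhibition modes, re-routing knockouts, twin phenotypes,
unidentifiable splits — but they say nothing about wall-clock behavior or
landscape multimodality at the scale of a genome-informed core model, where
published parameterizations report recovery rates below 1%.

## Problem sizes and determinism

The shipped tests and the acceptance script use: a 6-reaction single-branch
toy with 3 knockout strains for end-to-end recovery (20 multi-starts), 25
random stable parameter sets for solver-vs-ODE equivalence, 8 random flux
vectors across both toys for EMU-vs-isotopomer equivalence, and 25-50 noisy
replicates (8 MFA starts each) for the SSR-calibration and CI-coverage
checks. These sizes were chosen as the smallest that exercise the properties
convincingly; every random draw flows from an explicit seed, so all reported
numbers are reproducible bit-for-bit.

## Known limitations

* Ordered-sequential mechanisms only; no random-order or ping-pong kinetics,
  no activation, and no cross-reaction thermodynamic (Haldane) consistency
  enforcement.
* One enzyme per reaction; no gene-protein-reaction mapping.
* The spanning-tree enumeration is exponential in complex count and intended
  for mechanisms up to a handful of substrates/products — exactly the regime
  where the King-Altman construction is standard.
* Profile confidence intervals re-optimize from warm starts; on strongly
  multimodal profiles the interval can be conservative.
* The isotopomer oracle is exponential in carbon count (by design, as a
  reference method) and restricted to small fixture networks.
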