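---
title: "Nested DAPP maps from coupled infrastructure system models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested DAPP maps from coupled infrastructure system models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dappmap)
```

This vignette documents the model behind `dappmap`, the assumptions baked
into the synthetic hedgerow fixture, and every numerical choice a user may
want to question.  It states no empirical result beyond what the package's
tests and the acceptance script themselves compute.

## 1. The compartment model

A social-ecological system is represented by four compartments: a resource
`R`, whose state is a vector of ecosystem-service (ES) potentials in
`[0, 1]`, and three social roles — exploitation `E`, conservation `C`,
policy-making `P` — whose states are relative capacities of action in
`[0, 1]`.  Interactions are annual rates (`action_weights()`): self-loops
`u0a..u0d`; access/management and extraction `u1a`, `u1b` with regulation
rates `u5a`, `u5b` and monitoring returns `u5a_prime`, `u5b_prime`;
cross-role support and sanction links `u2*`, `u3*`, `u6*`; monitoring and
support of the resource `u4a`, `u4b`; and couplings with the external
settings `u7a..u7h`, of which `u7b ≤ 0` is the external (climate) stress on
the resource.

Three structural contracts are enforced:

* **Ranges.** `u1a, u2a, u4a, u5a, u5b, u5a_prime, u5b_prime ∈ [0, 1]`;
  `u7b ∈ [-1, 0]`; all other weights in `[-1, 1]`.  Signed weights carry
  their own sign; `cisf_derivative()` refuses out-of-range inputs.
* **Normalization.** The incoming weights of each social compartment sum
  to one (`check_normalization()`).  A compartment whose role has been
  switched off by an arrangement ends with all incoming weights zero; we
  treat that as an *absent* role that passes trivially, because a
  sum-to-one constraint on a non-existent compartment has no meaning.
  `allow_absent = FALSE` restores the strict reading.
* **Clamping.** Integration (`cisf_simulate()`) is fixed-step explicit
  Euler with `dt = 1` year — matching the annual framing of the case
  study — and clamps ES levels and role capacities to `[0, 1]` *after*
  each step (dynamics first, then clamp).

Two deliberate interpretation choices: the typeset role equations couple
the settings and externality terms of `dP/dt` to the conservation capacity
`C` (we keep them exactly as typeset rather than "fixing" them to `P`), and
where the scalar role equations need the resource as a scalar we use the
mean of the ES component levels.  The closed-form growth condition
(`resource_growth_condition()`) is exposed in two variants, because the
printed inequality mixes the regulation rate `u5a` with the monitoring rate
`u5a_prime` and uses the support weight `u4b` where the dynamics use `u4a`:
variant `printed` evaluates the closed form (with the stress rate entering
through its magnitude, since it sits on the loss side of the inequality),
variant `derived` takes the sign of `dR/dt` directly from the dynamics.
Both are returned; we do not guess which was intended.

## 2. Nested arrangements

Governance is encoded at three nested levels (`arrangement()`):

* **CCA** (constitutional): which roles exist (`role_mask`).  A role
  switched off forces every link whose dynamics involve that role's state
  off as well.
* **KCA** (collective): which individual links are active (`link_mask`).
* **OCA** (operational): the chosen intensity of each operational action —
  the weights outside the sum-to-one groups (management, regulation,
  support, stress, externalities) — within an admissible `[min, max]`
  range.

`arrangement_weights()` turns an arrangement plus a base weight set into
concrete weights: mask, apply OCA intensities, then rescale each active
compartment's remaining incoming weights proportionally so the sum-to-one
contract survives.  Proportional renormalization is a design choice (the
sharing of freed weight among surviving links is not otherwise
determined); it preserves the relative importance of the surviving links.
OCA intensities are *set* to their chosen value rather than multiplied
into the current weight: set-semantics makes the operation idempotent
(applying an arrangement to its own output is a no-op), which is the
property a configuration-application operator should have.  Intensities on
weights inside a sum group are rejected, because renormalization would
silently rescale them away.

Adaptation actions between arrangements (`diff_arrangements()`) are
reported at the *highest* level that differs — constitutional if the CCA
index differs, else collective from the link-mask difference, else
operational — as multi-tier action codes
(`U[_{level}[:{from}->{to}]]_[{trigger}->]{target}:{tier1}{tier2}`), with a
documented default SESF coding per link.  The grammar is this package's
own; the tier-2 index bounds per category (S: 7, RS: 10, RU: 7, GS: 10,
A: 9, I: 10, O: 3) follow the standard multi-tier attribute table.

## 3. Viability analysis

Actor needs are a box of ES constraints (`satisfactory_domain()`): lower
thresholds for services, upper thresholds for disservices.  Margins are
normalized by the feasible width of each bound (`1 - min` for a service,
`max - 0` for a disservice) so that 0 is the threshold and 1 is maximal
satisfaction regardless of where the threshold sits; the *security* of a
state is the mean normalized margin.

`compute_kernel()` computes the finite-horizon viability kernel by
backward induction on a regular grid:

* **Snapping.** Interval endpoints are snapped to the nearest grid node
  (discrete viability approximation).  On the hedgerow simplex a rounded
  node can leave the feasible region; the repair rule deterministically
  steps down the coordinate with the largest upward rounding residual
  until the node is feasible.  Trajectories leaving the grid bounds are
  non-viable and counted (`n_out_of_bounds`).
* **Constraint checking.** The domain is checked at every annual sub-step,
  not only at decision nodes, because viability requires the trajectory to
  stay in the domain at *all* times; `check_every_step = FALSE` restores
  node-only checking for speed.
* **Resolution.** Default 21 points per dimension, configurable.  Results
  are resolution-sensitive near the kernel boundary; the tests therefore
  verify exact agreement with exhaustive control enumeration on a toy grid
  (where both computations share the same snapping rule) rather than
  claiming grid-free accuracy.  The kernel-vs-enumeration and monotonicity
  test problems use 5–7 points per dimension in 2-D and 6 points per
  dimension on the 4-D hedgerow simplex — sizes at which exhaustive
  enumeration is exact and fast.

Two monotonicity properties are tested: relaxing every bound can only grow
the kernel, and extending the horizon can only shrink the epoch-0 kernel.

## 4. DAPP maps

Decisions are taken every `step` years over a `horizon`
(`decision_schedule()`; default 5 over 30, i.e. 7 epochs).  The
arrangement chosen at an epoch governs the following interval; the final
epoch's arrangement labels the end state but governs no interval.  This
convention makes the pathway space `U^(horizon/step + 1)` — `9^7 =
4,782,969` for nine arrangements — which is the published size of the
example's pathway space; six governed intervals alone would give `9^6`.

`enumerate_viable()` explores the choice tree epoch by epoch, pruning any
prefix that leaves the domain.  Because dynamics are deterministic, states
reached by different prefixes that coincide *exactly* (to the floating
point) are merged; no grid snapping is used in forward enumeration, so
memoization never changes the counts (a property the tests verify by
re-running with memoization disabled).  Suffix and prefix counts over the
merged DAG give per-segment traversal counts without materializing
millions of pathways; the grayscale shade of a segment is its count
divided by the maximum count in the same map (per-map normalization — the
alternative, normalizing across a family of maps, is not used).

Pathway scoring:

* **Security** = mean over the `horizon + 1` annual states of the mean
  normalized margin.  A worst-year alternative (`aggregate = "min"`) is
  available; the time-mean is the default because a single aggregate for a
  30-year trajectory should reward persistent slack, not only the worst
  year.
* **Per-ES optimality** = mean annual level of the named ES (maximized for
  services, minimized for disservices); all co-optimal pathways within a
  `1e-9` tolerance are returned.  Ties in `top_secured()` break by
  lexicographic arrangement sequence, which is deterministic and
  reportable.

`collect_pathways()` refuses to materialize more than `max_pathways`
(default 200,000) pathways; the probability map never needs
materialization, only the secured/optimal subsets do.

## 5. What the hedgerow fixture emulates — and what it does not

`default_fixture()` generates a synthetic case patterned on a hedgerow
management problem: landscape composition over five classes (tall/short ×
species-rich/species-poor + absent) evolving under an annual operator
composed of baseline degradation, arrangement-specific management
(planting, letting grow, enrichment, trimming, removal) and climate stress;
seven ES computed from composition.  Its constants are documented design
choices, not estimates:

* **Transition rates.** Baseline degradation of a few percent per year;
  management conversion rates between 0.1 % and 7 % per year, increasing
  with the institutional capacity of the arrangement (the single-role
  status-quo CCA1|KCA1 barely maintains the network; the fully polycentric
  CCA4|KCA8 funds planting, enrichment and growth).  Climate stress at
  levels {0, 1, 2} adds {0, moderate, strong} extra decay concentrated on
  the tall and species-rich classes and maps onto the stress weight
  `u7b = -0.1 × level`.
* **ES functions.** All but aesthetics are clipped linear in the class
  proportions, with species-rich classes weighing more for pollinator
  resources and fruit, tall classes for wood biomass and sunlight
  protection, and poorly-maintained (species-poor) classes weighing more
  for the two disservices.  Landscape aesthetics is the Shannon diversity
  of the four hedgerow classes, renormalized over hedgerows present and
  divided by `log 4`.
* **Constraint sets.** The rural domain is strictly tighter than the
  peri-urban one on every bound, encoding stronger rural dependence on the
  ES; the two SES types share identical dynamics, so every difference in
  their maps comes from the constraint sets alone.
* **Initial state.** Short/species-poor dominated
  (`TR 0.05, TP 0.15, SR 0.08, SP 0.42, NO 0.30`), consistent with a
  landscape long governed by the status-quo arrangement.
* **Seed.** The seed jitters the base action weights by ±5 % (group
  weights renormalized afterwards, so the sum-to-one contract holds for
  every seed).  Transition rates, ES coefficients and thresholds are fixed
  constants: the calibration below is a property of the shipped design,
  not of a random draw.
* **Calibration.** The shipped defaults were designed once so that holding
  CCA1|KCA1 for the whole 30-year horizon is non-viable for both SES types
  at every climate level — the fixture's status-quo-fails premise — while
  stronger arrangements restore viability.  The tests assert this property;
  no numeric agreement with any published map is claimed.

The nine arrangements pair four CCAs (E only; E+P with payment contracts;
E+C collective conservation; E+C+P polycentric) with KCA link-mask
variants; the exact role/link composition of published arrangements is not
reproducible from public material, so the fixture's masks are labelled
emulation and are configurable.

What passing tests therefore show: the *algorithms* (normalization,
masking, kernel, enumeration, scoring, sensitivity) are correct against
independent oracles, and the fixture reproduces the *qualitative* regime
described for the case (rural maps sparser than peri-urban, stress
shrinking the viable set, status quo failing).  What they do not show:
numeric agreement with any real site, estimated transition probabilities,
or published figure values.

## 6. Retrospective sensitivity

`delta_security()` asks, pathway by pathway, whether shifting management
effort toward species-rich over species-poor hedgerows (or tall over
short) would have gained security on each ES.  The default perturbation is
retrospective: the pathway's hedgerow trajectory is kept fixed, and the
per-class ES delivery coefficients are reweighted by the effort vector
(`1 ± perturbation_size` on the two class pairs, clipped to `[0, 2]`) —
effort improves a class's service delivery and reduces its disservices,
but does not replant the landscape.  Under this reading landscape
aesthetics, which depends only on the planted composition's diversity, is
*exactly* insensitive to effort swaps, and reversing the contrast flips
every delta's sign exactly; both are tested as identities.  The
alternative `mode = "dynamics"` rescales the management transition rates
and re-simulates — there the aesthetics delta is only approximately zero,
which is why it is offered as an exploratory mode rather than the default.
The default effort shift of 0.1 (10 %) is small enough to stay in the
linear response regime of the clipped ES forms for typical compositions.

Distribution summaries use exact type-7 sample quantiles and fixed-width
histogram bins (default 30) for export; empty samples return an explicit
empty marker rather than NAs.

## 7. Problem sizes and determinism

The default full run — nine arrangements, seven epochs, annual sub-steps —
enumerates the pruned choice DAG in seconds on one core because each layer
is evaluated as one matrix operation over all surviving states.  The test
suite's oracle comparisons run on deliberately small instances (3
arrangements × 3–4 epochs, 5–7 point grids) where exhaustive enumeration
is exact; the acceptance script runs all six SES × climate conditions at
full size plus a 6-point/dimension kernel.  A single seed governs all
stochastic fixture generation; every analysis stage downstream of the
fixture is deterministic, which the pipeline tests verify byte-for-byte on
exported files.

## 8. Known limitations

* Dynamics are deterministic; no stochastic transitions, no spatially
  explicit resource.
* The kernel is finite-horizon only; resilience (return-to-kernel) is out
  of scope.
* The meta-constitutional level is a fixed context, not a switchable
  arrangement.
* The compartment ODE layer and the hedgerow Markov layer are coupled only
  through the arrangement definitions and the stress weight `u7b`; the
  fixture's landscape dynamics do not feed back into role capacities.
* Kernel membership near the boundary depends on grid resolution and the
  snapping rule; treat slice plots as qualitative unless the resolution
  study says otherwise.
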