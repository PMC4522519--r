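---
title: "Modelling bistable perception with quantum instruments"
author: "qpercept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bistable perception with quantum instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpercept)
```

## The model

`qpercept` models the perception of an ambiguous figure — the canonical
example is the Schröder stair, read either as "left side in front" (L) or
"right side in front" (R) — as an *indirect quantum measurement*.  The
mental state is a density operator on a tensor product $H \otimes K$:

* $H$, the **sensation space**, carries the rich, consciously inaccessible
  state $\rho$ built from the visual input.  The alternatives L/R are *not*
  sharply represented there: the sensation subspaces associated with the two
  readings may overlap.
* $K$, the **perception space**, carries the state $\sigma$ open to
  conscious introspection.  On $K$ the answer is an ordinary projective
  observable with orthogonal projectors $(P_L, P_R)$ — the two conscious
  readings are mutually exclusive.

One presentation at rotation angle $\theta$ proceeds in three moves:

1. **Sensation dynamics.** The rotated image drives a unitary
   $\rho \mapsto U_\theta\, \rho\, U_\theta^*$ on $H$.
2. **Interaction.** Sensation and perception couple through a fixed unitary
   $U$ on $H \otimes K$ (the same at every angle):
   $R_{\mathrm{out}} = U (\rho \otimes \sigma) U^*$.  The initial state is a
   product — sensation and perception start unentangled.
3. **Conscious registration.** The answer $i \in \{L, R\}$ occurs with
   probability $p_i = \mathrm{Tr}\, [R_{\mathrm{out}} (I \otimes P_i)]$, and
   the registered answer *disentangles* the mind into the product of the two
   conditional reduced states,
   $\rho_i \propto \mathrm{Tr}_K [R_{\mathrm{out}} (I \otimes P_i)]$ and
   $\sigma_i \propto \mathrm{Tr}_H [R_{\mathrm{out}} (I \otimes P_i)]$,
   which seed the next presentation.

On the sensation factor alone, step 3 is an *unsharp* measurement: the
induced POVM $M_i = \mathrm{Tr}_K[(I \otimes \sigma) U^* (I \otimes P_i) U]$
has effects that are positive and complete but in general not projectors
(`induced_povm()`; the package verifies the three equivalent probability
routes — composite trace, Born rule on the reduced perception state, POVM
trace on the sensation state — against each other).  This unsharpness is the
model's rendering of unconscious inference: the unconscious read-out cannot
fully separate sensations that lead to different conscious perceptions.
Back-action without full projection is also why sequences of presentations
show memory: each answer deforms $\rho$ (and, by default, $\sigma$), so the
statistics of a context $C = (\theta_1, \dots, \theta_m)$ depend on the
order of the angles.

The package also implements the general measurement hierarchy behind this
scheme — projective observables, atomic instruments
($\rho \mapsto Q_i \rho Q_i^*/p_i$ with $\sum Q_i^* Q_i = I$), and
Davies–Lewis instruments (one positive superoperator per outcome,
trace-preserving in total, stored as Kraus components so positivity holds by
construction) — together with their induced POVMs, sequential composition by
the quantum Bayes rule
$p((a,b) \mid \rho) = p(b \mid \rho_a)\, p(a \mid \rho)$, and the mixing law
$p(a \mid q_1 \rho_1 + q_2 \rho_2) = q_1 p(a \mid \rho_1) + q_2 p(a \mid \rho_2)$,
which every implemented measurement kind satisfies identically because all
probabilities are traces against fixed effect operators.  The mixing law is
enforced here as a mathematical property of the formalism; whether cognition
obeys it empirically is an open scientific question outside this package's
scope.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| $d_H, d_K$ | factor dimensions | 2, 2 | binary L/R task; all state algebra works for arbitrary finite $d$ |
| $a, b$ | sensation rotation $g(\theta) = a + b\,\theta_{\mathrm{rad}}$ (radians) | 0, 1 | a monotone angle-to-rotation map is the minimal family able to produce the clockwise/counterclockwise crossover; $b = 0$ switches the order dependence off |
| $\mu_0, \mu_1$ | controlled-rotation interaction $U = \sum_k \lvert k\rangle\langle k\rvert \otimes R(\mu_k)$ | $\mp\pi/4$ | the angle difference is the measurement strength: $\mu_0 = \mu_1$ conveys no information, $\mu = \mp\pi/4$ on the neutral $\sigma_0$ is a sharp read-out |
| $\rho_0$ | pre-recognition sensation state | maximally mixed $I/2$ | no committed reading before the first picture; overridable (the hysteresis fixture uses $\lvert L \rangle$) |
| $\sigma_0$ | initial perception state | $(\lvert L\rangle + \lvert R\rangle)/\sqrt 2$ | the neutral superposition, the deepest state of uncertainty between the two readings |
| `reset_sigma` | reset $\sigma$ to $\sigma_0$ before each picture | `FALSE` | the default carries the conditional perception state forward from one picture to the next; the reset variant treats each picture as a fresh perception problem.  Both are defensible readings of the sequential protocol, so the choice is an explicit flag |
| angle grid | presentation angles | `seq(0, 90, length.out = 11)` in degrees | eleven pictures spanning a quarter turn; the exact experimental angles are a convention |

No concrete interaction unitary is dictated by the theory; the controlled
rotation is this package's modelling convention (chosen because measurement
strength is a single readable parameter), and a generic alternative
(`hermitian_unitary()`, the exponential of a parameterized Hermitian
generator) is provided for sensitivity checks.

## Contexts, contextuality, and the Leggett–Garg statistic

`run_context()` enumerates all $2^m$ outcome paths of a context exactly
(feasible up to $m = 16$); `sample_outcomes()` draws Monte-Carlo
trajectories.  `joint_feasibility()` asks whether the statistics collected
under several contexts are marginals of one classical joint distribution
over all variables, and `lg_statistic()` computes the standard three-time
Leggett–Garg combination $K = C_{12} + C_{23} - C_{13}$ of two-time
correlators ($L \mapsto +1$, $R \mapsto -1$), whose bound under any
classical joint is 1.  The underlying theory refers to a temporal
Bell-type inequality without fixing its constants; this package deliberately
substitutes the canonical three-time Leggett–Garg form, which is the
standard inequality for dichotomic sequential measurements and is implied by
classical embeddability — the implication is asserted in the test suite.

Two pair protocols are exposed.  In the default `"two_time"` protocol all
three images are presented in order — the sensation dynamics always acts —
but responses are collected only at the two chosen slots; this matches the
physical reading of two-time correlations (time passes whether or not one
answers).  `"marginalize"` instead measures at all three slots and
marginalizes, which in a disturbing theory is a genuinely different
experiment; the two protocols demonstrably differ on the committed fixtures.

The committed `"contextual"` fixture (constant sensation rotation $\pi/6$
between sharp measurements, perception reset each step) realizes the
textbook maximum $K = 2\cos(\pi/3) - \cos(2\pi/3) = 1.5$; the `"classical"`
fixture (diagonal phase dynamics, basis-controlled interaction, reset)
commutes with the outcome basis, making the outcome process a classical
mixture of conditionally i.i.d. sequences — embeddable, $K \le 1$.

## The synthetic experiment generator

`simulate_experiment()` emulates the reference three-group design: groups of
55, 48 and 48 subjects, 11 pictures, group A with a fresh random order per
subject, groups B/C with clockwise/counterclockwise orders.  All subjects
share one parameter set — the model describes a single idealized agent, and
between-subject heterogeneity is deliberately *not* simulated.  The
generator also omits lapses, response bias, learning across the session, and
reaction times: a green test against it establishes that the implementation
reproduces its own stated stochastic model at the stated design sizes, not
that real observers behave this way.  Group sizes are inflatable (the
recovery tests use 5,000 per group) without changing the design structure.

## Fitting

`fit_schroeder()` estimates $(a, b, \mu_0, \mu_1)$ by maximum likelihood
with seeded Nelder–Mead multistarts (8 by default).  Two likelihoods are
implemented: a binomial likelihood of per-(group, angle) frequency cells
under the exact model marginals, and the exact per-subject sequential path
likelihood (the chained quantum Bayes rule along each subject's realized
outcome sequence), which is the only correct treatment of random-order
subjects.  Unitary parameterizations carry gauge freedom — distinct
parameter vectors can induce identical probability curves — so the contract
of a fit is the predicted curve, never the raw parameters; the tests assert
probability-level recovery.

The deterministic-order curves alone do not always pin down the
random-order behaviour: distinct likelihood basins can tie on
clockwise/counterclockwise data while disagreeing on random orders.  The
recommended `sequential = "refine"` strategy therefore explores with the
cheap curve likelihood, evaluates the full sequential likelihood (all
groups) at every multistart optimum to select the basin, and polishes the
winner with the sequential likelihood of the random-order group plus the
curve likelihood of the rest, restarting Nelder–Mead until it reports
convergence.  Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ so
degenerate parameter values stay finite; non-convergence is reported in the
`convergence` flag, never silently.  Under-determined problems (fewer
informative cells than parameters) are flagged with a warning.

## Numerical choices

* **Tolerances.** Trace and Hermiticity are checked to $10^{-12}$;
  positivity to $-10^{-10}$ on the smallest eigenvalue; POVM completeness
  and probability normalization to $10^{-10}$; path-probability sums to
  $10^{-9}$.  The looser bounds absorb double-precision accumulation across
  up to 11 sequential steps.  Validation is strict by default and opt-out
  (`validate = FALSE`) for internal measurement chains.
* **Zero-probability conditioning.** The conditional post-state of an
  outcome with (numerically) zero probability is undefined; requesting it
  raises an error rather than returning a junk normalized state.  In the
  exact path enumeration such branches carry zero weight and propagate
  harmlessly.
* **Conditional states.** Conditional reduced states are computed from the
  two-sided (Lüders) form $(I \otimes P_i) R_{\mathrm{out}} (I \otimes P_i)$.
  On the sensation side this equals the one-sided form
  $\mathrm{Tr}_K[R_{\mathrm{out}}(I \otimes P_i)]$ identically (the cyclic
  property of the partial trace over $K$); on the perception side the
  two-sided form is the one that yields a valid Hermitian state, and for
  rank-1 projectors it gives $P_i$ itself, as a projective measurement
  should.
* **The branch engine.** `run_context()`, the samplers and the sequential
  likelihood advance all live branches (or all subjects) simultaneously as
  $d \times d \times B$ complex arrays, so an 11-angle exact enumeration
  (2,048 paths) costs about 30 ms.  A slow single-state reference route
  through `perception_step()`/`run_indirect()` exists solely so the tests
  can cross-check the engine against an independent implementation.
* **Feasibility residual.** Classical embeddability is decided by solving
  the marginal-constraint system over the $2^n$ global assignments as a
  *nonnegative least-squares* problem with an exact Lawson–Hanson active-set
  solve (the passive set never exceeds the constraint count, so each
  iteration factorizes a tiny matrix).  The reported residual is the maximal
  absolute marginal violation at the optimum: it vanishes exactly on
  feasible systems, and on infeasible ones upper-bounds the minimax-program
  optimum.  This formulation was chosen over a linear minimax program
  because no LP solver is available in the target environment, and the
  decision (zero vs. nonzero) is identical; the solver is cross-checked
  against a brute-force vertex-enumeration oracle in the tests.  Single-variable
  marginal inconsistencies between contexts are additionally reported with
  the offending context pair.
* **Seeding.** One global seed fans out to per-subject, per-order and
  per-multistart child seeds through a counter-based congruential hash
  (`derive_seed()`), so enlarging a group or adding restarts never perturbs
  earlier streams, and all derived seeds stay below $2^{31}$.

## Limitations

* The interaction unitary and the sensation dynamics family are modelling
  conventions, not theoretical commitments; conclusions about parameter
  *values* are gauge-dependent and should always be stated at the
  probability level.
* Non-unitary sensation–perception interactions and initially entangled
  mental states are out of scope (the product initial state is enforced),
  as are infinite-dimensional state spaces and continuous outcome sets.
* The exact enumerator is exponential in the number of measured steps
  (capped at 16); longer contexts must be sampled.
* The synthetic generator is not a psychometric model: no lapses, bias,
  learning, or subject heterogeneity.
* The mixing law is enforced as mathematics; its empirical status for
  cognition is untested here.

```{r example}
model <- fixture_model("hysteresis")
run_context(model, rotation_context(preset = "clockwise"))$marginals
contextuality_report(fixture_model("contextual"), c(0, 45, 90))
```
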