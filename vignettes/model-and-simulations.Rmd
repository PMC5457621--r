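---
title: "Observer agreement, metastability and the two-placebo trial contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer agreement, metastability and the two-placebo trial contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placebosim)
```

## The model

`placebosim` simulates an elementary experiment comparing two inert
placebos, `Pcb0` (the designated control) and `Pcb1`, against a binary
biological outcome per sample: change ("up") or no change ("down"). A
*direct* relationship pairs `Pcb0` with "down" and `Pcb1` with "up"; the
*reverse* relationship is the opposite pairing. The description is taken
from the standpoint of a participant who never takes part in the
measurements, and rests on three assumptions:

1. **Independent expectations.** Each of N observers independently expects
   a direct relationship with probability *p* (and reverse with
   *q* = 1 − *p*).
2. **Intersubjective agreement.** Interacting observers must report the
   same outcome. Joint configurations in which they disagree are discarded
   and the agreeing ones renormalized, which gives the agreement map
   \[
   f_N(p) = \frac{1}{1 + (1/p - 1)^N} = \frac{p^N}{p^N + q^N}.
   \]
   With no observers the probability is 1/2 regardless of *p*; with one
   observer the map is the identity.
3. **Temporal autocorrelation with small fluctuations.** Each iterate is
   built from the previous one, perturbed by a tiny random fluctuation
   \(\epsilon\):
   \[
   p_{n+1} = f_N(p_n + \epsilon_{n+1}), \qquad p_0 = 1/2.
   \]

Since \(|f_N'(1/2)| = N\), the starting point 1/2 is metastable for
N ≥ 2: deviations are multiplied by ≈ N each step until the trajectory is
absorbed at 0 or 1, both exact fixed points of the map. The branch is
chosen symmetrically at random. Designating `Pcb0` as the control removes
the 0-branch (that stable position would pair the control with both change
and no change, a contradiction), which we implement as post-selection:
trajectories absorbed at 0 are discarded, and the surviving ensemble has
empirical Prob(direct) = 1. The alternative — modifying the update rule to
reflect at 0 — is deliberately not implemented, because no modified
dynamics is specified by the model; post-selection is the minimal reading
of the self-elimination argument.

Two closed-form extensions complete the calculus:

* **Independence parameter d.** For two observers, the joint expectation
  table generalizes to diagonal weights \(p^2 + d\), \(q^2 + d\) and
  off-diagonal weights \(pq - d\), giving
  \(f_d(p) = (p^2 + d)/(p^2 + q^2 + 2d)\). At d = 0 this is the
  two-observer agreement probability; at d = pq it reduces to classical
  probability, \(f_d(p) = p\). We enforce \(0 \le d \le pq\): although the
  looser bound d ≤ 1 appears in one statement of the generalized product
  rule, the off-diagonal weights \(pq - d\) must stay non-negative for the
  joint table to be a distribution, and the interpolated formula's own
  domain is stated as \([0, pq]\). We expose d for the two-observer case
  only; no N-observer generalization of the joint table is defined by the
  model, and we prefer not to invent one.
* **Path amplitudes.** With real amplitudes a, b (a² = Prob(Pcb0),
  b² = Prob(Pcb1)), the probability of a direct relationship is
  \((aa + bb)^2\) when the two paths are indistinguishable (local
  assessment; the reverse component \((ba - ab)^2\) vanishes identically)
  and \((aa)^2 + (bb)^2\) when a remote supervisor distinguishes them.
  At a = b = 1/√2 these give 1 and 1/2 — the testable contrast. Amplitudes
  are real throughout; the sign device for stable position #2
  (b² read as −b × −b) is noted by the model but not developed, so only
  the sign-free probabilities are implemented.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `n_observers` | interacting observers N | 2 | smallest team exhibiting metastability |
| `p_direct` | elementary probability of a direct relationship | 0.5 | two indistinguishable placebos |
| `d_param` | independence parameter, in \([0, pq]\) | 0 | fully committed observers (quantum-like regime) |
| `p0` | initial probability | 0.5 | the no-observer value |
| `fluct` | fluctuation law | uniform, half-width 0.5e-15 | the published simulation conditions |
| `atol` | absorption tolerance | 1e-12 | see numerical choices |
| `transition_threshold` | departure from 1/2 that counts as the transition | 0.25 | halfway between the metastable point and either boundary |

The fluctuation scale is stated in two slightly different ways in the
model's description — "values around 10⁻¹⁵" and "between −0.5 and
+0.5 × 10⁻¹⁵". We adopt the second, read as a uniform law on
\([-0.5\times10^{-15}, +0.5\times10^{-15}]\) (the alternative reading,
±0.5, would contradict the standing assumption \(|\epsilon| \ll 1\)).
Both the distribution family (uniform or gaussian) and the width are
configurable; widths above 10⁻³ trigger a warning.

## What the simulator emulates, and what it does not

The trajectory generator *is* the synthetic-data source of the package:
its defaults are the study conditions (N = 2, p₀ = 1/2, uniform
fluctuations of half-width 0.5 × 10⁻¹⁵, up to 200 steps). It emulates an
idealized, perfectly autocorrelated system with stationary fluctuations.
It does not emulate: drifting or autocorrelated noise, "elastic" systems
with restoring forces (which never transition and are covered only by the
no-transition test cases N = 0, N = 1 and ε = 0), measurement dropout, or
patient-level covariates. Passing tests therefore show the internal
consistency of the model and its implementation — not that real trials
behave this way.

The virtual trial likewise realizes the model's endpoint exactly: local
assessment produces the constrained stable position (every `Pcb1` sample
up, every `Pcb0` sample down) before optional noise; remote assessment
keeps the same number of "up" outcomes but redistributes them uniformly
over all samples. The remote marginal rate is not specified by the model;
preserving the local-mode total (half the samples) is our inference from
the model's illustration of the two designs, and the margin-preserving
permutation is the most literal reading of "randomly distributed among the
two placebos". An independent Bernoulli(1/2) variant is exposed as
`remote_style = "bernoulli"` but is not the default. The noise parameters
`background_rate` and `flip_noise` default to 0; they are extensions for
power curves, not part of the core model.

## Numerical choices

* **Deviation-form map.** Near p = 1/2 the ratio form of \(f_N\) loses
  relative precision on the deviation by catastrophic cancellation, which
  matters when the dynamics amplifies 10⁻¹⁵-scale deviations. We evaluate
  the algebraically identical form
  \(f_N(p) = 1/2 + (p - 1/2)\,s/(p^N + q^N)\) with
  \(s = \sum_{k=0}^{N-1} p^k q^{N-1-k}\), using the exactly representable
  difference p − 1/2 (Sterbenz), so the one-step response at the
  metastable point is correct to the last bit.
* **Boundaries by continuity.** \(f_N(0) = 0\) and \(f_N(1) = 1\) for
  N ≥ 1 rather than a division-by-zero error: the absorbing states must be
  evaluable.
* **Clamping.** A perturbation pushing p + ε outside \([0, 1]\) is clamped
  to the nearer boundary. The map is undefined there, and the situation is
  only reachable within ε of a boundary, where the state is already
  decided.
* **Absorption.** A trajectory within `atol = 1e-12` of a boundary is
  declared absorbed and snapped to exactly 0 or 1. Iterates approach the
  boundary quadratically (near 1, the residual squares each step), so the
  snap changes the final value by at most `atol` while making the stable
  positions exact, as the model treats them.
* **Fixed points.** Located by a dense-grid sign-change scan of
  \(f_N(p) - p\) with bisection refinement to 1e-12, generalizing to any N
  without symbolic roots; the boundary fixed points are exact by
  construction. Stability comes from a finite-difference derivative
  (central in the interior, one-sided at the boundaries, step 1e-6);
  |derivative − 1| < 1e-9 is classified neutral, since no numerical
  definition of stability is part of the model.
* **Exact tests from first principles.** The 2×2 association test sums
  hypergeometric point probabilities (via `lchoose`) over tables no more
  probable than the one observed, with the customary 1 + 1e-7 relative
  guard for floating-point ties; the branch-symmetry test does the same
  with binomial masses. Both are cross-checked against the independent
  implementations in `stats` in the test suite.
* **Reproducibility.** Trajectory *i* of an ensemble is seeded with
  `base_seed + i`, so ensembles are deterministic given the base seed and
  any single trajectory can be regenerated in isolation. Identical
  (parameters, seed) give bit-identical trajectories.

## Problem sizes

The shipped test suite and the acceptance script use the sizes the model's
own description works at: 8-trajectory ensembles for the qualitative
absorption picture, 100–2000 trajectories for branch-symmetry and
full-absorption statistics, 200 runs per cell for the (N, width) sweep,
and 500 simulated trials per assessment mode for the rejection-rate
contrast at n = 20 per arm. At the default fluctuation scale a trajectory
transitions after ≈ log₂(0.25/10⁻¹⁵) ≈ 48 steps and absorbs within ~70,
so 200-step budgets absorb every run.

## Known limitations

* d is implemented for two observers only (see above).
* The recurrence is a discrete-time map; no continuous-time or SDE
  reformulation is offered.
* Complex amplitudes, density matrices and other general quantum-state
  formalism are out of scope: the path calculus is exactly the
  real-amplitude arithmetic the model uses.
* The trial simulator produces binary outcomes for two arms only; no
  longitudinal outcomes, covariates, or ingestion of real clinical-trial
  data.
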