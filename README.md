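# placebosim

Simulation of quantum-like correlations between placebo labels and
biological outcomes in a virtual two-placebo experiment.

## The scientific problem

Consider an elementary experiment comparing two *inert* placebos that differ
only by their labels: `Pcb0` (designated control) and `Pcb1`. Each sample of
a biological system either changes state ("↑") or does not ("↓"). Common
sense — and the standard null hypothesis

> Prob(↑ | Pcb0) = Prob(↑ | Pcb1)

— says the outcomes must be statistically indistinguishable between arms.

`placebosim` implements a probabilistic model in which this null can
nevertheless fail. The model describes the experimenters, the biological
system and their interactions together, from the standpoint of a
*participant uninvolved in the measurement*. Two ingredients drive it:

1. **Intersubjective agreement.** If each of N observers independently
   expects a "direct" relationship (`Pcb0`→↓, `Pcb1`→↑) with probability
   *p*, and interacting observers must agree, discarding disagreeing joint
   configurations and renormalizing gives

   Prob(direct) = 1 / (1 + (1/p − 1)^N) = p^N / (p^N + q^N),  q = 1 − p.

   With no observers (N = 0) this is 1/2 for every p.

2. **Random probability fluctuations.** In a real biological experiment,
   Prob(direct) is perturbed at every instant by tiny random fluctuations
   ε (scale ~10⁻¹⁵). Iterating the map on the perturbed value,

   p(n+1) = 1 / (1 + (1/(p(n) + ε(n+1)) − 1)^N),  p(0) = 1/2,

   turns the initial value 1/2 into a *metastable* point: the local
   derivative of the map is N, so any deviation is amplified until the
   trajectory is absorbed at one of the stable positions, Prob(direct) = 1
   or Prob(direct) = 0. Designating `Pcb0` as the control eliminates the
   0-branch, leaving Prob(direct) = 1: a perfect label–outcome correlation
   between two inert placebos.

The model's testable signature is the **assessment-mode contrast**, derived
from a real-amplitude path calculus (amplitudes a, b with a² = Prob(Pcb0),
b² = Prob(Pcb1)):

* **local assessment** (open-label or local blind; correlations first
  assessed inside the experiment): coherent calculus, square of the summed
  amplitudes — Prob(direct) = (a·a + b·b)² = **1**;
* **remote assessment** (centralized blind; first assessed by an outside
  supervisor): classical calculus, sum of squares —
  Prob(direct) = (a·a)² + (b·b)² = **1/2**.

A virtual trial therefore comes out significant under local assessment and
null under remote assessment.

## Worked example

```r
library(placebosim)

## fixed points and stability of the two-observer agreement map
fixed_points(2)
#> Fixed points of the agreement map, N = 2
#>  p_star derivative_magnitude  stability
#>     0.0         9.999224e-07 attracting
#>     0.5         2.000000e+00  repelling
#>     1.0         9.999779e-07 attracting
```

The metastable point 1/2 repels with derivative magnitude N = 2; the
absorbing states 0 and 1 attract.

```r
## 2000 trajectories at the published conditions
## (N = 2, p0 = 1/2, uniform fluctuations on [-0.5e-15, +0.5e-15])
es <- run_ensemble(model_params(n_observers = 2), 2000, 200,
                   base_seed = 40000)
es
#> Ensemble of 2000 trajectories (N = 2, base seed = 40000)
#>   absorbed at 1: 969   absorbed at 0: 1031   unabsorbed: 0
#>   absorption steps: min 53, median 55, max 66
branch_symmetry_test(es)
#> Exact binomial branch-symmetry test (null: proportion = 1/2)
#>   branch one: 969 / 2000  (proportion 0.4845)
#>   two-sided p-value: 0.1725517
#>   95% CI: [0.4623838, 0.5066617]
```

Every trajectory is absorbed at exactly 0 or 1 within ~66 steps (the
deviation doubles each step from the 10⁻¹⁵ scale: log₂(0.25/10⁻¹⁵) ≈ 48
steps to leave the metastable region), and the branch choice is a fair
coin, as the exact binomial test confirms.

```r
## the local-significant / remote-null trial contrast
simulate_trial(trial_config(20, "local", seed = 7))
#> Two-placebo trial, local assessment
#>       outcome
#> label  down up
#>   Pcb0   20  0
#>   Pcb1    0 20
#>   exact two-sided p-value: 1.450889e-11
#>   relationship called: direct
simulate_trial(trial_config(20, "remote", seed = 7))
#>       outcome
#> label  down up
#>   Pcb0    8 12
#>   Pcb1   12  8
#>   exact two-sided p-value: 0.3430672
#>   relationship called: none
trial_power(trial_config(20, seed = 1000), n_sims = 500)
#> Trial-contrast power (500 sims/mode, alpha = 0.05)
#>   local rejection rate:   1
#>   remote rejection rate:  0.032
#>   interaction gap:        0.968
```

Under local assessment the trial is perfectly separated and always rejects
the no-association null; under remote assessment the same number of
biological changes lands at random places across the arms and the rejection
rate stays within the 5% level.

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/placebosim trajectory --N 2 --half-width 0.5e-15 \
    --steps 200 --seed 1 --out runs/t1
Rscript inst/cli/placebosim fixed-points --N 2 --out runs/fp
Rscript inst/cli/placebosim trial --mode local --n 20 --seed 7 --out runs/tr
```

Each run writes its artifacts (CSV/JSON) plus a `manifest.json` with the
fully resolved configuration and seed; re-feeding a manifest via
`--config` reproduces the artifacts byte for byte.

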