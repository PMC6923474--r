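---
title: "Modelling NMDA receptor open-channel block and calcium-dependent desensitization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling NMDA receptor open-channel block and calcium-dependent desensitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdarblock)
```

## The problem

Amitriptyline (ATL) inhibits NMDA receptor (NMDAR) currents through two
separable mechanisms: voltage-dependent open-channel block of the pore by
the protonated (cationic) drug, and enhancement of Ca²⁺-dependent
desensitization triggered by Ca²⁺ entering the cytosol through the open
channel.  The experimental signatures are distinct.  Block produces a
concentration-dependent onset relaxation (`1/τ_on = k_on·[B] + k_off`), a
concentration-independent offset relaxation (`1/τ_off = k_off`), an IC₅₀
that grows e-fold per ~50 mV of depolarization (Woodhull behaviour for a
+1 charge at electrical depth δ ≈ 0.5), and trapping of the blocker when
the channel closes on it.  The desensitization pathway produces an IC₅₀
that falls steeply (roughly e-fold per 0.6–0.7 mM) as bath Ca²⁺ rises
from 0.25 to 4 mM, is abolished by loading the cell with the fast Ca²⁺
chelator BAPTA, and needs no membrane field to act.

This package provides the full quantitative workflow for such a study:
a deterministic kinetic simulator standing in for the recordings, the
per-trace measurements, and the model fits that turn those measurements
into mechanism-level parameters.

## The kinetic scheme

The simulator integrates the master equation of a five-state aggregated
scheme:

```
        C  <->  O  <->  D
                |
               OB  <->  CB
                         |
                         C   (escape, rate k_escape)
```

* `C -> O` at `beta_open_max·[NMDA]/([NMDA]+EC50)`; zero while AP5 is
  applied (complete competitive shutoff of activation).
* `O -> C` at `alpha_close`; `O -> D` at the desensitization rate below;
  `D -> O` at `k_rec`.
* `O -> OB` at `k_on(Vm)·[ATL]` with
  `k_on(Vm) = k_on0·exp(−δ·z·Vm/(RT/F))`: all of the voltage dependence
  of block is assigned to the on-rate, so
  `Kd(Vm) = (k_off0/k_on0)·exp(δ·z·Vm/(RT/F))` has exactly the Woodhull
  form.  `OB -> O` at the voltage-independent `k_off0`.
* `OB -> CB` at the closing rate (the gate shuts on the blocker —
  trapping); `CB -> OB` at the opening rate; `CB -> C` at `k_escape`
  (slow escape of the trapped blocker; 0 means full trapping).  Setting
  the blocked-state closing rate to zero (`alpha_close_blocked = 0`)
  instead yields a sequential ("foot-in-the-door") blocker, which cannot
  trap and generates a tail current on washout.

The desensitization rate is
`k_des0·ca_coupling·influx·(1 + gain·[ATL]/([ATL]+K))`, where
`influx = Ca_out·max(0, e_rev − Vm)/(e_rev + 70)` is a driving-force-
scaled surrogate for Ca²⁺ entry, normalized so it equals `Ca_out` at the
−70 mV reference holding potential.  Ca²⁺ acts from the cytosol, so a
BAPTA-loaded cell multiplies this rate by `bapta_factor`, 0 by default:
complete chelation, reflecting the observation that BAPTA loading
abolishes the Ca²⁺-dependent component.

Macroscopic current is `N·γ·(Vm − E_rev)·P(O)`, optionally with additive
Gaussian noise.  Solution exchange is a first-order lag
(`tau_exchange`, default 10 ms).  One deliberate exception: the AP5
field acts as an unlagged valve state.  A binary "shut while AP5 > 0"
gate combined with an exponentially decaying concentration would never
reopen (the lagged concentration never reaches exactly zero), which is
an artefact of combining a hard gate with a lag rather than a property
of the preparation.

## Parameter defaults and their calibration

| parameter | default | unit | rationale |
|---|---|---|---|
| `alpha_close` | 60 | 1/s | deactivation on the tens-of-ms scale |
| `beta_open_max`, `ec50_nmda` | 90, 30 | 1/s, µM | open probability ≈ 0.5 at 100 µM NMDA |
| `k_on0` | 3.99×10⁻⁴ | 1/(s·µM) | gives k_on(−70 mV) = 0.0016 with δ = 0.51 |
| `k_off0` | 0.204 | 1/s | measured dissociation rate; Kd(−70 mV) = 127.5 µM |
| `delta_block`, `z_block` | 0.51, 1 | — | e-fold IC₅₀ shift per ~50 mV |
| `k_des0·ca_coupling`, `k_rec` | 0.4, 0.5 | 1/s per mM, 1/s | visible sag to steady state over ~1 s |
| `atl_des_gain`, `atl_des_k` | 8.21, 3.02 | —, µM | calibrated (below) |
| `k_escape` | 0.2 | 1/s | partial trapping over seconds of washout |
| `n_channels_gamma`, `e_rev` | 24, 0 | pA/mV, mV | ~−500 pA plateau at −70 mV |
| `rt_over_f` | 25.7 | mV | room temperature |

The two desensitization-enhancement constants were calibrated once,
against the algebraic stationary distribution of the scheme (no
simulation in the loop), so that the steady-state IC₅₀ at −70 mV equals
63 µM in 0.25 mM Ca²⁺ and 0.72 µM in 4 mM Ca²⁺ — the ends of the
experimentally reported span.  Between those anchors the model's IC₅₀ is
strictly decreasing in bath Ca²⁺ but falls faster than the reported
intermediate means: the single saturable enhancement term has one
concentration scale, and no choice of its two constants reproduces all
five means at once.  A consequence worth knowing before comparing
fixtures with real data: at low Ca²⁺ the simulated inhibition curves are
biphasic (a desensitization component saturating by ~10 µM plus a block
component with Kd ≈ 127 µM), hence shallower than the experimental
single-Hill curves (fitted h ≈ 0.35 rather than ~1.4).

Presets bundle the study conditions: `rate_set()` is the full
calibrated model; `rate_set_pure_block()` switches desensitization and
escape off and speeds gating up (open probability 0.995) so the
macroscopic block obeys the two-state closed forms
`I_b/I_c = Kd/(Kd+B)` and `1/τ = k_on·B + k_off` within 1%;
`rate_set_trapping()` and `rate_set_sequential()` generate the trapping
and foot-in-the-door fixtures.  `rate_set_pure_block()` is voltage
independent by default, carrying the rates measured at the reference
holding potential (0.0016, 0.204); voltage-dependence studies pass
`delta_block = 0.51, k_on0 = 0.204/220` explicitly, which reproduces
IC₅₀(0 mV) = 220 µM with the 50 mV e-fold.

Two subtleties of the full (physiological-gating) model are deliberate
behaviour, not bugs.  First, with open probability ≈ 0.5 the macroscopic
relaxation method returns *apparent* rate constants scaled by the open
occupancy, so they differ from the microscopic `k_on0/k_off0` by a
factor ≈ 0.53; the steady-state IC₅₀ of the BAPTA condition still
equals the microscopic Kd, mirroring the experimental situation in which
kinetic and equilibrium estimates of Kd need not coincide.  Second, the
driving-force influx surrogate makes the desensitization component
weakly voltage dependent (effective δ ≈ 0.25 at 4 mM Ca²⁺, versus ≈ 1.1
at 0.25 mM where the block and influx gradients compound), so the
package's qualitative check is strong attenuation at high Ca²⁺ rather
than strict voltage independence.

## Measurements and fits

* **Steady state**: mean over the final 20% of an epoch (configurable),
  never nearer than three exchange time constants to the epoch edge,
  with a linear-drift steadiness criterion.  Baseline is the
  pre-agonist epoch mean; no rundown correction is applied.
* **Relaxations**: unweighted nonlinear least squares of
  `(I_max − I_min)·exp(−t/τ) + I_min`, initialized from the segment
  endpoints and the 1/e crossing.  Onset fits start three exchange
  time constants after the solution switch.
* **Test-pulse rise (trapping protocol)**: constrained double
  exponential `I₁·exp(−t/τ₁) + I₂·exp(−t/τ₂) − C` with
  `C = I₁ + I₂ + I_b`, `I_b` being the residual non-blocked current at
  the end of the blocker application.  Fast/slow labels are assigned by
  time-constant ordering; a τ ratio under 3 flags the components as
  degenerate and reports a single-exponential fallback.
* **Hill fits**: `1/(1 + ([B]/IC₅₀)^h)` parameterized in log₁₀(IC₅₀),
  h bounded to [0.3, 4].  Per-cell fits are aggregated as mean ± SEM
  across cells (matching per-cell symbols with mean ± SEM), not pooled.
* **Rate constants**: `k_on = (1/τ_on(C₂) − 1/τ_on(C₁))/(C₂ − C₁)`
  with the (10, 100) µM default pair, guarded to `C₂ ≥ 3·C₁`;
  `k_off = 1/τ_off`; `Kd = k_off/k_on`.
* **Voltage dependence**: least squares of log(IC₅₀) on Vm — the
  Woodhull model is exactly linear in log space and multiplicative
  scatter is homoscedastic there.  The calcium dependence
  `A·exp(−Ca/b)` is instead fitted unweighted on the *linear* IC₅₀
  scale, because that is the scale on which the condition means are
  conventionally summarized and refit.  The two choices are
  deliberately different.
* **Composite surface**: `prefactor·exp(a·Vm − Ca/b)` by least squares
  of log(IC₅₀) on (Vm, Ca); the prefactor can also be composed from the
  component fits as `IC₅₀(0 mV)·A/IC₅₀(Ca_ref)` with the reference
  calcium level passed explicitly.  The implied depth `a·(RT/F)/z` is
  reported alongside for comparison with the directly fitted δ.
* **Trapping analysis**: the fast-component fraction
  `I_f/(I_f + I_s)` per washout duration; escape is modelled as a
  single-exponential recovery `f∞ − (f∞ − f₀)·exp(−k·t)` with f∞ ≤ 1 —
  the minimal saturating form, since only a monotone trend is
  established experimentally.  Classification: a washout tail current ⇒
  sequential; otherwise a flat fraction (slope p > 0.05 or fitted
  recovery amplitude < 0.05) ⇒ full trapping; otherwise partial
  trapping; tail plus flat-but-incomplete recovery ⇒ indeterminate.
* **Statistics**: pooled-variance two-tailed t tests, one-way ANOVA
  with Bonferroni-corrected pairwise t tests (one family per
  comparison), SEM = sd/√n over cells, stars at 0.05/0.01/0.001/0.0001.
  Tests are unpaired throughout.

## Numerical choices

Integration uses a stiff solver (`deSolve::lsoda`) segment by segment
between solution breakpoints, with absolute tolerance 10⁻¹⁰ on the
occupancies; at segment boundaries the state is projected back onto the
probability simplex (negative excursions beyond −10⁻⁸ are an error).
Noise is plain white Gaussian at the output rate — the recording
chain's 200 Hz low-pass is not emulated.  Randomness is confined to the
noise stream and the per-cell lognormal jitter (conductance sd 0.25,
kinetic rates sd 0.08 by default); a single integer seed derives
per-cell streams by fixed offsets, and a noiseless trace is bit-for-bit
reproducible without any seed.  Sampling-rate defaults are chosen per
protocol kind (50 Hz for staircases and relaxations whose time
constants exceed 2 s; 400 Hz for the trapping protocol whose fast rise
is tens of ms).  The test suite and pipeline run on reduced designs —
2–3 cells per condition, 20-seed replicate loops — which keeps the full
suite around four minutes on one core; SEMs at these sizes are
correspondingly coarse.

## What the generator does and does not emulate

It emulates: staircase concentration–inhibition protocols with
within-application normalization; single-step block/unblock
relaxations; the trapping protocol (block, AP5 washout of stated
duration, test pulse); BAPTA-loaded cells; cell-to-cell lognormal
variability; recording noise.  It does not emulate: Mg²⁺ block or other
co-blockers, agonist-binding intermediates (activation is a single
lumped step, so rise times lack the sigmoidal delay of multi-step
binding), desensitized-blocked states, slow permeation of the blocker
through the pore, subunit heterogeneity, series-resistance or
liquid-junction artefacts (the measured −11 mV junction potential is
metadata only), or rundown.  Passing tests therefore demonstrate
internal consistency of the estimation pipeline against a generator
with known parameters — not that the scheme is the true mechanism of
any particular recording.

## Known limitations

* The five printed condition-mean IC₅₀s cannot all be matched by the
  one-scale saturable enhancement; only the span ends are anchored.
* Escape-rate recovery is unbiased only when desensitization is absent
  (the trapping presets); under the full model, recovery from
  desensitization during washout inflates a single-exponential escape
  fit.
* Apparent rate constants from macroscopic relaxations are
  occupancy-scaled under physiological gating (see above).
* The composite surface is fitted in log space; with strong
  multiplicative scatter the linear-scale and log-scale estimates of
  `b` differ by a few percent.
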