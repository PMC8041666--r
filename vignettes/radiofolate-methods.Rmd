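---
title: "Methods: dosimetry, efficacy and survival in radiofolate combination-therapy studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry, efficacy and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiofolate)
```

# Scope

`radiofolate` implements the quantitative backbone of a preclinical targeted
radionuclide therapy study in which a folate-receptor-targeted Lu-177
radioconjugate is combined with CTLA-4 checkpoint blockade in a syngeneic
breast-tumor mouse model. Four analysis stages are covered:

1. **Biodistribution bookkeeping** — %IA/g tables, decay correction, group
   summaries, receptor-blocking comparisons;
2. **Dosimetry** — time-integrated activity concentration coefficients
   (TIACCs), absorbed fractions from a self-contained electron Monte Carlo,
   and mean specific absorbed doses in Gy/MBq;
3. **Tumor efficacy** — relative tumor volume (RTV), tumor growth inhibition
   (TGI), tumor growth delay (TGD~2/5/8~) and its index (TGDI), and composite
   humane-endpoint rules;
4. **Survival** — Kaplan–Meier estimation, median survival with study-end
   censoring semantics, and the log-rank (Mantel–Cox) test, implemented from
   first principles.

Because per-animal raw data for such studies are rarely published, the
package ships a seeded synthetic cohort generator that reproduces the
*design* of a four-arm, n = 11/arm, 70-day study. It is first-class, tested
code: every pipeline stage is exercised on data whose ground truth is known.

# Dosimetry model

## Time-integrated activity concentration coefficient

For each source region the non-decay-corrected activity concentration
$a(t)$ (fraction of injected activity per gram) is integrated over all
time:

$$\tilde{a} = \int_0^\infty a(t)\,dt \quad [\mathrm{h/g}].$$

The measured points are integrated by the trapezoidal rule with the
convention $a(0) = 0$ and a linear rise to the first sample (activity needs
time to localise after injection; a flat back-extrapolation variant would
overestimate the early integral for receptor-mediated uptake). Beyond the
last sample an analytic exponential tail $a_{\text{last}}/\lambda_{\text{tail}}$
is added. The tail rate is either the physical decay constant
$\lambda_{\text{phys}} = \ln 2 / T_{1/2}$ or the log-linear slope of the last
two samples, **floored at** $\lambda_{\text{phys}}$: the effective
(biological + physical) clearance can never be slower than physical decay,
so a noise-induced rising terminal segment floors to the physical rate with
a warning. Trapezoid-plus-analytic-tail is the minimal-assumption standard
in preclinical dosimetry when the original fitting details are unpublished.

## Absorbed fraction Monte Carlo

Targets are unit-density spheres (tumor default 0.2 g; kidney default
0.3 g — one member of a mouse kidney pair; both configurable). Electrons are
started at uniformly sampled positions with isotropic directions; energies
are drawn from the Lu-177 beta spectrum, generated in code from
allowed-shape Fermi theory over the three main branches (endpoints 0.4983,
0.3849, 0.1766 MeV; intensities 79.4/9.0/11.6%). Transport is a
**straight-track continuous-slowing-down approximation** using the
Katz–Penfold range–energy relation for water,
$R = 0.412\,E^{\,1.265 - 0.0954\ln E}$ (g/cm², E in MeV): an electron whose
CSDA range fits within its chord to the surface deposits all of its energy;
otherwise it escapes with the energy corresponding to its residual range.
There is no scattering, bremsstrahlung or photon transport. For the soft
beta spectrum of Lu-177 in ≥ 0.1 g spheres this first-order transport is a
standard desk-scale surrogate for condensed-history codes; all testing of
$\varphi$ is property-based (limits, monotonicity in mass, energy
conservation, history-count self-consistency), never equivalence to a
specific production code.

Two asymptotic properties deserve explicit caveats, because they hold only
in the limit and not to within Monte Carlo precision at any finite size:

* **Containment**: even in a 10⁶ g sphere, electrons born within one CSDA
  range of the surface partially escape, so $\varphi \approx 0.9996$ rather
  than 1. The deficit is first order in $R_{\mathrm{CSDA}}/R_{\mathrm{sphere}}$
  and is a real feature of any transport model.
* **Vanishing target**: a 10⁻⁹ g sphere (radius ≈ 6 µm) still stops the
  low-energy tail of the spectrum entirely and extracts
  stopping-power × chord from faster electrons, giving
  $\varphi \approx 0.02$, small but strictly positive.

The reported Monte Carlo standard error is the delta-method error of the
energy-weighted ratio $\sum d_i / \sum E_i$.

## Dose coefficients

$$\mathrm{Gy/MBq} = \tilde{a}\,[\mathrm{h/g}] \times 3.6\times10^{9}\,
\tfrac{\mathrm{decays}}{\mathrm{MBq\,h}} \times \bar{E}_{e}\,[\mathrm{MeV}]
\times 1.602\times10^{-13}\,\tfrac{\mathrm{J}}{\mathrm{MeV}} \times \varphi
\times 10^{3}\,\tfrac{\mathrm{g}}{\mathrm{kg}}$$

with $\bar{E}_e = 0.1479$ MeV per decay (mean beta energy 0.1333 MeV plus
conversion/Auger electrons, standard compilations; overridable). Photons are
excluded from the local dose: at mouse-organ scale Lu-177 photon absorbed
fractions are negligible next to the electron term. Using the beta-only
spectrum for $\varphi$ while scaling by the total electron energy assumes
conversion/Auger electrons are absorbed like the average beta — conservative
for those short-range emissions. %IA/g values live on the percent scale
everywhere in the package; conversion to fraction happens once, inside
`build_curve()`.

# Efficacy statistics

* **RTV**: $V(t)/V(0)$ per mouse; a disappeared tumor has RTV 0.
* **TGI** at evaluation day $d$:
  $\mathrm{TGI}_i = 100 - \mathrm{RTV}_{T,i}/\overline{\mathrm{RTV}}_C \times 100$
  per treated mouse, summarised as mean ± SD. Evaluating per mouse against
  the control-arm *mean* is what reproduces a "mean ± SD" presentation
  (including negative values for mice outgrowing the average control); the
  textbook formula alone does not fix this, so it is an explicit design
  choice. The evaluation day defaults to the day the first control mouse
  reaches the humane endpoint, with a study-end fallback.
* **TGD~x~**: first crossing of RTV = x (x = 2, 5, 8), log-linearly
  interpolated between bracketing measurement days (exponential growth
  between calipers; linear interpolation available). Whether to interpolate
  at all was an open choice; interpolation is the default because
  integer-day crossings otherwise quantise small delays away.
* **TGDI~x~**: ratio of arm-level TGD~x~ (median across mice; mean
  available) over the control arm. Mice that never reach the fold are
  assigned the study-end day as a censored lower bound and flagged — never
  dropped, because dropping responders would bias the index downward.
* **Endpoint rule**, checked in fixed order: (i) volume ≥ 1000 mm³,
  (ii) body-weight loss ≥ 15%, (iii) volume ≥ 800 mm³ together with loss
  ≥ 10%, (iv) ulceration, (v) abnormal behavior. The reason reported for a
  day on which several criteria hold is the first in this order.

# Survival analysis

The product-limit estimator, median rule and log-rank test are implemented
from first principles so their conventions match exactly: aggregate-$d_i$
steps at tied event times, hypergeometric variance with the $({n_j - d_j})/({n_j - 1})$
tie correction, censored times reducing risk sets without steps. Animals
euthanised for any endpoint reason are events; only study-end survivors are
censored. The median is the smallest observed time with $S(t) \le 0.5$;
when more than half an arm survives to day 70 the median is reported as the
sentinel "> 70" rather than a number. Pairwise log-rank comparisons are
unadjusted by default (matching conventional preclinical reporting), with
Holm adjustment one flag away.

The implementation is cross-checked in the test suite against
`survival::survdiff`/`survfit` (agreement to ~1e-10) and against a
brute-force permutation null. Note a small-sample caveat: at n = 12 the
asymptotic $\chi^2_1$ p-value differs from the exact permutation null by a
few percent (anti-conservative); this is the well-known $O(1/n)$ error of
the asymptotic reference distribution, not an implementation artifact.

# Synthetic data generator

## What it emulates

* **Biodistribution**: per-organ kinetics
  $a(t) = A\,(1 - e^{-k_{\mathrm{up}}t})\,e^{-k_{\mathrm{bio}}t}$
  (decay-corrected), groups of 4 mice sacrificed at {1, 4, 24, 48, 120} h,
  multiplicative lognormal measurement noise (CV 10% — typical γ-counting
  plus dissection variability; concentrations are positive and CV-stable,
  hence lognormal rather than additive Gaussian). Amplitudes are calibrated
  in closed form so the kidney template reads exactly 18 %IA/g at 4 h and
  the tumor template peaks at exactly 12 %IA/g between 4 and 24 h.
  A folic-acid-blocked group at 4 h scales receptor-specific organs by
  blocking factors 0.50 (tumor) and 0.35 (kidneys).
* **Therapy cohort**: four arms, n = 11, daily measurements over 70 days.
  Tumor growth is piecewise exponential — the paper-style RTV/TGD
  definitions presuppose approximately exponential growth, and exponential
  is the minimal model consistent with them; baseline volumes are lognormal
  with the arm means/SDs of the study design (110 ± 51, 71 ± 44, 98 ± 75,
  88 ± 67 mm³), growth rates are lognormal across mice (median 0.19/day,
  CV 20%). Treated arms get a growth-arrest delay; responders (drawn with
  arm-specific probability, 8/11 for the combination arm) regress
  exponentially, disappearing entirely when cured (7/8 of combination
  responders) or plateauing at 20% of baseline otherwise. Body weight is a
  Gaussian random walk; ulceration is a constant daily hazard while the
  tumor measures ≥ 300 mm³ (ulceration is a large-tumor phenomenon — an
  ungated hazard would dominate endpoint reasons and kill slowly regressing
  responders, contradicting the design being emulated).

Growth parameters were calibrated once, before the test suite was frozen,
against three qualitative anchors of the emulated design — first control
endpoint near day 8, control median survival ≈ 12 days, majority of the
combination arm alive at day 70 — and are not revisited. The published TGI
values and single-agent medians are *not* calibration targets: without
per-animal data they are not reproducible, and the generator makes no claim
of matching them.

## Seeding

One master seed drives everything. Each mouse draws from a deterministic
substream keyed by (master seed, arm label, mouse index), so enlarging an
arm or adding an arm never perturbs existing trajectories; identical
(parameters, seed) pairs are byte-identical.

## What it does not emulate

No immune mechanism (responder status is a coin flip, not a CD8⁺ model), no
caliper-formula geometry (volumes are emitted directly in mm³), no
measured-frequency fidelity (daily measurements are assumed), no
inter-organ correlation in biodistribution noise. Passing tests therefore
demonstrate that the *statistics pipeline* is correct and well calibrated
on data with known truth — not that the generator is a faithful biological
model.

# Problem sizes and numerical choices

The default test and acceptance runs use 10⁵–2×10⁵ Monte Carlo histories
per absorbed fraction (MC SE on $\varphi$ ≈ 7×10⁻⁴ at 10⁵ histories for a
0.2 g sphere), 100 simulated cohorts of 44 mice for stochastic properties,
and 10⁴ draws for permutation nulls — sizes chosen so the full suite
completes in a few minutes on a laptop while keeping Monte Carlo error well
below the tolerances being asserted. Degenerate inputs are rejected early:
empty organ lists, non-positive injected activity, missing day-0
measurements, all-zero activity curves, non-positive survival times; a
log-rank comparison with zero events in both arms returns `NA` with a
warning rather than an error, since downstream pairwise tables should
degrade gracefully.

# Known limitations

* The CSDA Monte Carlo ignores scattering and delta rays; its $\varphi$ is
  a first-order surrogate, adequate for ranking and for Gy-scale dose
  coefficients at mouse scale, not for sub-percent dosimetry.
* The asymptotic log-rank p-value is anti-conservative by a few percent at
  n ≤ 12 per the permutation comparison above; for confirmatory analyses at
  these sizes an exact/permutation p should be preferred.
* The generator's piecewise-exponential growth has no Gompertz deceleration;
  large-tumor kinetics near the 1000 mm³ endpoint are therefore slightly
  fast. A Gompertz variant is a natural extension point.
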