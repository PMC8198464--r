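---
title: "Analysing Langmuir monolayer experiments with langmuirkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing Langmuir monolayer experiments with langmuirkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmuirkit)
```

`langmuirkit` implements the analysis chain of a classical
nanoparticle–membrane interaction study on a Langmuir trough: isotherm
thermodynamics, dilatational rheology, penetration kinetics, and
Owens–Wendt surface energetics, together with synthetic-data generators
that give every stage a closed-loop oracle. This vignette is the package's
account of the science behind each stage: the models, the tunable
parameters and why their defaults are what they are, the numerical
choices, and what the synthetic tests do and do not demonstrate about
laboratory data.

## The physical setting

A Langmuir monolayer is a one-molecule-thick amphiphile film at the
air–water interface, compressed by movable barriers while a Wilhelmy plate
records the surface pressure π (mN·m⁻¹) — the reduction of the water
surface tension caused by the film. Plotted against the mean molecular
area A (nm² per phospholipid molecule), the compression trace is the π–A
isotherm. DPPC, the workhorse zwitterionic lipid of model-membrane work,
shows the textbook sequence: a gas/liquid-expanded (LE) region, a nearly
horizontal LE–liquid-condensed (LC) coexistence plateau, a steep LC
branch, and collapse. Nanoparticles mixed into the spread film expand the
isotherm, tilt and shorten the plateau, and shift the condensed branch —
which is exactly the signature the analysis chain is built to quantify.

## Isotherm analysis

### Per-molecule normalisation

`mean_molecular_area()` converts trough area to area per phospholipid
molecule: the molecule count is
`V·c·(1 − X_W)/M · N_A`, with the deposit volume `V`, mixture
concentration `c`, phospholipid molar mass `M` (default DPPC, 734.04
g·mol⁻¹) and the nanoparticle weight fraction `X_W` excluded from the
count. Normalising per lipid rather than per total mass is what makes
isotherms at different `X_W` directly comparable.

### Compression modulus

The compression modulus `C_s⁻¹ = −A·dπ/dA` is computed by three-point
Lagrange differences on the actual area grid, with two-point one-sided
differences at the boundaries. Central differences were chosen over spline
differentiation deliberately: a smoothing or interpolating spline
oscillates near the sharp plateau knots of real (and of the synthetic)
isotherms, and those oscillations masquerade as spurious phase structure.
The scheme is exact for quadratics on arbitrary grids; the test suite
checks it against symbolic derivatives (linear, quadratic and ideal-gas
π = c/A isotherms, for which C_s⁻¹ = π identically) to 10⁻⁶ relative
error away from the boundaries.

Differentiation amplifies noise, so noisy isotherms should first pass
through `smooth_isotherm()`, a local-polynomial (Savitzky–Golay-type)
filter that fits each window with the true abscissae — irregular grids are
therefore handled exactly, and on uniform grids it reproduces the
classical filter (the suite cross-checks against `signal::sgolayfilt`).
Window 11 / order 2 is a light default for plotting; for transition
detection at sensor-level noise (0.05 mN·m⁻¹) we use window 41 / order 3,
wide enough to bring the derivative noise well below the coexistence
threshold while remaining much shorter than the ~120-sample plateau.

### Phase classification

`classify_phase()` implements the Davies–Rideal modulus ranges with the
interval convention *lower bound inclusive*: below 12.5 mN·m⁻¹ gaseous
region, [12.5, 50) LE, [50, 100) liquid, [100, 250] LC, and strictly above
250 solid — the source criterion says "more than 250" for the solid state,
which pins the open boundary there; the other boundaries are not assigned
in the literature and the inclusive-lower convention is ours. Negative
moduli are flagged `"unstable/artifact"` rather than classified.

### Transition detection

Minima of the C_s⁻¹–π curve mark phase transitions. `detect_transitions()`
finds the deepest interior local minimum below the coexistence threshold
(default 50 mN·m⁻¹, the LE upper bound), flanked by the two principal
maxima of the LE and LC branches, and walks outward from the minimum to
the first samples at or above the threshold; the samples just inside bound
the coexistence interval, giving the entry pressure π′_C (reported as the
plateau onset π_C, with A_C the area there) and the exit pressure π″_C.
Two robustness choices deserve note:

* **Effective threshold.** For films whose LE maximum never reaches 50
  mN·m⁻¹ (pure DPPC peaks near 31) a literal below-50 interval would
  extend to the lift-off region. The effective bound is therefore
  `min(50, midpoint of plateau floor and branch maximum)`, which always
  intersects the steep knot flank; because that flank spans only a couple
  of samples, the entry estimate is insensitive to the exact bound.
* **Entry/exit definition.** π′_C/π″_C are read from the C_s⁻¹ curve, not
  from curvature sign changes of π(A); the modulus-based definition
  survives noise far better because it only requires crossing a large
  threshold gap. Both interpretations coincide for the piecewise synthetic
  model.

A plateau whose detected width π″_C − π′_C is below `plateau_tol`
(0.5 mN·m⁻¹) is reported as a single (A_C, π_C) point — the
nearly-horizontal pure-DPPC case — with the raw entry/exit values still
available as `pi_entry`/`pi_exit`. A monotone modulus curve (no interior
minimum, e.g. a strictly linear isotherm) yields a report with the
transition fields absent rather than an error. The minimum search also
ignores pressures below `pressure_floor` (2 mN·m⁻¹), excluding the
trivial low-modulus region near lift-off; the floor only needs to sit
below any plausible transition pressure (the studied films sit at
5–12 mN·m⁻¹).

### Extrapolated area and shifts

`A_EXT` extrapolates the "first linear slope" of the isotherm to π = 0.
"First linear slope" is not a sharply defined object, so it is
operationalised: a least-squares line over the first contiguous run of
points whose pressure lies inside a window, by default
[0.3, 0.9] × the plateau-onset estimate. On the quadratic LE branch of the
synthetic model the fitted line depends (weakly) on that window — a
window hugging the onset approaches the analytic tangent through
(A_C, π_C), which crosses zero at 0.895 nm² for the DPPC defaults — but
*differences* of A_EXT between films fitted with the same relative window
are window-independent, which is why the composition effect (the 0.19 and
0.14 nm² expansions) is recovered to well under a percent. Fits with
fewer than 5 points or R² below 0.98 carry a low-confidence warning;
a non-negative slope is an error (wrong branch).

`isotherm_shift()` inverts each isotherm at a common pressure by linear
interpolation and refuses pressures on a coexistence plateau, where the
inverse is ill-conditioned; the guard is a local |dA/dπ| bound (default
0.1 nm² per mN·m⁻¹, an order of magnitude above the LE/LC branch values
and an order below the plateau's).

## Dilatational rheology

The oscillating-barrier experiment imposes
`A(t) = A₀(1 + u·sin 2πft)` with small `u` (1 % in the reference
protocol; the package caps `u` at 5 % to stay in the linear regime —
"1 %" is read as the peak amplitude, half the peak-to-peak excursion)
and records π(t). The complex modulus follows the defining relation
`δπ = −E·δA/A`. `fit_harmonic()` performs least-squares demodulation at
the known barrier frequency — chosen over an FFT bin because it is exact
for non-integer cycle counts and short records — and
`viscoelastic_moduli()` forms `E = −z_π/z_x` from the two harmonic
phasors `z = a_sin + i·b_cos`. The sign convention makes an ideally
elastic film (π in exact antiphase with area) have phase 0 and E″ = 0,
and a purely viscous film phase π/2; phases beyond π/2 are flagged as
non-physical (usually a sign or frequency mismatch). The estimate is
invariant under pressure offsets and area rescaling, so relative area
traces work unchanged.

Rest intervals between oscillation bursts (the protocol pauses 60 s
between cycles) appear as gaps in the time grid; each burst is fitted
separately and moduli averaged, with the spread across bursts reported.
The first cycle of each burst is discarded as a mechanical transient
whenever at least three full cycles remain — whether published sweep
values are burst means is generally not stated, so this replicate handling
is a documented package choice. An optional ±5 % frequency refinement
(golden-section on residual sd) covers miscalibrated metadata; it is off
by default because the barrier drive frequency is normally trusted.

Noise-free closed-loop recovery is exact to 10⁻⁸ relative over the grid
E′ ∈ [10, 120], E″ ∈ [0, 30] mN·m⁻¹, f ∈ [20, 140] mHz; at pressure noise
0.05 mN·m⁻¹ the estimator is unbiased to well under 0.5 mN·m⁻¹ over 100
seeds (the quadrature standard error at 10 × 64 samples is ≈0.28 mN·m⁻¹
per fit).

## Penetration kinetics

`delta_pi()` interpolates the simultaneous penetration and reference
traces onto the union of their sample times inside the overlap (at least
80 % of the shorter trace is required) and differences them. No smoothing
is applied before differencing: the differential measurement itself is the
drift filter — any ramp common to both troughs cancels identically, which
is the purpose of running the reference in parallel. Time zero is the
injection instant.

`adsorption_summary()` reports the raw interpolated value at 360 min (the
6 h endpoint of the reference protocol; whether published endpoints are
raw or smoothed readings is not stated, and raw is the default here) and
fits `Δπ_max(1 − e^{−kt})` by bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, positivity bounds, initialised from the final value
and the time to half-final). The saturation fit is an *added* summary —
endpoint values are the primary readout — and it is skipped for flat
series (degenerate) and for negative-trending series, which indicate
extraction of lipid from the interface and are summarised by their
minimum instead. A non-convergent fit leaves the fit fields absent with a
diagnostic; the endpoint is still reported.

## Owens–Wendt surface energy

With two probe liquids of known components the Owens–Wendt relation
linearises in `x = √γ_d`, `y = √γ_p`:
`γ_L(1 + cos θ)/2 = x·√γ_L^d + y·√γ_L^p`, one equation per liquid. Two
liquids give an exact solve; more give least squares on the same
linearisation (an extension beyond the two-liquid protocol). A purely
dispersive liquid set leaves the polar component unidentifiable; the
corresponding column is dropped and the component fixed at zero rather
than declaring the system singular — the singularity error is reserved
for genuinely proportional component rows. Negative roots, which arise
from noisy angles near a component's zero, are clamped to zero with a
prominent flag instead of erroring, so batch runs complete; roots within
numerical noise of zero are clamped silently.

Uncertainties come from a seeded bootstrap over drop angles (default 2000
resamples) rather than first-order propagation, because the square of a
near-zero root is decidedly non-Gaussian. Drop sets with fewer than 10
angles per liquid are flagged as below the measurement protocol but not
rejected. The probe-liquid table is user-editable; the defaults are
literature component sets for glycerin (63.4 = 37.0 + 26.4 mJ·m⁻²) and
diiodomethane (50.8, purely dispersive), since protocols name the liquids
but rarely their components.

## The synthetic-data generators

The generators define the package's study conditions; they are calibrated
once and are not tuning knobs.

**Isotherms.** No functional form for π(A) is dictated by thermodynamics
alone, so the reference model is chosen for analytic tractability: zero
above lift-off, a quadratic LE branch
`π = π_C·((A_lift − A)/(A_lift − A_C))²`, a linear tilted plateau, and a
linear LC branch capped at collapse. Tangents and knots then have closed
forms, which is what makes the A_EXT and transition oracles exact. The
pure-DPPC defaults are `A_lift = 1.02`, `A_C = 0.77` nm², `π_C = 5`
mN·m⁻¹, plateau end 0.55 nm², tilt 0.5 mN·m⁻¹, LC slope 250 mN·m⁻¹·nm⁻²,
collapse 55 mN·m⁻¹ — the plateau coordinates are the published DPPC
values, the rest are realistic free choices fixed once. Binary films add
a uniform LE-branch expansion `ΔA_LE`, a raised onset pressure, and a
signed condensed-branch shift `ΔA_LC`, blended linearly in pressure
across the plateau; at X_W = 0.36 the native-starch film uses
(0.19 nm², 12 mN·m⁻¹, −0.05 nm²) and the aminated-starch film
(0.14 nm², 10 mN·m⁻¹, +0.05 nm²), with deviations scaled linearly in
X_W/0.36 at other compositions. The binary plateau end is placed so that
the condensed branch is colinear with the base DPPC branch before the
shift, making the high-pressure displacement equal `ΔA_LC` exactly — the
squeeze-out signature in its cleanest form. Isotherm noise level and
sampling density are not reported by trough vendors in any standard way;
the defaults (Gaussian sd 0.05 mN·m⁻¹, 400 points) are stated choices,
not inferences.

**Oscillation traces** realise the linear viscoelastic response for given
(E′, E″) with no dispersion — E(f) constant — which is deliberate: it
makes flat-sweep behaviour a testable property. The calibrated
composition series (`default_film_moduli()`) mirrors the qualitative
trends of the study system — elastic films with E′ ≫ E″, E′ falling as
X_W grows, E″ flat for native-starch films and slightly falling for
aminated ones — with the numeric values as free calibration choices.

**Penetration pairs** use Δπ_max = 7.3 and 4.32 mN·m⁻¹ (both with
k = 0.01 min⁻¹), chosen so the noise-free 6 h endpoints reproduce the
published 7.1 and ≈4.2 mN·m⁻¹ for the aminated- and native-starch
scenarios respectively. Noise is independent between the troughs; a
common drift can be added and must cancel.

**Contact angles** are drawn around the exact inverse Owens–Wendt Young
angle, clipped to (0°, 180°); the ground-truth surfaces are the published
polymer component sets (starch 28.8 + 5.6, aminated starch 26.1 + 18.0
mJ·m⁻²). Infeasible solid/liquid combinations (cosine outside [−1, 1])
error naming the liquid.

All noise is Gaussian and independent per sample; seeds are explicit
arguments everywhere and never global state, and identical parameters
plus seed give bit-identical output.

### What passing the synthetic tests does and does not show

The generators emulate the *signal structure* of the instrument outputs:
piecewise-smooth isotherms with a coexistence plateau, harmonic pressure
responses, exponential adsorption over a drifting baseline, Gaussian drop
angles. They do not emulate correlated sensor drift within one trace,
barrier-speed hysteresis, film leakage or collapse dynamics, nonlinear
(higher-harmonic) rheology, Vroman-type competitive adsorption, or
drop-shape fitting errors that correlate across drops. Closed-loop
success therefore demonstrates that the estimators are correct and
well-conditioned for data of the assumed structure, not that laboratory
artifacts cannot bias them; the low-confidence flags, residual
diagnostics and plateau guards exist precisely because real traces
violate the clean model in these known ways.

## Problem sizes and runtime

The shipped tests and the acceptance script run the chain at the sizes a
desk analysis would use: 400-point isotherms (4001-point grids only for
the derivative-oracle checks), 10-cycle oscillation records at 64 samples
per cycle, 361-sample six-hour kinetics, 10 drops per liquid, 100–200
noise seeds for the bias properties and 500–2000 bootstrap resamples.
Everything completes in seconds on one core.

## Known limitations

* No equation-of-state thermodynamics (van der Waals/Volmer), no
  excess-area or excess-Gibbs-energy miscibility analysis, and no
  collapse-pressure analysis.
* Rheology is strictly linear: no Lissajous analysis, higher-harmonic
  distortion metrics, or Maxwell/Lucassen frequency-domain model fits.
* Penetration analysis stops at the differential trace and the saturation
  summary: no diffusion-limited (Ward–Tordai) modelling and no
  maximum-insertion-pressure analysis across initial pressures.
* Surface energetics is Owens–Wendt only (no Zisman or van Oss
  acid–base), and angles are taken as given numbers — drop-shape image
  analysis is out of scope.
* Transition detection assumes a single coexistence plateau; films with
  multiple reorganisation minima report only the deepest.
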