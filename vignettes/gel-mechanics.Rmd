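---
title: "Large-deformation mechanics and nonlinear rheology of biopolymer gels with gelmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-deformation mechanics and nonlinear rheology of biopolymer gels with gelmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmech)
```

## Scope

`gelmech` is a desk-scale pipeline for the large-deformation mechanics of
hydrocolloid gels, with agarose-xanthan mixtures as the motivating system.
Four measurement modalities are covered, each paired with a synthetic-data
generator that emulates the corresponding instrument with known ground truth:

* **Ring tensile and compression tests** (texture analyzer): force-displacement
  records are converted to engineering and true stress-strain curves, Young's
  modulus, an elastic/plastic strain split, and a failure point.
* **Johnson-Cook plasticity and damage** (constitutive modelling): forward
  evaluation, parameter fitting, and a strain-driven material-point tensile
  simulator.
* **LAOS** (rheometer): odd-harmonic Fourier decomposition of oscillatory
  stress waveforms, Lissajous-Bowditch loops, nonlinearity metrics, and
  detection of the linear viscoelastic region.
* **DIC** (camera): subset-based digital image correlation on speckle image
  pairs, yielding displacement and strain fields and a strain-concentration
  index.

No instrument data ships with the package; every analysis is validated by
round-trip recovery of generator ground truth. What that does and does not
demonstrate is discussed at the end.

## Ring tensile mechanics

A gel ring hangs between two pins; the top pin rises at constant speed (1 mm/s
by default) until the specimen snaps. The ring geometry avoids gripping damage
— the perennial failure mode of dog-bone specimens cut from soft gels. With
pin separation increased by $\Delta s$, both straight segments of the oval
lengthen, so the inside circumference is

$$C_i = C_0 + 2\,\Delta s, \qquad D_i = C_i / \pi,$$

and, treating the stretched ring as a thin-walled pressure-vessel wall
(Laplace's law for the circumferential stress),

$$\sigma_r = \frac{F}{w\,D_i}, \qquad
  \varepsilon_r = \frac{C_i - C_0}{C_0}.$$

Because gels fail at strains of order 0.1, the engineering measures are
converted to true stress and strain before any constitutive work:

$$\sigma_\mathrm{true} = \sigma_r (1 + \varepsilon_r), \qquad
  \varepsilon_\mathrm{true} = \ln(1 + \varepsilon_r).$$

Young's modulus is the origin-anchored least-squares slope over the initial
linear region, taken by default as the first 40 % of the pre-failure strain
range (`linear_fraction`, configurable; the choice only matters when yielding
encroaches on the window). The strain split follows
$\varepsilon_\mathrm{elastic} = \sigma_\mathrm{true}/E$,
$\varepsilon_\mathrm{plastic} = \varepsilon_\mathrm{total} -
\varepsilon_\mathrm{elastic}$, with yield flagged at the first sample whose
stress deviates from the elastic line by more than 2 % relative
(`yield_tol`).

**Failure** is distinguished from gradual fracture: the detector returns the
first local stress maximum followed by a drop exceeding 50 % of the peak
(`drop_fraction`). Peaks below 10 % of the global maximum are ignored
(`min_peak_fraction`) so that force noise around zero stress early in a run
cannot masquerade as failure. A curve with no qualifying drop is *censored*
and the global maximum is reported.

Compression uses the elementary $\sigma_c = F/A$, $\varepsilon_c = \Delta L/L$
on a 25.4 mm diameter, 20 mm tall cylinder by default.

```{r ring-example}
geom <- ring_geometry()          # d = 6 mm, C0 = 60 mm, w = Tr = 5 mm
mat  <- calibrate_ring_material(2.65e6, 0.08, geom)   # pure agarose target
rec  <- generate_ring_tensile_record(mat, geom)
ana  <- analyze_ring_record(rec, geom)
c(stress_MPa = ana$failure$failure_stress / 1e6,
  strain     = ana$failure$failure_strain,
  E_MPa      = ana$youngs_modulus / 1e6)
```

### Geometry defaults

The specimen dimensions are not fixed by any published number, so the
defaults ($C_0$ = 60 mm, $w = T_r$ = 5 mm, pin diameter 6 mm) are chosen as a
plausible bench-top ring and are all overridable. Width and thickness are
held constant during the test: measured dimension changes in gel rings are
below 0.5 mm and negligible against the 5 mm width. Sampling defaults to
50 samples/s, matching a 50 fps video record of the same test.

## Johnson-Cook plasticity and failure

Post-yield flow stress follows the reduced (isothermal) Johnson-Cook law

$$\sigma = \left(A + B\,\varepsilon_p^{\,n}\right)
           \left(1 + C \ln \frac{\dot\varepsilon_p}{\dot\varepsilon_0}\right),$$

with initial yield strength $A$, hardening modulus $B$, hardening exponent
$n$, rate sensitivity $C$ and reference rate $\dot\varepsilon_0$. The thermal
softening bracket of the full law is disabled throughout: frictional heating
in a gel stretched at 1 mm/s is negligible. Ductile failure accumulates
damage

$$D = \int \frac{d\varepsilon_p}{\varepsilon_f}, \qquad
  \varepsilon_f = \left(d_1 + d_2 e^{-d_3\,\sigma_m/\bar\sigma}\right)
                  \left(1 + d_4 \ln \frac{\dot\varepsilon_p}{\dot\varepsilon_0}\right),$$

with failure at $D = 1$. The trailing temperature factor of the
fracture-strain law is fixed at 1; `d5` is stored but inert. The damage flag
trips at $D \ge 1 - 10^{-9}$ so that increments summing to one analytically
are not defeated by floating-point accumulation.

### Material-point simulator

The published workflow embeds this law in a 3-D explicit-dynamics finite
element model; `simulate_tensile()` replaces that with a strain-driven
material point, which preserves everything the constitutive law itself can
express (the uniaxial stress-strain curve and failure point) while dropping
the spatial field. Integration is explicit in strain (default step $10^{-3}$)
with an implicit return mapping per step: the elastic predictor
$\sigma = E(\varepsilon - \varepsilon_p)$ is relaxed onto the hardening
surface by a bracketed root solve. Three numerical choices deserve note:

* The rate bracket is evaluated at the *nominal applied strain rate* rather
  than the per-step plastic rate. With the plastic rate the law has no yield
  threshold at all (the logarithm drives the flow stress to $-\infty$ as the
  increment vanishes), which makes yield onset ill-posed; at the rates and
  $C = 0.01$ typical of gels the two conventions differ by well under 0.1 %
  post-yield, and the nominal-rate form keeps the pre-yield response exactly
  elastic.
* For $n$ near zero (measured value 0.00067 for pure agarose) the hardening
  curve is near-vertical at $\varepsilon_p = 0$; a consistency root below
  $10^{-12}$ strain is treated as an elastic step.
* Damage increments use the harmonic mean of the fracture strain at the step
  endpoints, making the accumulated $D$ the exact trapezoidal integral of
  $1/\varepsilon_f$ along the plastic path. Rates below
  $\dot\varepsilon_0 e^{-1/C}$ would drive the bracket negative; the bracket
  is floored (default 0.05) with a warning, a regime no gel test reaches.
* Triaxiality is fixed at 1/3, uniaxial tension; the 3-D field variation a
  finite element model would supply is out of scope.

### Parameter fitting

`fit_hardening()` estimates $(A, B, n)$ from true stress vs plastic strain
at the reference rate by variable projection: for each candidate $n$ the
conditionally linear $(A, B)$ are profiled out by least squares (constrained
non-negative), and $n$ is located by golden-section search on $\log n$, then
polished with Levenberg-Marquardt. A joint three-parameter descent fails
where this succeeds: at $n \approx 10^{-3}$ the Jacobian is numerically
singular, while the profiled search recovers noiseless parameters to
$10^{-8}$ relative for all three gel parameter sets. Callers should know the
statistical limit too: for $n \lesssim 0.1$ the regressor
$\varepsilon_p^{\,n}$ is nearly collinear with the intercept, so under 1 %
stress noise $A$ individually carries roughly 10 % uncertainty even though
the fitted curve stays accurate to well under 1 %. The tests assert exactly
that behaviour rather than an unattainable pointwise claim.

`fit_damage()` fits $(d_1, d_2, d_3, d_4)$ to observed fracture strains by
Levenberg-Marquardt, with identifiability guards rather than silent fits:
$d_3$ requires at least two distinct triaxialities, $d_4$ at least two
distinct rates, and anything unidentifiable must be frozen explicitly via
`fixed`. Identifying the full exponential triplet $(d_1, d_2, d_3)$ well in
practice takes three or more triaxiality levels.

## The synthetic-data generators

The generators declare their forward models to be exactly the laws the
pipeline fits; this self-consistency is by construction and stated openly —
it makes recovery tests well-posed, and it is the standard device when no
raw instrument data are published.

* **Ring tensile**: strain path from the pin kinematics, elastic /
  Johnson-Cook true stress integrated along it, damage-terminated, inverted
  to force through the Laplace geometry ($F = \sigma_\mathrm{true} w C_0 /
  \pi$, which the reader can verify is the product of the engineering stress
  and the instantaneous $w D_i$). Gaussian force noise is scaled to the peak
  noiseless force.
* **Calibration to a failure target**: `calibrate_ring_material()` builds a
  material whose noiseless record fails at a prescribed engineering stress
  and strain. The elastic modulus is set so that the plastic part of the true
  failure strain is 40 % of the total (`plastic_fraction`), yield begins at
  60 % of the true failure stress (`yield_fraction`), $B$ is solved so the
  hardening curve passes through the failure point at the test rate, and the
  fracture strain is the constant $d_1$ equal to the plastic strain at
  failure. The published per-gel moduli are deliberately *not* forced here:
  gel stress-strain curves strain-harden (convex), so at the measured
  failure points the secant stiffness exceeds the initial modulus, which no
  elastic/Johnson-Cook material (whose post-yield tangent is below $E$) can
  reproduce with the published $E$ values. The calibrated modulus is the
  package's own consistent choice; the published $E$, $A$, $B$, $n$ sets are
  exercised separately by the fitting and simulation tests.
* **Compression**: a two-parameter convex law $\sigma = k_1\varepsilon +
  k_2\varepsilon^p$ ($p = 2$, initial slope 30 % of the secant to the failure
  point), matching the qualitative strain-hardening shape of measured gel
  compression curves, with a 60 % stress drop at the configured failure
  strain and a plateau out to 80 % strain.
* **LAOS**: $\gamma = \gamma_0 \sin\omega t$ and
  $\sigma = \gamma_0\,(G'\sin\omega t + G''\cos\omega t + e_3\sin 3\omega t
  + v_3\cos 3\omega t)$ plus noise. The third-harmonic coefficients are
  *moduli* (multiplied by $\gamma_0$), so decomposition returns them in
  their own units and sign convention.
* **Speckle pairs**: dark Gaussian blobs on a light background, quantized to
  8 bits, deformed by an affine map about the image centre. Both images are
  rendered analytically — the deformed image evaluates the blob field at
  inverse-mapped coordinates — so there is *no* interpolation error anywhere
  and the ground-truth displacement field is exact. This replaces the more
  common rasterize-then-warp recipe; it is stronger for validation because
  measured errors are attributable entirely to the correlation algorithm.

All generators are bitwise reproducible under a fixed seed, and noiseless
outputs are seed-independent.

## LAOS analysis

Harmonic decomposition discards the first cycle as transient and projects the
stress onto $\sin k\omega t$, $\cos k\omega t$ for odd $k$ over the remaining
integer number of cycles. For uniformly sampled band-limited signals over
full cycles the rectangle-rule projection is exact, which is why linear
moduli and configured third harmonics are recovered to $10^{-9}$ relative
rather than merely "closely". Requests beyond the Nyquist harmonic or on
non-integer cycle counts are errors, not approximations.

Lissajous-Bowditch loops return the final steady cycle, with the strain-rate
axis computed analytically as $\gamma_0\omega\cos\omega t$ — numerical
differentiation of a measured stress trace would amplify noise for no
benefit. For a linear material the elastic loop is an ellipse of area
$\pi\gamma_0^2 G''$, which the tests verify to 0.5 % at 256 samples/cycle.

The nonlinearity metrics are the third-harmonic intensity ratio $I_3/I_1$
and the strain-stiffening ratio $S = (G'_L - G'_M)/G'_L$ with tangent modulus
$G'_M = \sum_k k G'_k$ at $\gamma = 0$ and secant modulus
$G'_L = \sum_k (-1)^{(k-1)/2} G'_k$ at $\gamma = \gamma_0$. In this standard
(Chebyshev) convention, intracycle stiffening ($S > 0$) corresponds to a
*negative* sine-convention third-harmonic Fourier coefficient — a sign trap
worth stating explicitly, and the package's tests pin it down.

The LVR detector takes the plateau as the median of the first three sweep
points and reports the first strain where $G'$ drops more than 10 % below it
(`tolerance`); a sweep with no such drop is flagged absent rather than
erroring, since a stiff gel may be linear over the whole measured range.

## Digital image correlation

`track_subsets()` is deliberately minimal: zero-normalized cross-correlation
(ZNCC, insensitive to uniform lighting changes) over an exhaustive integer
search window, then sub-pixel refinement in two stages — a quadratic
(log-parabola) fit of the 3x3 correlation neighborhood, then
coordinate-descent maximization of the ZNCC against a bilinearly interpolated
deformed subset. The second stage is what brings translation errors from
~0.05 px (the classic pixel-locking bias of a pure paraboloid fit) down to
~0.005 px. There are no subset shape functions: within a 21 px subset a 1 %
strain moves material points by at most ~0.1 px relative to the subset
centre, so zeroth-order matching is adequate for the affine-dominated,
pre-localization fields of interest here, and this is documented as the
fidelity limit — fields with strong intra-subset gradients (post-necking,
crack tips) need a shape-function DIC such as Ncorr.

Strains come from local least-squares plane fits of $u$ and $v$ over a
(2 `window` + 1)$^2$ grid neighborhood (default 3x3; at least 6 unmasked
neighbors). The strain-concentration index, max/median of a strain
component, is exactly 1 on uniform fields and grows as strain localizes at
an incipient failure site.

Measured on the synthetic pairs: RMS displacement error ~0.0001 px for
integer translations, ~0.015 px under 1 % stretch, RMS $\varepsilon_{xx}$
error ~0.0008 — all comfortably inside the 0.1 px / 0.002 budgets the
validation regime demands.

## Orchestration

`run_pipeline()` executes the configured stages (ring, compression, LAOS,
DIC) in dependency order from a single YAML/JSON config or R list, writes
every intermediate as delimited text (records, curves, spectra, loops,
fields) plus a JSON summary, and derives all stage seeds from the one
top-level seed, so a rerun is byte-identical. A thin command-line front-end
ships in `inst/cli/gelmech.R`; the package functions are the primary
interface. Units are SI internally; the text formats carry mm and N where
their headers say so.

## Problem sizes and limitations

The test and validation runs use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: tensile records of one to
two hundred samples at 50 samples/s, LAOS records of 4 cycles at 256
samples/cycle, speckle images of 96-192 px with ~80-260 grid points. All are
the package's own defaults and scale up by configuration.

What the passing round-trips establish is internal consistency: the analysis
inverts the generator exactly where the generator implements the same model
the analysis fits. They do not establish that real agarose-xanthan gels obey
a Johnson-Cook law (its concave post-yield hardening is qualitatively wrong
for the convex curves real gels show — see the calibration note above), that
rheometer transients die within one cycle, or that real speckle video meets
the noise-free affine assumptions of the DIC validation. Those are
instrument- and material-facing questions the published measurements answer;
this package's claim is that, given records of the stated form, the numbers
it extracts are the ones defined here, computed correctly.
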