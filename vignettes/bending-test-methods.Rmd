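---
title: "Methods: from channel flow to cell-wall elasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from channel flow to cell-wall elasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyphabend)
```

`hyphabend` turns observed tip deflections of flow-loaded fungal hyphae
into bending stiffnesses and cell-wall moduli. This vignette documents the
physical model, the numerical choices, and — importantly — what the
synthetic-data generator does and does not emulate, so that passing
recovery tests are interpreted correctly.

## Units

Everything internal is µm / s / µN. This makes viscosity
µN s µm⁻² (water ≈ 10⁻⁹), pressure µN µm⁻² ≡ MPa, bending stiffness
µN µm², and the modulus E = k_b/I lands in MPa with no conversion
factors. Interfaces accept the bench units: flow rates in µL min⁻¹
(1 µL min⁻¹ = 10⁹/60 µm³ s⁻¹), angles in degrees in CSV tables, forces
reported in pN µm⁻¹.

## Flow model

The chamber is a rectangular duct of width $w$ (spanwise, hyphae grow
along $y$ from the side wall at $y = 0$) and height $h$. We use the
classical odd-harmonic series for fully developed laminar flow,

$$u(y,z) = \frac{4\,G\,h^2}{\pi^3 \mu} \sum_{n\ \mathrm{odd}}
\frac{1}{n^3}\left[1 -
\frac{\cosh\!\big(n\pi\,(y - w/2)/h\big)}{\cosh\!\big(n\pi w/(2h)\big)}
\right]\sin\frac{n\pi z}{h},$$

with $G = R_f\,Q$ the pressure gradient and $R_f$ the per-length
hydraulic resistance from the matching series. Both series truncated at
the *same* order make $\iint u\,\mathrm{d}A = Q$ exact term by term, so
flow conservation holds to quadrature accuracy at any order. The cosh
ratio is evaluated in exponential form so large aspect ratios cannot
overflow. Default order `n_max = 51` for field evaluations: convergence
at the centre is alternating and far below 0.1 % there, and the
no-slip residual on the walls stays under 10⁻³ of the peak velocity.
One caveat worth knowing: the *term-wise Laplacian* of the truncated
series converges only like $1/n_\mathrm{max}$ (a Gibbs effect on the
square-wave source term), so pointwise momentum-balance checks need a
much higher order than field values do.

Flow-rate recovery from measured velocity profiles
(`fit_flow_rate()`) fits the single scale factor $Q$ by linear least
squares with the cross-section fixed — geometry is known from
fabrication and microscopy, so one parameter is all the data must
support. Vertical profiles are excluded by default: particle-image
velocimetry integrates over the depth of field, so the apparent
velocity near the horizontal walls does not fall to zero but saturates
near 30 % of the maximum. A flag (`include_vertical = TRUE`) lets the
biased fit be studied deliberately.

## Drag model

The force per unit length on the hypha inherits the spanwise harmonic
profile of the flow:

* **floor**: proportional to the unperturbed wall shear rate, an
  $n^{-2}$ series;
* **center**: proportional to the local mid-height velocity with the
  confinement factor $\varepsilon = (\ln(h/2r) - 0.92)^{-1}$, an
  alternating $n^{-3}$ series. $\varepsilon$ requires
  $h > 2r\,e^{0.92}$ (≈ 5 radii); shallower channels raise a domain
  error naming the bound.

The alternating sign $\sin(n\pi/2)$ is evaluated exactly as
$+1, -1, \dots$, never by floating trigonometry. Default truncation is
`n_max = 11`; `truncation_diagnostic()` reports both the
first-neglected-term contribution (< 0.5 % at mid-span for the center
series) and the cumulative tail. The two differ: for the
floor configuration's $n^{-2}$ series the cumulative tail is the larger
number, so the diagnostic exposes both rather than choosing one.

The hemispherical tip approximately doubles the local load over the last
radius. We represent it as a point force
$F_\mathrm{tip} = \int_{L-r}^{L} f\,\mathrm{d}y'$ (adaptive quadrature,
relative tolerance 10⁻⁸) applied at the free end. For a tilted hypha
the arc position $y'$ maps to the channel coordinate
$y = y_0 + y'\cos\alpha_0$ — the initial geometry, not the deflected
one, which preserves the geometric span of the tip segment under the
small-angle assumption. `compare_cfd_profile()` accepts externally
computed force profiles for validation; no flow simulation is run here.

## Beam inversion

Euler–Bernoulli theory for a clamped cantilever of constant annular
cross-section:

$$\frac{\mathrm{d}^4 w_f}{\mathrm{d}y'^4} =
\frac{\cos\alpha_1\, f(y')}{k_b}, \qquad
w_f(0) = w_f'(0) = 0,\quad w_f''(L) = w_f'''(L) = 0,$$

solved by quadruple cumulative trapezoidal quadrature on a uniform grid
(`n_grid = 2001`; the uniform-load closed form $f_0L^4/8k_b$ is
reproduced to better than 10⁻⁶, and an independent sparse
finite-difference boundary-value solver agrees to 10⁻⁵ for arbitrary
smooth loads). The distributed load varies along the hypha — it is
*not* frozen at a representative value — and a constant-load comparison
is a one-liner via a custom load object. The total tip deflection
superimposes the point-load closed form:

$$w_\mathrm{max} = w_{f,\mathrm{max}} + \frac{F_\mathrm{tip}L^3}{3 k_b},$$

with $F_\mathrm{tip}$ computed from the diminished load
$f^* = \cos\alpha_1\,f$. Omitting the tip force biases $k_b$ low;
`tip_force_bias()` quantifies this (about 10 % at $L = 40$ µm for the
default chamber, growing steeply as $L$ shrinks). The exact figure
depends on chamber geometry and base position, which is why it is a
diagnostic rather than a constant.

**Angles.** The beam equation describes deflection perpendicular to the
hypha axis, so the displacement observed along the flow direction is
$w_\mathrm{max}\cos\alpha_0$; measured displacements are divided by
$\cos\alpha_0$ before fitting. The load factor uses the *measured*
chord angle $\alpha_1$ of each record — mirroring how the angle is read
from the image — while the forward simulation computes $\alpha_1$
self-consistently by fixed-point iteration (tolerance 10⁻⁸ rad, cap 50
iterations; non-convergence is an error because it signals deflections
far outside small-angle validity, and the generator flags such rows
rather than dropping them).

**Fitting.** Because the load is linear in $Q$ and the deflection linear
in $1/k_b$, each measurement satisfies
$w_\mathrm{max} = (A/k_b)\,Q\cos\alpha_1$ with a per-hypha response $A$
computed once. The least-squares fit runs through the origin — zero
flow must give zero deflection — with an optional intercept for
diagnosing partial-adhesion artifacts at low flow. Fits use absolute
displacements and warn on sign flips at positive flow.

**Validity.** Measurements with relative deflection
$w_\mathrm{max}/L > 0.25$ are excluded (inclusive boundary: 0.25 is
kept); in the center configuration a hypha more than 10 µm from the
mid-plane invalidates the whole specimen. The 10 µm default ties to the
chamber height: with $h = 90$ µm the mid-height velocity 10 µm off-plane
is reduced by just under 5 % (`center_plane_force_deviation()`), and
the deviation shrinks for taller chambers.

## Cell wall

$I = (\pi/4)\big(r^4 - (r-t)^4\big)$ and $E = k_b/I$. With the
electron-microscopy means $r = 1.4$ µm and $t = 0.287$ µm,
$I = 1.812$ µm⁴, so a mean stiffness of 18.3 µN µm² gives
$E = 10.1$ MPa. Population summaries report the modulus both ways —
modulus of the mean stiffness, and mean of per-hypha moduli — because
the two differ under spread in $k_b$ and neither is canonically "the"
population value.

## Loading circuit

The spore-loading half is a resistor network solved by nodal analysis
(conductance Laplacian, grounded reference, conservation residual
< 10⁻¹⁰). Growth channels are square ducts of side equal to the
hydraulic diameter (2.8 µm) — the true funnel-shaped 3-D inlet is out of
scope, and the flow-partition results depend only on resistance ratios,
which is also why the unprinted channel length (default 100 µm) is
harmless. Blocked channels are removed outright (spores as perfect
plugs). Downstream chamber/outlet resistances default to zero (ideal
outlets), configurable to study their effect; with ideal outlets the
growth/serpentine flow ratio equals the resistance ratio exactly, so
the 20× serpentine rule yields a ratio of 20 at the start of loading,
decaying as channels fill and pressure rises to the all-blocked maximum
set by the serpentine path alone.

## What the generator emulates — and what it does not

`synthetic_config()` defaults define the study conditions: lengths
uniform on 30–150 µm (30 µm is the minimum exposed length at which
measurements start), radius normal (1.4 ± 0.1 µm), initial tilt normal
(sd 5°), mid-plane offset normal (sd 3 µm, clamped to the half-height),
true stiffness log-normal with mean 18.3 µN µm² and the observed
coefficient of variation 8.7/18.3, flow schedule 0–25 µL min⁻¹ within
the 0–50 µL min⁻¹ pump range, displacement noise 0.2 µm (of the order
of the optical resolution at the magnifications used). The radius sd,
tilt sd, offset sd and noise sd are this package's choices of realistic
scales; they are not reported device values. Likewise chamber
width 500 µm and height 90 µm (center; 45 µm floor) are plausible
scales only — absolute force magnitudes therefore are not reproduction
targets, while every ratio, recovery and convergence statement is.

Measurements are generated by the *same forward model* the fit inverts,
plus Gaussian noise on the scalar tip displacement (the bench pipeline
reduces images to base/tip coordinates before analysis, so noise on the
scalar is the right level of abstraction). Recovery tests therefore
demonstrate the correctness and conditioning of the inversion — not
that the drag model matches a real hypha, which only external data
(µPIV profiles, CFD force profiles, TEM geometry) can test. The
velocity-profile generator applies the depth-of-field artifact as a
hard clamp at 30 % of the maximum; a smooth depth-of-correlation kernel
is deliberately out of scope.

Determinism: every stage takes its own seed (`run_simulate()` uses
seed, seed+1, seed+2 for population, measurement noise and profile
noise), so a fixed master seed gives byte-identical files and any stage
can be regenerated alone.

## Known limitations

* **Selection bias from the validity filter.** Long, compliant hyphae
  exceed $w_\mathrm{max}/L \le 0.25$ at every scheduled flow rate and
  drop out. Among the *fitted* population this induces a positive
  association between stiffness and length even when none exists in the
  truth — visible in the README example (p ≈ 0.05 with zero injected
  trend at n = 17). A real stiffness–length dependency must therefore
  be markedly stronger than the filter artifact; the package's recovery
  test injects a trend and checks p < 10⁻⁴ at n = 200, far beyond the
  selection signal. Flow schedules adapted per hypha (as at the bench)
  mitigate the dropout.
* Small-deflection linear beam theory only; no large-deflection update
  of the drag geometry, no viscoelasticity or hysteresis, no turgor
  mechanics.
* The drag model assumes an isolated, rigid, straight cylinder:
  meandering growth paths, hypha–hypha interaction and partial floor
  adhesion are outside the model (adhesion shows up as a non-zero
  intercept, which the optional intercept fit can flag).
* The tip end effect is a lumped point force estimated from the last
  radius of load; its true magnitude varies with tip shape.
* Floor-configuration drag uses the wall-contact shear rate as written;
  whether a center-height evaluation is preferable is untestable
  without reference data and both differ only in a constant factor at
  fixed geometry.
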