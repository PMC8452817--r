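---
title: "The core-annulus model of the Fahraeus-Lindqvist effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The core-annulus model of the Fahraeus-Lindqvist effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flvisc)
```

## The phenomenon and the model

When blood flows through tubes narrower than roughly 300 micrometres, its
apparent viscosity — the viscosity of the homogeneous Newtonian fluid that
would deliver the same discharge under the same pressure gradient — drops
well below its bulk value and keeps dropping as the tube narrows. The
mechanism modelled here is red-blood-cell (RBC) marginalization: cells
concentrate in a central core and leave a cell-poor annulus at the wall,
where shear is highest, so the wall region is lubricated by nearly pure
plasma.

flvisc implements a two-fluid continuum version of this picture for steady,
fully developed, axisymmetric laminar flow. All viscosities are relative to
plasma and all radii are normalized by the tube radius \(R^* = D^*/2\):

* the **core** (radius \(s\), relative viscosity \(\eta_c > 1\)) carries
  most of the RBCs; \(\eta_c\) is also the wide-tube (bulk) limit of the
  apparent viscosity;
* the **marginal annulus** has relative viscosity
  \(\eta_A = 1 + \alpha(\eta_c - 1)\), interpolated by the marginal
  viscosity fraction \(\alpha \in [0, 1]\). \(\alpha = 0\) is Haynes'
  classical cell-free layer; \(\alpha = 1\) collapses the model to a
  homogeneous suspension.

Two physical ingredients close the model.

**Size exclusion at the inlet.** Cell centres cannot approach the wall
closer than a half-thickness \(a^*\), so the core enters the tube with
dimensionless radius \(s_0 = 1 - 2a^*/D^*\) (`inlet_core_radius()`). The
geometry requires \(D^* > 2a^*\); narrower vessels are a hard error.

**Mass conservation through the entrance region.** Radial migration in the
entrance region thins the core until the flow settles into the asymptotic
core-annulus state. Equating the inlet core flux to the asymptotic one
gives a quartic in the asymptotic core radius \(s_\infty\), whose single
admissible root has the closed form

\[
s_\infty = \frac{s_0}{\sqrt{1 + \sqrt{(1 - s_0^2)\,
  [\,1 - s_0^2(1 - \eta_A/\eta_c)\,]}}} ,
\]

implemented in `core_radius_closed_form()`. The piecewise-parabolic
velocity profile (`velocity_profile()`, flux-normalized to unit mean
speed) and the apparent relative viscosity

\[
\eta_{\mathrm{app}} = \left[\, s_\infty^4\!\left(\frac{1}{\eta_c}
  - \frac{1}{\eta_A}\right) + \frac{1}{\eta_A}\right]^{-1}
\]

(`apparent_relative_viscosity()`) follow. `predict_vessel()` composes the
chain per vessel and also reports the asymptotic marginal-layer thickness
\(R^*(1 - s_\infty)\) — the quantity compared against intravital
measurements, deliberately *not* the inlet gap \(a^*\), which it always
exceeds.

```{r}
p <- model_params(eta_c = 3.3, alpha = 0.1, a_star_um = 1.2)
predict_vessel(100, p)
```

## Parameters, units, defaults

| Parameter | Meaning | Units | Typical / default |
|---|---|---|---|
| `eta_c` | core relative viscosity; bulk limit of \(\eta_{app}\) | — | 1.7–6.4 depending on hematocrit; fitted in (1.001, 10] |
| `alpha` | marginal viscosity fraction | — | 0.05–0.15; fitted in [0, 0.15] |
| `a_star_um` | RBC exclusion half-thickness | µm | 1.0–1.5 (human; about half the disk thickness); ~0.8 for rat blood |
| `eta_p_mPas` | plasma viscosity scale (optional) | mPa·s | only for dimensional output |

`eta_c` can instead be derived from a discharge hematocrit through the
Charm–Kurland correlation (`model_params(phi = ...)`); the route is
recorded in the returned object, because the correlation is only an
estimate — it strictly applies at high shear rates, while small vessels
often sit below that regime. The correlation's bracket diverges near
hematocrit 0.78, so its domain is guarded at \([0, 0.7)\), comfortably
above the largest value used in practice (0.66).

External lengths are always micrometres; the solver is dimensionless
inside. The empirical Pries and Secomb laws shipped for comparison
likewise take diameters in micrometres — no unit auto-detection anywhere.

## Numerical choices

* **Closed form first, bisection as oracle.** The closed-form
  \(s_\infty\) is the production path. `core_radius_numeric()` solves the
  quartic by bracketed root search on \(x = s_\infty^2 \in (0, 1)\)
  (the bracket is guaranteed: the cleared residual is positive at 0 and
  negative at 1) to tolerance `1e-14` and is retained as an independent
  check; the suite verifies agreement below `1e-10` on 1000 random valid
  triples.
* **A second, formula-free route to \(\eta_{app}\).**
  `apparent_viscosity_poiseuille_oracle()` integrates
  \(dv/dr = -\tau/\eta(r)\) with the piecewise viscosity by adaptive
  quadrature, integrates again for the flux, and reads off the viscosity
  of the homogeneous flow with the same flux and gradient. Quadrature
  panels are split at the core interface, where the integrand is only
  piecewise smooth. Agreement with the discharge formula is verified to
  `1e-8` relative.
* **Degenerate limits.** The hematocrit ratio in the Pries/Secomb laws is
  `0/0` when the shape exponent \(C(d)\) vanishes; it is continuously
  extended (l'Hôpital in the exponent) to
  \(\log(1-\phi)/\log(0.55)\). The Secomb law's \((d - 1.1)^{-2}\)
  factor makes \(d \le 1.1\) µm a domain error.
* **Continuum validity.** The two-fluid description degrades when the
  vessel is only a few cell diameters wide. `predict_vessel()` warns —
  never errors — below a configurable 30 µm threshold; no sharp physical
  cutoff exists, and 30 µm marks where published thickness comparisons
  themselves are at the edge of applicability.
* **Wide-vessel convergence is slow.** The bulk limit is approached like
  \(\sqrt{a^*/D^*}\) (the tests assert the decay rate), so `eta_app` at
  \(D^* = 10^6\) µm still sits about 0.015 below `eta_c` for the
  reference configuration; agreement to `1e-4` needs \(D^* \sim 10^{11}\)
  µm. The empirical reference curves, by contrast, converge to their 3.2
  asymptote exponentially fast.

## Fitting

`fit_parameters()` estimates \((\eta_c, a^*, \alpha)\) by bounded
Levenberg–Marquardt least squares on **relative** residuals
\((\hat\eta_{app}(D_i) - \eta_i)/\eta_i\): tube-viscometry errors are
multiplicative (typically 10–20%), so relative residuals stabilize the
variance. Choices made where the methodology was open:

* **Deterministic multistart.** The 3-parameter surface is mildly
  nonconvex, so the local optimizer is restarted from a deterministic
  3×3×3 grid of interior points of the bounds; equal-loss optima are
  resolved to the lexicographically smallest \((\eta_c, a^*, \alpha)\).
  Identical inputs always return identical fits.
* **Bounds encode physiology.** Defaults \(\eta_c \in (1.001, 10]\),
  \(\alpha \in [0, 0.15]\), \(a^* \in [1.0, 1.5]\) µm; all overridable
  (rat blood wants \(a^* \approx 0.8\) µm).
* **Fixed-parameter fits** (`fixed = c(a_star_um = 1.2)`) support the
  common design of sharing \(a^*\) across series fitted separately.
* **Feasibility by penalty.** During the search, a candidate \(a^*\) with
  \(D_i \le 2a^*\) yields a large finite residual instead of an
  exception, so the bounded optimizer can retreat rather than crash.

Identifiability is asymmetric: \(\eta_c\) is pinned by the large-diameter
plateau and recovers well (within 10% at 10% noise with 30 points on
40–600 µm), while \(a^*\) and \(\alpha\) only act through the thin
marginal layer and are weakly identified at realistic noise — \(a^*\)
estimates frequently sit on a physical bound. `recovery_experiment()`
quantifies this: it repeats generate-then-fit and reports per-parameter
bias and RMSE, which the tests require to shrink as datasets grow (10
versus 40 diameters) and to grow with the noise level (10% versus 20%).

## What the synthetic generator does and does not emulate

`generate_dataset()` draws
\(\eta_i = \eta_{app}(D_i)\,(1 + \varepsilon_i)\) with
\(\varepsilon_i\) i.i.d. Gaussian of standard deviation `rel_noise_sd`,
truncated at ±3 sd (redrawn, not clipped), reproducible bit-for-bit from
one integer seed (Mersenne-Twister via `withr::with_seed`, leaving the
global RNG state untouched). The 0.10–0.20 default range mirrors reported
in-vitro viscometry error magnitudes; only a magnitude is reported in that
literature, so the Gaussian shape is this package's choice, and truncation
keeps observations physical.

The generator deliberately does **not** emulate diameter measurement
error, shear-rate dependence of the core viscosity, hematocrit drift
between runs, or inter-sample donor variability. Passing recovery tests
therefore demonstrate that the estimator is correct and well-behaved under
the stated error model — not that three parameters are sharply
identifiable from any real viscometry series.

## Validation problem sizes

The shipped suite checks the closed form against the quartic oracle on
1000 random triples, the discharge formula against the quadrature oracle
on 40, flux conservation on 30 profiles at `1e-9`, zero-noise recovery on
20-point datasets, noisy recovery on 30-point datasets at 10% noise, and
RMSE shrinkage with 20 replicates at 10 versus 40 diameters.

## Known limitations

* Only the asymptotic state is modelled: the entrance-region evolution
  \(s(x)\) is summarized by the mass-conservation constraint, not
  resolved.
* \(\eta_c\) is shear-rate independent; the inverse effect in
  capillary-scale tubes (diameters comparable to one cell) is outside the
  continuum description, as are cell deformability and glycocalyx
  interactions.
* The hematocrit route to \(\eta_c\) inherits the Charm–Kurland
  correlation's high-shear assumption; treat it as an estimate, and
  prefer fitting \(\eta_c\) when data allow.
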