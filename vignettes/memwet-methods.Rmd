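---
title: "Methods: phasor fluidity, wetting geometry and condensate electrokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor fluidity, wetting geometry and condensate electrokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memwet)
```

memwet quantifies three things about membrane–condensate systems: how
fluid (loosely packed and hydrated) a lipid membrane is, how strongly a
biomolecular condensate wets it, and how charged the condensate surface
effectively is. This vignette explains each model, its assumptions, the
numerical choices made where the literature leaves them open, and what the
synthetic-data generators do and do not emulate.

## Spectral phasor analysis of LAURDAN fluidity

### Model

A hyperspectral stack assigns each pixel an emission spectrum $I(\lambda)$
sampled on equal-bandwidth channels over $[\lambda_{min}, \lambda_{max}]$
(default 416–728 nm in 32 channels of 9.75 nm). The spectral phasor is the
first Fourier harmonic of the normalised spectrum:

$$G = \frac{\sum_k I_k \cos \phi_k}{\sum_k I_k}, \quad
  S = \frac{\sum_k I_k \sin \phi_k}{\sum_k I_k}, \quad
  \phi_k = \frac{2\pi n (\lambda_k - \lambda_{min})}{\lambda_{max} - \lambda_{min}},$$

with harmonic $n = 1$ by default. The integral form is discretised as a sum
over channel-center wavelengths with uniform weights, matching acquisition
on equal-bandwidth channels. Two consequences drive everything downstream:

- **Modulus bound.** For non-negative spectra $(G, S)$ lies in the unit
  disk ($G^2 + S^2 \le 1$; equality only for a single occupied channel).
- **Linearity.** The phasor of $aI_1 + bI_2$ lies on the segment between
  the phasors of $I_1$ and $I_2$, at the position given by the fractional
  *integrated intensities*. A membrane whose LAURDAN emission interpolates
  between a packed (gel-like) and a fluid state therefore traces a straight
  trajectory in phasor space.

The *fluidity fraction* of a pixel is its scalar projection onto a
user-chosen trajectory segment, clamped to $[0, 1]$; orientation is fixed
by convention with fraction 1 at the most fluid endpoint. Clamping is
deliberate: the fraction is defined only on the segment, and pixels beyond
the endpoints (noise, or spectra slightly outside the two-component span)
carry no extra information about the mixture. The population statistic is
the center of mass $CM = \sum_i F_i\, i / \sum_i F_i$ of the normalised
fraction histogram, with $i$ the bin-center fraction.

### Parameters and numerical choices

- **Harmonic** `harmonic = 1`: one trigonometric period across the
  acquisition range; higher harmonics are passed through but not otherwise
  exploited.
- **Background mask** `threshold = "otsu"`: the masking rule of the
  original acquisition software is not published, so the package defaults
  to Otsu's threshold on the total-intensity image (256-bin histogram),
  overridable by a fixed count. On ring-shaped vesicle images with dark
  background the two rules coincide.
- **Histogram bins** `n_bins = 100` on $[0, 1]$. Published distributions
  are smooth without a stated bin count; the CM is required (and tested) to
  move by less than 0.01 across 50–400 bins, so the choice is cosmetic.
- **Cursor tie-break**: with overlapping circular cursors, the *first
  cursor in input order* wins — a deterministic rule for reproducing
  multi-cursor colourings.
- The CM is invariant under uniform intensity rescaling (the transform is
  normalised per pixel), which the suite asserts.

## Wetting geometry and fluid-elastic parameters

### Model

An equatorial cross-section of a vesicle–condensate couple shows three
interfaces — membrane/buffer (*ie*), membrane/condensate (*ic*) and
condensate/buffer (*ce*) — as circular arcs meeting at two contact points.
At the contact line the tensions balance, closing a *tension triangle*; the
three apparent contact angles $\theta_i, \theta_e, \theta_c$ (opening into
interior, exterior and condensate) are the supplements of the triangle's
interior angles and sum to 360°. The law of sines then gives the membrane
segment tensions from the condensate interfacial tension $\Sigma_{ce}$, and
the material parameters follow:

$$\Phi = \frac{\sin\theta_e - \sin\theta_c}{\sin\theta_i}, \qquad
  \cos\theta_e^{in} = \Phi, \qquad W = \Phi\,\Sigma_{ce},$$

with $\Phi \in [-1, 1]$ ($-1$ complete wetting, $+1$ dewetting). $\Phi$,
$\theta_e^{in}$ and $W$ are size- and shape-invariant; the apparent angles
are not. Only the difference $W$ of the two adhesion parameters is
identifiable from angles plus $\Sigma_{ce}$, so the package reports $W$ and
the segment tensions but never a common membrane tension. $\Sigma_{ce}$ is
a supplied per-system constant (15.7 µN/m for glycinin, shipped in
`condensate_systems`); estimating it from coalescence is out of scope.

A useful identity (used as a property test): at fixed $\theta_i$ the valid
family has $\theta_e + \theta_c = 360° - \theta_i$, and sum-to-product
reduces the geometric factor to
$\Phi = \sin((\theta_c - \theta_e)/2) / \sin(\theta_i/2)$ — strictly
*decreasing* in $\theta_e$, i.e. wetting improves as the external angle
opens.

### Fitting and angle extraction

- **Circle fit.** Taubin's algebraic least-squares fit: deterministic,
  exact on noiseless data (including the three-point circumcircle), nearly
  unbiased at small noise; the suite cross-checks it against an independent
  geometric (orthogonal-residual) refit.
- **Flat interfaces.** A partial-wetting *ic* interface can be flat. The
  fit falls back to a total-least-squares line when the fitted radius
  exceeds 1000× the point-cloud extent. The cut is placed where it is
  because a line model read at a chord end mis-states the tangent by
  $\arcsin(\mathrm{extent}/2R)$; at 1000× this error is under 0.03°,
  preserving the package's 0.1° noiseless angle-recovery contract, while a
  merely shallow arc keeps its (informative) curvature.
- **Contact points** are the intersections of the *ie* and *ce* circles,
  validated against the *ic* interface within 5% of the condensate radius.
- **Region assignment.** The interior side of the contact chord is taken
  as the side holding the *ie* circle center — true whenever the vesicle
  body subtends more than half its circle, which holds for equatorial
  cross-sections in partial wetting. The *ic* tangent at the contact point
  is initialised from the chord-proximal (minor) arc of its circle and then
  disambiguated by requiring $\theta_i, \theta_c \in (0°, 180°)$: the
  flipped tangent shifts both by 180° the wrong way, so exactly one choice
  is physical. This keeps the inversion exact even for strongly curved
  *ic* interfaces bulging into the vesicle.
- **Left/right averaging.** Angles are measured at both contact points and
  averaged; asymmetry above 5° (a symptom of a mis-projected cross-section)
  raises a warning and is reported.
- **Units and tolerances.** Degrees at every interface, radians internally.
  Angle-sum tolerance: 1° for experimental input, 1e−6° for noiseless
  synthetic data. $\Phi$ values within 1e−9 outside $[-1, 1]$ are clamped;
  larger excursions raise an error.

## Condensate electrokinetics

The drift velocity is the least-squares slope of field-axis–projected
position against time — robust to Brownian noise, unlike endpoint
displacement. The conversion to ζ uses the modified Smoluchowski relation
for liquid droplets,

$$\zeta = \frac{3\eta_c \nu}{\epsilon_0 \epsilon_r E}
          \cdot \frac{1}{3\eta_e + \kappa R}.$$

The denominator adds a viscosity ($3\eta_e$, Pa·s) to the dimensionless
product $\kappa R$ — the published form is dimensionally heterogeneous and
its derivation lives in the electrokinetics literature. The package
implements the expression exactly as written under a fixed all-SI
convention (viscosities in Pa·s, $\kappa$ in 1/m, $R$ in m, $E$ in V/m,
$\nu$ in m/s), documents that convention at the interface, and verifies
that simulate→estimate round trips are exact under it. Electroosmotic-flow
correction and double-layer polarisation are out of scope.

## What the synthetic generators emulate — and what they do not

All generators are deterministic in (arguments, seed), restore the caller's
RNG state, and record their ground truth.

- **Hyperspectral vesicles** (`simulate_hsi_vesicle`): a ring-shaped GUV
  cross-section whose pixels carry the mixture
  $f\,S_{fluid} + (1-f)\,S_{gel}$ of unit-normalised Gaussian reference
  spectra, scaled to a photon budget with Poisson noise; the background is
  dark. Defaults: gel 440 nm / σ 15 nm, fluid 490 nm / σ 35 nm. The widths
  were calibrated once so the *sampled* spectra's centers of mass differ by
  ≈50 nm on the default grid — the emission shift between highly packed
  and fluid phosphatidylcholine membranes (naive widths understate the
  shift because the gel Gaussian is truncated at the 416 nm edge); the
  narrower gel spectrum also matches the physics of reduced dipolar
  relaxation. Not modeled: detector read noise (photon noise dominates at
  confocal budgets), optical PSF, spectral bleed-through, out-of-focus
  signal. Passing recovery tests therefore demonstrate estimator
  correctness under photon statistics, not robustness to optical artefacts.
- **Wetting geometries** (`simulate_wetting_geometry`): from
  $(\Sigma_{ce}, W, \bar\Sigma)$ the segment tensions are
  $\bar\Sigma \mp W/2$, the tension triangle gives the angles, and three
  arcs are constructed to meet at two contact points with exactly those
  tangent sectors; points are jittered with isotropic Gaussian noise in
  pixel units (0.5 px mimics contour-extraction uncertainty). Rendering is
  in continuous coordinates (x right, y down, pixel units); no pixelation,
  segmentation error, or 3-D projection misalignment is modeled — the
  package flags asymmetry but does not automate projection correction.
- **Drift tracks** (`simulate_drift_track`): drift at the ν implied by the
  requested ζ plus a 2-D Brownian walk of diffusivity $D$ (default
  0.05 µm²/s, a few-µm droplet in water), sampled at 1 s over 1000 s — the
  duration fields are applied in such recordings. Not modeled: field
  inhomogeneity, electroosmotic backflow, droplet coalescence or
  deformation.

## Problem sizes used by the verification suite

The package's own studies run at desk scale, chosen to exercise every
contract comfortably: 64×64×32 stacks at 10⁴ photons/pixel (20 replicates
per mixing fraction over $f \in \{0, 0.25, 0.5, 0.75, 1\}$, recovery within
0.05); 500 random tension triples for the geometry round trip (Φ within
1e−3 noiseless, 0.05 at half-pixel noise); ensembles of 100 seeded 1000 s
tracks (mean ζ within 2%). The naive direct-sum phasor oracle, the
geometric circle refit and the algebraic ζ inversion provide independent
routes against which the implementations are checked at 1e−12/1e−9.

## Known limitations

- Contours are inputs: the package does not segment raw confocal images
  into arcs, and it trusts that the user supplied equatorial
  cross-sections (mis-projection shows up as left/right asymmetry, which
  is reported, not corrected).
- The two-component fraction is meaningful only when exactly two spectral
  states span the data; three-component mixtures project onto the
  trajectory with no warning beyond their histogram shape.
- The region-assignment rule assumes the vesicle body subtends more than
  half its fitted circle; extreme engulfment geometries violate it.
- The ζ conversion inherits the published relation's unit convention; ζ
  values are comparable within that convention, and round trips are exact,
  but absolute values depend on it.
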