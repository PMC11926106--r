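# memwet

Quantitative analysis of membrane–condensate wetting for giant unilamellar
vesicle (GUV) experiments. The package implements, as tested R functions, the
three measurement chains such studies rely on:

1. **Membrane fluidity from LAURDAN hyperspectral imaging.** Each pixel's
   emission spectrum is mapped to first-harmonic Fourier coordinates
   (the *spectral phasor*)

   G = Σ I(λ) cos(2πn(λ−λ_min)/(λ_max−λ_min)) / Σ I(λ),
   S = Σ I(λ) sin(2πn(λ−λ_min)/(λ_max−λ_min)) / Σ I(λ),

   so mixtures of two membrane states fall on the straight segment joining
   the pure-state phasors. Projecting pixels onto a two-cursor trajectory
   gives a per-pixel *fluidity fraction* (1 = most fluid), summarised by the
   center of mass CM = Σ Fᵢ·i / Σ Fᵢ of its histogram.

2. **Wetting geometry of a vesicle–condensate couple.** Circles are fitted
   (Taubin least squares, with a line fallback for flat interfaces) to the
   three interface arcs of an equatorial cross-section; the tangent sectors
   at the contact points give the apparent contact angles θᵢ, θₑ, θ꜀
   (summing to 360°). From the tension triangle:

   - geometric factor Φ = (sin θₑ − sin θ꜀)/sin θᵢ, with Φ ∈ [−1, 1]
     (Φ = −1 complete wetting, Φ = +1 dewetting),
   - intrinsic contact angle θₑⁱⁿ = arccos Φ,
   - affinity contrast W = Φ·Σce (Σce = condensate interfacial tension,
     e.g. 15.7 µN/m for glycinin),
   - membrane segment tensions Σᵢₑ = Σce·sin θ꜀/sin θᵢ and
     Σᵢ꜀ = Σce·sin θₑ/sin θᵢ (law of sines).

3. **Condensate ζ-potential from microelectrophoresis.** The drift velocity
   ν is the least-squares slope of field-axis–projected position vs time,
   converted via the modified Smoluchowski relation for liquid droplets
   ζ = [3 η꜀ ν / (ε₀ εᵣ E)] · 1/(3 ηₑ + κR), evaluated in SI units.

Every chain has a seeded synthetic-data generator
(`simulate_hsi_vesicle()`, `simulate_wetting_geometry()`,
`simulate_drift_track()`) producing inputs with known ground truth, so the
whole pipeline is verifiable by parameter recovery without microscopy data.

All user-facing functions take and return tibbles, compose with the pipe,
and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(memwet)

# fluidity: a synthetic vesicle with 35% fluid-phase signal
sim <- simulate_hsi_vesicle(f = 0.35, photons_per_pixel = 1e4, seed = 42)
fl  <- fluidity_summary(sim$stack, reference_axis())
fl$cm
#> [1] 0.350

# wetting: noisy contours generated at affinity contrast W = -6.5 uN/m
wet <- simulate_wetting_geometry(sigma_ce = 15.7, W = -6.5, sigma_mean = 15.7,
                                 noise_sigma = 0.5, seed = 42)
wetting_analysis(wet$contours, sigma_ce = 15.7, pixel_size = 0.1)
#>   theta_i theta_e theta_c     phi theta_e_in      W sigma_ie sigma_ic
#>       124   139.4   96.61 -0.4131      114.4 -6.485    18.81    12.33

# zeta: drift + Brownian track at 10 mV ground truth
p   <- medium_params(eta_c = 4, radius = 5e-6)
trk <- simulate_drift_track(zeta_mv = 10, params = p, E = 100, D = 0.05,
                            duration = 1000, seed = 42)
fit <- drift_velocity(trk$track)
zeta_potential(fit, p, E = 100)
#> [1] 9.51
```

The fluidity CM reproduces the mixing fraction (0.350 vs 0.35); the wetting
chain recovers W = −6.5 µN/m as −6.49 from half-pixel-noise contours (the
negative sign: the membrane prefers the condensate over buffer); the
electrokinetic chain returns 9.51 mV for a 10 mV droplet from a single noisy
1000 s track (the ensemble mean is unbiased).

`run_pipeline()` chains simulate → analyze → report for all three stages
from one config and master seed, and reports per-condition mean ± SD:

```r
run_pipeline(list(seed = 42))$summary
#>     stage condition n  truth mean_estimate sd_estimate
#>       hsi    f=0.25 3  0.250         0.250    0.000292
#>       ...
```

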