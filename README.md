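# eisr — resolution analysis for Born-approximation electromagnetic inverse scattering

Microwave medical imaging reconstructs the dielectric contrast
χ(r) = (ε(r) − ε₀)/ε₀ of tissue from far-field scattered microwaves, and
routinely reports *super-resolution*: features finer than the λ/2
diffraction limit. `eisr` is a toolkit for analyzing exactly when and why
that happens in the linear (weak-scattering) regime, where multiple
scattering cannot be the explanation.

The package implements, in 2-D transverse-magnetic geometry:

* a **pulse-basis method-of-moments forward solver** for the coupled field
  equations `J = χ(Eⁱ + G_D J)`, `Eˢ = G_S J`, with the free-space kernel
  (j/4)H₀⁽¹⁾(k₀|r−r′|) and an equal-area-circle self term;
* the **two-step Born inversion**: minimum-norm radiating current
  `Jˢᵒˡ = VΣ⁻¹U*Eˢ` from a truncated SVD of G_S, followed by the per-cell
  least-squares contrast
  `χˢᵒˡ = Σₙ Jₙˢᵒˡ Eₙⁱ* / Σₙ Eₙⁱ Eₙⁱ*`;
* the **spread-function algebra**: far-field data constrain χ only on a
  thin ring of spatial frequencies of radius k₀/2π, whose Fourier
  transform is J₀(k₀ρ); the point spread function is therefore
  `PSF(x) = [J₀(k₀x)]²` and an extended scatterer images as the
  convolution `χˢᵒˡ ∝ χ ∗ [J₀(k₀r)]²`;
* **resolution criteria** as root-finding problems on those profiles:
  - Rayleigh: first null of the PSF → σ = 0.383 λ,
  - Sparrow (equal pair): smallest separation d with f″(0; d) = 0 of the
    joint profile → σ = 0.344 λ for points, and for cylinders the
    edge-to-edge σ = d − 2r using the closed-form four-term J₀J₁ second
    derivative of the interval-integral profile,
  - modified Sparrow (unequal pair): curvature evaluated at the Gaussian
    point g (the stationary point of the asymmetric profile between the
    peaks), the saddle condition f′(g) = 0 ∧ f″(g) = 0,
  - the inverse query: the cylinder radius achieving a prescribed σ.

The headline result the package quantifies: resolution is a property of
the *scatterer*, not only of the wavelength — extended weak scatterers
resolve strictly better than points (e.g. 0.152 λ for 0.1 λ-radius
cylinder pairs at 300 MHz), which accounts for super-resolution reports
under the Born approximation without invoking evanescent-wave arguments.

## Worked example

```r
library(eisr)
cfg <- eis_config(300e6)          # lambda = 1 m exactly (c = 3e8 m/s)

rayleigh_resolution(cfg)$sigma_wavelengths
#> [1] 0.3827399
sparrow_resolution_points(cfg)$sigma_wavelengths
#> [1] 0.3444044
sparrow_resolution_cylinders(0.1, cfg)$sigma
#> [1] 0.1520915

# modified Sparrow for two points of contrast 0.1 and 0.2:
modified_sparrow_resolution(scatterer("point", epsilon_r = 1.1),
                            scatterer("point", epsilon_r = 1.2), cfg)
#> <eis_resolution> modified_sparrow criterion
#>   critical center separation d* = 0.382378 m
#>   edge-to-edge resolution sigma = 0.382378 m = 0.382378 wavelengths
#>   Gaussian point g = -0.200625 m
```

The Rayleigh → Sparrow → cylinder progression (0.383 λ → 0.344 λ →
0.152 λ) is the quantitative story: point pairs never beat the classical
limit, extended pairs do, and asymmetry (here contrasts 0.1 vs 0.2)
*worsens* resolution (0.382 λ), because the weaker image peak drowns in
the stronger one's skirt — the dip, and hence the Gaussian point g, sits
beyond the weaker scatterer's center.

The imaging pipeline itself verifies the spread-function model:

```r
fx  <- figure_fixture("fig2")       # one point scatterer, 300 MHz
img <- reconstruct(fx)              # exact forward solve + Born inversion
cs  <- cross_section(img, y = -0.01)
sqrt(mean((cs$value - psf(cs$x + 0.01, cfg))[abs(cs$x + 0.01) <= 1]^2))
#> [1] 0.004241442                   # reconstruction vs [J0(k0 x)]^2
```

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/eisr resolve --criterion modified --scene fig5g --out out/
Rscript inst/exec/eisr invert  --scene fig4g --out out/     # CSV + PNG image
Rscript inst/exec/eisr psf-check --out out/
```

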