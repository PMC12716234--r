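# guvmech

Extraction of the membrane **area expansion modulus** *K* of giant
unilamellar vesicles (GUVs) from real-time deformability cytometry (RT-DC)
event data.

## The problem

RT-DC pushes vesicles through a narrow microfluidic channel (side length
*L*, flow rate *Q*, buffer viscosity *η*) and images each one at high speed.
Every event yields a projected area *A* and a deformation

    D = 1 − 2·sqrt(π·A) / P,

the circularity deficit of the detected contour (*P* its perimeter; *D* = 0
for a circle). A fluid lipid bilayer has no shear modulus and negligible
bending resistance at these stresses, so the stationary bullet shape — and
hence *D* — is governed by a single material constant, the area expansion
modulus *K* (N/m), through one dimensionless group

    K̂ = K·L² / (η·Q),     Â = A / L².

`guvmech` turns event tables into *K* estimates with three complementary
strategies built on a simulation-calibrated response:

| method | idea | use case |
|---|---|---|
| `direct_K()` | invert the calibrated surface K̂ = γ·D^(−β·Â^α)·Â^(−δ) per event | single-vesicle moduli, population histograms, mixture screening |
| `collective_K()` | least-squares slope *s* of the linear *D*–*A* relation, then K̂ = a·(s·L²)^(−b) | noise-resistant population estimate |
| `combined_K()` | direct moduli → Gaussian mixture on ln K → drop the outlier class → collective refit | noisy or heterogeneous samples, mixed populations |

Because everything is formulated on (K̂, Â), one calibration serves every
flow rate, channel size and buffer viscosity; `rescale_K()`/`rescale_A()`
transfer data and estimates between setups exactly. The package also ships
contour shape features with quality gates (`contour_features()`,
`porosity()`, `apply_gates()`), a pixelation correction, a fully seeded
synthetic event generator (`generate_events()`, `rasterize_contour()`) for
offline validation, CSV/TSV event-table I/O, and a small CLI
(`inst/cli/guvmech.R`: `simulate | extract | classify | calibrate`).

## Worked example

Simulate a DOPC-like population (*K* = 0.2 N/m, 5% injected outliers,
multiplicative lognormal deformation noise) in a 20 µm channel at
0.04 µL/s with a 6.3 mPa·s buffer, then extract *K*:

```r
library(guvmech)
setup <- channel_setup(channel_um = 20, flow_ul_s = 0.04, viscosity_mpa_s = 6.3)
gen   <- generate_events(population_spec(n = 2000, K = 0.2, seed = 7), setup)

combined_K(gen$events, setup, seed = 7)
#> Combined GUV estimate: 1 class(es), 112 outlier event(s) removed
#> GUV population estimate (combined): K = 0.2129 N/m  [n = 1888]
#>   dD/dA^ = 0.04525, intercept = -0.004719, R^2 = 0.900

collective_K(gen$events, setup)
#> GUV population estimate (collective): K = 0.1847 N/m  [n = 2000]
#>   dD/dA^ = 0.04908, intercept = -0.005294, R^2 = 0.638
```

The mixture stage reports what was filtered and the geometric-mean modulus
of the dominant component:

```r
print(combined_K(gen$events, setup, seed = 7)$mixture)
#> Gaussian mixture on ln K (2 components, n = 2000, loglik = 46.83)
#>   comp 1: weight 0.081  K = exp(mu) = 0.09909 N/m  sd(lnK) = 0.536  [outlier class]
#>   comp 2: weight 0.919  K = exp(mu) = 0.2008 N/m  sd(lnK) = 0.184
```

Reading: ~5–8% of events form a low-modulus outlier component (injected
artifacts plus noise tail); the dominant component sits at 0.20 N/m — the
generating truth — and the combined slope refit of the retained events gives
0.213 N/m. Typical fluid-phase phosphatidylcholine bilayers have
*K* ≈ 0.15–0.26 N/m, stiff sphingomyelin/cholesterol membranes several N/m;
see the methods vignette (`vignettes/guvmech-methods.Rmd`) for the model,
conventions, noise assumptions and known limitations — including the
deterministic few-to-twenty percent offset between the two built-in
calibration laws at the soft end.

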