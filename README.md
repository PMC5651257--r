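# morphocode

Discrete coding of anatomical shape: how many bits does it take to
describe a structure — a hippocampus, a putamen — to within a given
geometric accuracy in millimeters?

A population of anatomical surfaces is a continuum object, so its
complexity is only meaningful relative to a resolution. morphocode makes
that trade-off computable. It is aimed at computational-anatomy and
medical-imaging researchers who work with template-based shape models and
want information-theoretic summaries (code rate in bits at a geometric
accuracy in mm) of a shape population.

## The model

Shapes are diffeomorphic deformations of a triangulated template,
parameterized by an initial momentum `p0` (one 3-vector per template
vertex). A Gaussian kernel `K(dx) = exp(-|dx|²/2σ²)` (σ = 6.5 mm)
induces the velocity field `v(x) = Σᵢ K(x−xᵢ) pᵢ`, and the template flows
along the Hamiltonian particle system `ẋᵢ = v(xᵢ)`,
`ṗᵢ = −Dv(xᵢ)ᵀ pᵢ` from t = 0 to 1 (geodesic shooting, RK4).

Momenta form a vector space, so a population supports Gaussian
statistics: tangent-space PCA under the kernel (dual-space) metric
`⟨p,q⟩_K = Σₐᵦ pₐᵀ K(xₐ−xᵦ) qᵦ` gives a prior
`p0 = b0 + Σᵢ βᵢ bᵢ`, with kernel-orthonormal modes `bᵢ`, independent
`βᵢ ~ N(0, σᵢ²)`, and dimension `B` chosen to capture 95% of the
covariance trace.

The continuous prior is discretized with a random code. For independent
Gaussians, reverse water-filling allocates distortion
`Dᵢ = min(λ, σᵢ²)` and the minimal rate is
`R(D) = Σᵢ ½ log₂(σᵢ²/Dᵢ)` bits; a codebook of `2^(N·R)` codewords drawn
`N(0, σᵢ² − λ)` per live dimension achieves it asymptotically in the
block size `N`. Encoding a shape means projecting its momentum onto the
basis and taking the nearest codeword. Shooting both the shape and its
codeword to surfaces and measuring their Hausdorff distance (closest
vertex pairs, in mm) yields geometric error as a function of rate, and a
fitted curve `err(R) = a·2^(−bR) + c` gives the code rate required at
clinically relevant scales (1.0 and 1.5 mm, about one clinical-MRI
voxel).

A synthetic-population generator (icosphere template, kernel-orthonormal
modes, power-law spectrum) provides known ground truth for every stage,
so the whole pipeline is validated end-to-end without external data.

## Worked example

```r
library(morphocode)

spec  <- syntheticSpec(seed = 2L)            # 162-vertex template, 5 modes
gt    <- makeGroundTruthPrior(spec)
pop   <- makePopulation(gt, 100, seed = 3L)  # 100 synthetic subjects
prior <- fitPrior(pop, priorTemplate(gt))    # kernel-metric PCA
prior
#> ShapePrior: 5 modes on a 162-vertex template (sigma = 6.5 mm, 95% trace)
#>   variances: 27.47, 13.38, 8.004, 7.021, 4.908

curve <- rateErrorExperiment(prior, rates = seq(0L, 10L, 2L),
                             nObs = 10L, seed = 4L)
curve
#> RateErrorCurve: N = 1, 10 obs/rate
#>  rate_bits mean_error_mm stderr_mm
#>          0      3.465256 0.4282399
#>          2      2.833426 0.4210118
#>          4      2.652754 0.2886458
#>          6      1.610026 0.1891285
#>          8      1.393890 0.1143900
#>         10      1.161887 0.2618365

rateBits(fitRateAtError(curve, 1.0))
#> [1] 11.46424
rateBits(fitRateAtError(curve, 1.5))
#> [1] 7.797149
```

Reading the output: the prior retained 5 modes covering 95% of the
population's kernel-metric variance. At rate 0 every shape is replaced by
the mean shape, giving ≈3.5 mm average Hausdorff error; each added pair
of bits buys a finer codebook and the error falls to ≈1.2 mm at 10 bits.
Inverting the fitted curve says this synthetic population needs ≈11.5
bits for 1.0 mm accuracy but only ≈7.8 bits for 1.5 mm — low-variability
populations can need 0 bits at coarse scales, i.e. the mean template
alone suffices. For comparison, `reverseWaterfill(c(4, 1), 2)` returns
the textbook allocation `λ = 1, R(D) = 1 bit`, and
`surfaceStorageBits(1000)` = 192,000 bits is what the same surface costs
stored as raw double-precision vertices.

A command-line runner with the same functionality ships in
`inst/scripts/morphocode` (subcommands `simulate`, `fit-prior`, `shoot`,
`make-codebook`, `encode`, `decode`, `rd-curve`, `rate-error`,
`rate-at-scale`, `demo`); every run writes a JSON manifest from which its
outputs are bit-reproducible.

## Package layout

- `R/` — S4 classes (`TriSurface`, `MomentumField`, `ShapePrior`,
  `Codebook`, `RateErrorCurve`, ...) and the module implementations:
  surface/momentum I/O, geodesic shooting, kernel-metric PCA,
  rate-distortion and codebooks, Hausdorff metrics, the rate-at-scale
  pipeline, and the synthetic generator.
- `vignettes/shape-coding.Rmd` — the methods vignette: model,
  assumptions, numerical choices, generator design, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests
  (closed-form oracles, conserved-quantity checks, parameter recovery,
  brute-force encoders).
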