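---
title: "Volumetric and stylopodial body-mass estimation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric and stylopodial body-mass estimation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masshull)
library(dplyr)
```

## The problem

Estimating the body mass of extinct tetrapods is done two ways. *Element
scaling* regresses known body mass on the dimensions of a single bone —
classically the summed minimum midshaft circumference of the humerus and
femur — across a large extant calibration sample. *Volumetric estimation*
reconstructs the whole body: each skeletal body segment is wrapped in its
minimum convex hull (MCH), segment hull volumes are summed, and the total
is converted to mass through an assumed tissue density, with a predictive
regression calibrated on extant animals of known mass correcting the
systematic shortfall of a hull relative to a fleshed body.

`masshull` implements both estimators, the accuracy/precision machinery
used to compare them (percent prediction error, PPE), limb-bone
"robustness" allometry as the mechanistic explanation for their
disagreement, and center-of-mass (CoM) positional metrics that volumetric
models additionally make available.

## Models

**Convex hulls.** A segment's hull is computed by an incremental 3D
convex-hull construction (compiled code); volume and the solid centroid
come from signed-tetrahedron summation over the oriented boundary
triangles, which is exact for polytopes and independent of the chosen
origin. Face orientation is re-derived rather than trusted from input
winding, and a consistency check (every directed edge paired with its
reverse) guards the integration. Coplanar or collinear input is a hard
error rather than a zero-volume hull, because a silently empty segment
would corrupt downstream mass sums. All internal lengths are metres;
millimetre meshes are scaled by exactly 1e-3 on read. The default
containment tolerance is 1e-9 m.

**Predictive equations.** Both estimators are ordinary least squares fits
on the log10–log10 scale. The volumetric equation is

$$\log_{10}(\text{mass}) = 0.968\,\log_{10}(V_{\text{MCH}}\times\rho) + 0.215,$$

with mass in kg, hull volume in m³, and density $\rho$ in kg/m³ (default
1000, the density of water); the stylopodial equation is

$$\log_{10}(\text{mass}) = 2.716\,\log_{10}(C_h + C_f) - 4.078,$$

with circumferences in mm. Both are available as reference fits
(`mch_reference_fit()`, `ss_reference_fit()`) and are re-derived by
`calibrate()` from any specimen table. A raw-scale through-origin fit
(`fit_through_origin()`), whose slope acts as a single expansion factor,
is provided for model comparison via quantile–quantile residual
diagnostics (Blom plotting positions $(i-3/8)/(n+1/4)$, adjusted
Fisher–Pearson skewness).

**PPE.** The cited PPE implementations do not print their formula, so both
conventions are exposed: absolute PPE $100\,|obs-pred|/pred$ (used for
group means and confidence intervals, $t$-based with $n-1$ df) and a
signed variant $100\,(pred-obs)/obs$ whose sign puts underestimation left
of zero in density plots. Density plots use a sign-preserving pseudo-log,
$\mathrm{sign}(s)\log_{10}(1+|s|)$, which keeps an exact prediction at
zero; the transform behind the published density plots is unstated, so
this is a package convention. Because the stylopodial sample (n = 266) is
far larger than the volumetric one (n = 33), `subsample_mean_ppe()`
repeatedly subsamples the former to the latter's size — without
replacement, since the study design subsamples rather than bootstraps —
1000 iterations by default.

**Robustness allometry.** Robustness is circumference/length of a
stylopod. `robustness_study()` fits log10 circumference on log10 length
per clade (null slope 1: geometric similarity) and log10 robustness on
log10 volumetric-predicted mass (null slope 0). Allometry verdicts are a
CI trichotomy: positive if the 95% CI sits entirely above the null,
negative if below, isometry otherwise.

**Center of mass.** Segment masses are volume × expansion factor ×
density; the body CoM is their mass-weighted centroid mean. Two positional
proxies are used: the percentage cranial along the acetabulum→glenoid
transect (%C(AG)) and the distance cranial of the acetabulum divided by
femur length (DCA/FL). Both derive from the same projection of the CoM
onto the acetabulum→glenoid unit vector, making them proportional for a
given body; this single-axis convention is a design choice, since the
original measurement protocol is described only in supplementary material
not shipped here. Both metrics are exactly invariant to uniform density
rescaling, which is why varying density across the measured 893–1080
kg/m³ range cannot move them.

## Expansion factors, deflation, and variants

Hull-to-skin expansion factors are segment-wise means of skin:hull volume
ratios across reference specimens (`compute_expansion_factors()`),
yielding mammal-specific (MEF) or sauropsid-specific (SEF) tables. The
published numeric MEF/SEF values live in their original sources and are
supplied by the user; `synthetic_expansion_table()` provides clearly
labelled synthetic stand-ins for tests and demonstrations. Expansion is
modelled as uniform inflation about the segment centroid — centroids stay
put, masses scale — because whether the original models recomputed
centroids after inflation is unstated; centroid-preserving inflation is
the conservative reading and keeps the identity "factor $f$ on one segment
changes total mass by exactly $(f-1)V\rho$". Trunk deflation variants
(90/80/70% of hull volume) emulate a lower-density trunk through the same
mechanism. `com_study()` runs every variant, regresses each CoM metric on
log10 skull:tail volume ratio per clade, and flags regressions at the
p < 0.05 gate used for plotting; no multiple-testing correction is
applied, since none is described for the original analysis.

## The synthetic-data generator

The generator exists so every stage is testable without the study's CT
meshes or supplementary tables.

**Bodies.** `make_body()` lays out the 16 canonical segments (skull, neck,
trunk, tail, and stylopod/zeugopod/autopod for four limbs) as boxes along
a cranio-caudal axis, with landmarks at the trunk corners. Boxes and
polygonal frusta have exact analytic hull volumes and centroids
(agreement to 1e-12 is a test invariant); ellipsoid point clouds inscribe
their ellipsoid, so hull volume approaches $\tfrac43\pi abc$ from below —
the same direction of bias a hull has around a real body. The skull box
is sized to hit a requested skull:tail volume ratio exactly, so
`synthetic_com_sample()` can build clade templates spanning a ratio
gradient: crocodylian-like (tail ≫ skull), mammal-like (skull > tail),
fossil-like (intermediate). Since a relatively larger skull pulls the CoM
cranially, %C(AG) rises with the ratio by construction; what the CoM
acceptance check demonstrates is therefore that the pipeline recovers a
known geometric relationship through the hull→assembly→metric path, not
that real crocodylians behave this way.

**Populations.** `make_population()` draws specimen tables under the
published coefficients (0.968/0.215; 2.716/−4.078; per-clade robustness
slopes) across the published extant mass span (0.127–2735 kg,
log-uniform). Residual scatter defaults to σ = 0.15 log10 units — a
generator convention chosen to give r² values near the published fits,
not a published quantity. Three mutually linked regressions cannot all be
generated with noise purely in the response from a single latent chain,
so the generator is anchored: the default limb-length anchor generates
circumference (robustness law) and then mass (stylopodial law) with
response noise and back-derives hull volumes, while `anchor = "volume"`
generates mass from the volumetric law with response noise.
Parameter-recovery tests use the anchor that makes the tested law the
generative regression; refitting a law whose noise entered on the
predictor side is mildly attenuated (a well-known errors-in-variables
effect), which is why the default anchor places that side on the
volumetric law, whose slope is closest to the data's dominant variance.
One consequence of the shared chain is that the two methods' per-specimen
errors are correlated in synthetic tables, unlike in real data.

**Fossils.** `make_fossil_set()` gives fossils a steeper robustness law
(default slope 1.319, intercept −1.053) than the extant laws behind the
stylopodial equation, so stylopodial estimates exceed volumetric ones
increasingly with size — the qualitative discrepancy pattern. The
magnitude of the synthetic ratios exceeds the published ones because the
synthetic chain applies the slope gap over the full length range with a
mammal-anchored "true" mass; the pattern, not the magnitude, is the
generator's target.

**Seeding.** All randomness flows from one integer master seed through
`split_seed(seed, stream)`, so modules can be regenerated independently
and every pipeline output is byte-reproducible under a fixed seed.

## Numerical choices and degenerate inputs

- Hull construction uses a visibility tolerance scaled to the bounding-box
  diagonal (1e-10 relative), so metre- and millimetre-scale inputs behave
  identically; degenerate point sets report their affine rank.
- STL input (a triangle soup) merges coincident vertices at 1e-9 absolute
  tolerance; binary STL is single precision, which bounds cross-format
  agreement at ~1e-7 relative rather than the 1e-9 of the double-precision
  formats.
- Log-log fits require strictly positive inputs and n ≥ 3; through-origin
  fits require a non-degenerate predictor. An exact fit reports skewness 0
  by convention.
- Tail sub-segments (`tail_sub_k`) simply sum into the tail volume for the
  skull:tail ratio, mirroring the mixed single-hull/subdivided-tail
  treatment of the source datasets.
- `estimate_fossils()` reports the SS/MCH ratio at full precision and the
  published-style table rounds to 1 decimal only for display.

## Problem sizes used in validation

The test-suite defaults were chosen to keep the full run in the order of a
minute while leaving Monte-Carlo and coverage margins comfortably
resolvable: rejection-sampling oracles use 10⁶ samples on 20 seeded random
polytopes (3-standard-error agreement); CI-coverage checks use 500
replicate populations per law at the published sample sizes (n = 33
volumetric, n = 266 stylopodial, n = 9 fossil robustness); the residual-SD
convergence check uses one n = 10,000 population.

## Known limitations

- Synthetic bodies are box assemblies: adequate for exact volumetric
  ground truth, silent on mesh pathologies of real CT segmentations
  (holes, osteoderms, pose variation), which are out of scope.
- Passing the synthetic CoM checks shows the pipeline recovers constructed
  relationships; it does not validate the biological regressions, which
  require the original specimen models.
- Phylogenetically informed regression (GLS) is deliberately excluded —
  accounting for relatedness was reported to leave the predictive
  equations essentially unchanged — as are SMA/RMA fits and
  heteroscedasticity-robust errors.
- The supplementary specimen tables are not shipped; the acceptance check
  that refits them runs only when the user supplies
  `inst/extdata/supplementary/extant_specimens.csv`.
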