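# masshull

Body-mass estimation for quadrupedal tetrapods from whole-body **minimum
convex hull (MCH) volumetrics** and from **stylopodial scaling** (combined
humerus + femur midshaft circumference), with the statistical machinery to
compare the two: percent-prediction-error (PPE) accuracy and precision,
limb-bone robustness allometry, and center-of-mass (CoM) positional
metrics. It is aimed at paleobiologists and comparative biomechanists who
estimate the mass of extinct animals — particularly taxa whose anatomy
falls outside the extant calibration range, where the two estimators can
disagree several-fold.

## The models

Segment meshes (OBJ/PLY/STL) are wrapped in convex hulls; exact hull
volumes and solid centroids come from signed-tetrahedron summation over
the oriented boundary. Summed hull volume × density feeds the volumetric
predictive equation, an OLS fit on extant taxa of known mass
(n = 33):

    log10(Body Mass) = 0.968 · log10(MCH Volume × Density) + 0.215

with mass in kg, volume in m³, density in kg/m³ (1000 by default). The
element-scaling alternative (n = 266 extant amniotes) is

    log10(Body Mass) = 2.716 · log10(Humerus + Femur Circumference) − 4.078

with circumference in mm. Accuracy and precision are compared by PPE per
specimen and t-based 95% CIs on group means, with the larger stylopodial
sample subsampled (1000×, without replacement) to the volumetric sample
size. Stylopod *robustness* — circumference/length — scales differently
across clades (and more steeply in Permo-Triassic fossils), which is why
a largely mammal-calibrated circumference equation overestimates
large-bodied sprawling taxa. CoM position is summarised as %C(AG), the
percent cranial along the acetabulum→glenoid transect, and DCA/FL, the
CoM's distance cranial of the acetabulum in femur lengths; both can be
regressed on log10 skull:tail volume ratio across model variants
(expansion-factor-inflated segments, deflated trunks).

A synthetic-data module generates convex-primitive bodies with exact
analytic ground truth and specimen tables drawn under the published
scaling laws, so the entire pipeline is testable offline.

## Worked example

```r
library(masshull)

# a synthetic crocodylian-like body, run through the real mesh->hull pipeline
body  <- make_body(synthetic_body_spec("crocodylian_like", trunk_length = 0.4))
model <- body_from_synthetic(body, specimen = "croc_demo")
model
#> <body_model> croc_demo (crocodylian): 16 segments, volume 0.012308 m^3, mass 12.308 kg

predict_mass_mch(body_volume(model))   # volumetric equation, density 1000
#> [1] 18.63376

com_metrics(model)[, c("pct_AG", "dca_fl", "log10_skull_tail")]
#> # A tibble: 1 × 3
#>   pct_AG dca_fl log10_skull_tail
#>    <dbl>  <dbl>            <dbl>
#> 1   40.1   1.82           -0.824
```

The direct mass (volume × 1000 = 12.3 kg) is what a bare hull implies; the
predictive equation inflates it to 18.6 kg, the mass an extant animal with
this hull volume would typically have. The CoM sits 40% of the way from
hip to shoulder socket and 1.8 femur lengths cranial of the acetabulum
(consistent with quadrupedal posture); the negative skull:tail ratio says
the tail dwarfs the skull, as built.

Calibrating both equations on a synthetic population generated at the
published coefficients recovers them:

```r
pop <- make_population(synthetic_population_spec(seed = 42))
calibrate(pop)
#> <calibration>
#>  volumetric (MCH): <scaling_fit> log10-log10: slope 0.967, intercept 0.2327 (n = 33)
#>   slope 95% CI [0.9316, 1.002], r^2 = 0.9901, p = 1.18e-32
#>  stylopodial (SS): <scaling_fit> log10-log10: slope 2.721, intercept -4.087 (n = 266)
#>   slope 95% CI [2.68, 2.761], r^2 = 0.9849, p = 3.07e-242
```

`fossil_mass_estimates()` ships the published 12-taxon comparison table;
`estimate_fossils()`, `accuracy_report()`, `robustness_study()` and
`com_study()` run the corresponding analyses on any specimen table, and
`plot_ppe_density()` / `plot_com_study()` / `autoplot()` draw the standard
figures. A thin command-line wrapper is installed at `exec/masshull`
(subcommands `hull`, `calibrate`, `estimate`, `accuracy`, `robustness`,
`com`, `simulate`).

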