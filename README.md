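# petlesion

Quantifying the **relative positioning of lymphoma lesions** — aggregation
versus dissemination — from 3D PET standardized-uptake-value (SUV) volumes,
and evaluating its prognostic value. The package is aimed at imaging and
biostatistics researchers working on FDG-PET biomarkers in diffuse large
B-cell lymphoma (DLBCL), in particular around CAR T-cell therapy, where
classical dissemination markers (Ann Arbor stage III/IV, >1 extranodal
site) have shown weak prognostic value.

## What it computes

From an SUV volume, lesions are segmented by fractional-SUVmax thresholding
(voxels with SUV > 0.41 · SUVmax, strict), separated by flood-fill
connected-component labelling, cavity-filled, converted to watertight
triangular meshes (marching tetrahedra at iso-level 0.5, Taubin-smoothed),
and measured. Per patient this yields:

- **TMTV** = Σ lesion mesh volumes (mm³) and **TTS** = Σ surfaces (mm²),
  with the divergence-theorem volume V = (1/6) Σ_faces v₀·(v₁×v₂);
- **TVSR** = TMTV / TTS (mm), a compactness measure of aggregation
  (a single sphere of radius *r* has TVSR = *r*/3, and always
  TVSR ≤ (3·TMTV/4π)^{1/3}/3 by the isoperimetric inequality);
- **bulky disease**: any lesion with 3D caliper diameter > 5.0 cm;
- **extra stage** (dissemination): lesions above *and* below the diaphragm
  *and* more than one distinct extranodal organ involved.

The survival module mirrors the standard prognostic battery — Kaplan–Meier
curves, log-rank tests, univariate/multivariate Cox proportional-hazards
models (Efron ties), Spearman correlations and ROC analysis with the
Youden-index cutoff — and `run_study()` assembles them into one report,
including the three-level synergy stratification (*neither / either /
both* indicators).

Since clinical PET datasets cannot ship with the package, a synthetic-data
module generates phantoms with analytically known 41%-isocontour geometry
(uniform spheres/ellipsoids, Gaussian blobs) and cohorts with exponential
proportional-hazards survival at stated effect sizes; all validation runs
against those closed-form truths.

## Worked example

```r
library(petlesion)

# a noise-free phantom containing one 10 mm sphere
ph <- make_phantom(phantom_spec(
  grid_shape = c(26, 26, 26),
  lesions = list(lesion_sphere(center = c(12.5, 12.5, 12.5), radius = 10))
))
lab <- segment_lesions(ph$volume, verbose = FALSE)
measure_lesions(lab, ph$volume)
#> # A tibble: 1 × 9
#>   label voxel_count volume_mm3 surface_mm2 suvmax max_diameter_mm ...
#> 1     1        4224      4223.       1275.      5            20.5
```

The analytic sphere has volume 4188.79 mm³ and surface 1256.64 mm²; the
measured mesh is within 0.9% and 1.5% respectively, and TVSR = 4223/1275 =
3.31 mm against the exact r/3 = 3.33 mm.

```r
# simulate a 200-patient cohort (both indicator log-HRs = ln 2.5) and
# run the full prognostic study
demo <- demo_study(seed = 1)
demo$report
#> Prognostic study report (n = 200 patients)
#> TVSR vs CR: AUC 0.617, Youden cutoff 6.77 mm
#> ...
#>   stratum     n n_events median
#> 1 neither    80       40  270.
#> 2 either     99       70  204.
#> 3 both       21       18   53.3
#>   comparison        chi_square   p_value
#> 1 both vs either         18.2  0.0000204
#> 2 neither vs either       4.87 0.0273
```

Patients carrying both the aggregation and the dissemination indicator do
markedly worse than patients with either one (median 53 vs 204 days,
log-rank p = 2·10⁻⁵), who in turn do worse than patients with neither —
the synergy pattern the indicators are designed to capture. TMTV and TVSR
are strongly rank-correlated on such sphere-like disease (ρ = 0.86 here),
which is why TVSR adds little over TMTV in this setting.

A thin command-line wrapper over the same functions is installed at
`inst/cli/petlesion-cli.R` (verbs: `simulate-phantom`, `simulate-cohort`,
`segment`, `measure`, `indicators`, `study`, `demo`; NIfTI in, CSV/STL
out).

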