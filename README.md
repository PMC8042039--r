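# climorph

Geometric-morphometric analysis of climate-associated midfacial shape.

Human midfacial and upper-respiratory anatomy — external nose, internal
nasal cavity, choanae, maxillary sinuses — is hypothesized to adapt to
temperature and humidity: cold, dry inspired air must be warmed and
humidified. Testing this across worldwide cranial samples is confounded by
geography, because neighbouring populations share both climate and
ancestry. `climorph` implements a pipeline built around a **geographically
weighted reduced rank regression** that addresses exactly this confound,
and projects individual specimens — including out-of-sample fossils — into
the *adaptive shape space* spanned by its leading dimensions.

## The model

For `g` groups with standardized climate design `X` (`g x p`; TMN/TMX in
°C, HMN/HMX in hPa, z-scored) and column-centered group mean Procrustes
shape coordinates `Y` (`g x q`, `q = 3L` for `L` landmarks), spatial
non-independence is encoded by the similarity weights

    W_ij = (d_max − d_ij) / d_max        (1 for coincident groups, 0 at the maximal pair)

and the fit is

    B = (X′ W⁻¹ X)⁻¹ X′ W⁻¹ Y,      U D V′ = B   (thin SVD, r = min(p, q)).

Each singular value `d_k` is the regression slope of the latent shape score
`Y v_k` on the latent climate score `X u_k`; `d_k² / Σ d_j²` is dimension
k's share of the summed squared partial regression coefficients, and the
generalized R² is `1 − tr(E′W⁻¹E)/tr(Y′W⁻¹Y)` with `E = Y − XB`. Unlike
two-block PLS, the decomposition maximizes the *effect* of a unit climate
change on shape, not the covariance.

Around the estimator, the package provides the full preprocessing chain
(generalized Procrustes alignment with proper rotations, object-symmetry
symmetrization, thin-plate-spline imputation of missing landmarks with the
`> 4 missing → exclude` rule, sex-dimorphism correction, centroid-size
partitioning into five anatomical regions), file formats (wide landmark
CSV, 3D TPS files, climate and distance CSVs, YAML schemes and models), and
a seeded synthetic-data generator with known ground truth.

## Worked example

Fit the weighted RRR to a synthetic study generated at the emulated design
scale (16 groups, 61 landmarks, 4 climate variables):

```r
library(climorph)
truth <- synthetic_truth(seed = 42)                    # known ground truth
gg    <- simulate_groups(truth, seed = 42)             # locations + climate
gs    <- simulate_group_shapes(truth, gg$climate, gg$D, seed = 42)
W     <- weights_from_distances(gg$D)
model <- fit_weighted_rrr(gs$X, gs$Y, W)
model
#> Weighted reduced rank regression: 16 groups, 4 climate variables, 183 shape coordinates
#> dimension shares: 69.5%, 22.1%, 5.1%, 3.3%
#> variance explained (generalized R^2): 98.7%

round(climate_loadings(model, 1), 3)
#>    TMN    TMX    HMN    HMX
#> -0.546 -0.295  0.752 -0.221

abs(cor(shape_loading(model, 1), truth$v_true[, 1]))
#> [1] 0.992

head(round(adaptive_scores(model, gs$Y), 4), 4)
#>        dim1   dim2
#> G01  0.0016 0.0031
#> G02 -0.0376 0.0035
#> G03  0.0304 0.0070
#> G04  0.0221 0.0093
```

The first loading vector contrasts cold/dry against warm/humid climates;
group mean scores along `dim1` ordinate the groups on that axis, and the
fitted first shape loading correlates with the generating one at 0.99.
The generating spectrum here is 73/21/4/2 % — the estimated shares drift
(69/22/5/3 %) because the simulated climate variables are as collinear as
real ones; the loadings are the stable quantities.

The five numbered drivers under `analysis/` run the same machinery
end-to-end on a ~310-specimen synthetic study — simulate and knock out
landmarks, preprocess (exclusion, TPS imputation, symmetrization, sex
correction), fit, project all specimens plus two held-out fossils, and
summarise centroid sizes — writing their tables under
`results/synthetic_study/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_wrrr.R
Rscript analysis/04_project_specimens.R
Rscript analysis/05_size_analysis.R
```

`inst/extdata/group_climate.csv` ships the published climate/location table
for the 16 modern study groups and the two Upper Palaeolithic individuals
(Sungir, Mladeč), ready for `read_climate_csv()` when real landmark data
are available.

## Package layout

- `R/` — the implementation: schemes and specimen containers, morphometry
  (`gpa_align`, `symmetrize`, `impute_missing`, …), climate/geography
  (`zscore_columns`, `haversine_matrix`, `weights_from_distances`,
  `variogram_diagnostic`), the estimator (`fit_weighted_rrr`,
  `dimension_shares`, `variance_explained`, `adaptive_scores`,
  `regress_size_on_climate`), the generator (`synthetic_truth`,
  `simulate_specimens`, `knockout_landmarks`) and the orchestration
  (`run_pipeline`, `report_sizes`).
- `vignettes/climate-shape-methods.Rmd` — the methods vignette: model,
  assumptions, defaults and their rationale, numerical choices, and known
  limitations.
- `tests/testthat/` — unit, property and acceptance suites.
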