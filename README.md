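# nucmorph

Quantifying how epithelial cell shape deforms the nucleus — and how the
nucleus responds. In stratifying epithelia, apico-basal compression of
cells flattens their nuclei; the flattening stretches the nuclear
lamina, and Lamin A/C levels rise with that stretch while the
phosphorylated (soluble) Lamin fraction falls. `nucmorph` implements the
full measurement chain for this mechanism: dimensionless shape indices,
a volume-conserving spheroid model of nuclear surface-area strain, 3D
fluorescence image quantification, permutation statistics, and
Hertz/Sneddon fitting of AFM indentation curves — plus a synthetic-data
generator with known ground truth so every stage is validated end to
end.

## The core model

Cell and nuclear shape are summarised by two scale-free indices
(`A` apical area, `h` height, `A_n` nuclear cross-section, `h_n`
nuclear height, all in µm):

- `D_cell = ln(A / h^2)` — 0 for a cube, positive for squamous,
  negative for columnar cells;
- `D_nuc  = ln(4 A_n / (pi h_n^2))` — 0 for a spherical nucleus,
  positive for flattened (oblate), negative for elongated (prolate).

The nucleus is modelled as a spheroid with semi-axes
`a = sqrt(A_n/pi)`, `c = h_n/2`. Its **surface-area strain**
`ΔS = (S_spheroid − S_sphere) / S_sphere`, relative to the sphere of
equal volume, is the geometric proxy for lamina stretch: `ΔS ≥ 0`
always, zero only for a sphere, increasing with `|ln(a/c)|` at fixed
volume.

## Worked example

```r
library(nucmorph)

# A squamous cell, 100 um^2 apical area, 5 um tall:
cell_deformation_index(100, 5)
#> [1] 1.386294

# Its nucleus: 50 um^2 cross-section, 3 um tall
nuclear_deformation_index(50, 3)
#> [1] 1.956363
shp <- spheroid_from_measurements(50, 3)
shp
#> <spheroid_shape> n = 1
#>   a = 3.989 um, c = 1.5 um  [oblate]
surface_area_strain(shp)
#>   volume sphere_radius sphere_surface spheroid_surface  strain
#> 1    100      2.879412       104.1879         124.9286 0.19907

# Synthetic cohort with ground truth, and the strain-Lamin association
co <- sample_cohort(archetype_presets()$squamous, lamin_link_params(),
                    n = 1000, seed = 1)
permutation_fdr(co$true_strain, co$lamin, "spearman",
                n_iterations = 10000, seed = 2)
#> <correlation_result> spearman r = 0.7114 (n = 1000),
#>   FDR = 9.999e-05 (two-sided, 10000 perms) *

# AFM: synthesise a 5 kPa indentation curve and fit it back
cu <- generate_force_curve(5000, spring_constant = 0.1,
                           indenter = indenter_cone(25), seed = 1)
fit_force_curve(cu)
#> <indentation_fit> cone_25deg: E = 5042 Pa (nu = 0.5, 147 pts, RMS 2.11e-11 N)
```

End-to-end runs are driven by a single seeded configuration and are
byte-reproducible:

```r
cfg <- run_config(seed = 7)
res <- run_all(cfg, "runs/demo")   # simulate -> quantify -> stats -> afm
res$correlations                   # Spearman + permutation FDR per pair
```

A command-line interface with `simulate`, `quantify`, `stats`, `afm` and
`run-all` subcommands lives at `inst/cli/nucmorph.R`.

## Package layout

| Area | Key functions |
|---|---|
| Geometry | `cell_deformation_index`, `nuclear_deformation_index`, `spheroid_from_measurements`, `surface_area_strain` |
| Synthetic data | `archetype_presets`, `sample_cohort`, `render_nucleus_stack`, `render_junction_image`, `generate_force_curve` |
| Image quantification | `segment_nucleus_3d`, `nucleus_morphometry`, `lamin_in_nucleus_3d`, `apical_areas_from_junctions` |
| Statistics | `correlation`, `permutation_fdr`, `binned_scatter`, `loess_trend`, `group_compare` |
| AFM | `force_vs_separation`, `fit_cone`, `fit_pyramid`, `fit_force_curve`, `stiffness_map` |
| Pipeline | `run_config`, `simulate_run`, `quantify_run`, `stats_run`, `afm_run`, `run_all`, `audit_cohort` |

See `vignettes/methods.Rmd` for the model, all defaults with their
rationale, and the numerical choices (global Otsu threshold, z-aligned
height axis, sub-sample AFM contact refinement, determinism scheme).

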