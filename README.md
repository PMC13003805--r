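# vsdmri

Intravoxel **vessel size distribution (VSD) imaging** by simulated
susceptibility-contrast MRI, as a self-contained, tested R package.

## The problem

Vascular remodeling — in tumors, small-vessel disease, diabetes — changes
not just how much blood a voxel holds but the *sizes* of the vessels
holding it. `vsdmri` implements a pipeline that recovers, per volume of
interest (VOI), both

* **CBV**, the cerebral blood volume fraction, and
* the **VSD**, the vessel-volume-fraction (vvf) weighted histogram of
  vessel radii (forty 1 µm bins, normalized by the tallest bin),

from the ratio of pre- and post-contrast **GESFIDE** signals (gradient-echo
sampling of the free induction decay and spin echo: 18 echoes at
10–180 ms, ideal 180° pulse at 60 ms, spin echo at 120 ms). An
intravascular iron-oxide agent (susceptibility shift Δχ = 10⁻⁶ at 3 T)
turns every vessel into a microscopic field perturber; water diffusing
(D = 10⁻³ mm²/s) through those field gradients encodes vessel radius in
the echo-time dependence of the signal, which a two-stage neural estimator
learns to invert.

The pipeline stages, each an exported function family:

1. `generate_network()` — seeded 3D vascular networks with exact ground
   truth (per-tube radius and vvf, CBV, VSD), plus `render_lsfm_like()`
   for wall-stained light-sheet-like intensity volumes;
2. `enhance_contrast()`, `segment()`, `fill_lumens()`,
   `skeletonize_and_label()`, `vessel_table()`, `compute_vsd()` — the
   morphometry cascade (CLAHE, Otsu, spherical-kernel closing, 3D
   homotopic thinning, star-line radii);
3. `simulate_gesfide()` — Fourier dipole field plus explicit
   Bloch–Torrey evolution with periodic boundaries (compiled kernel);
4. `filter_and_split()`, `train_two_stage()`, `predict()` — the CBV
   estimator (18→2048→…→8→1, ReLU output) and VSD estimator
   (19→2048→…→64→40, sigmoid output), trained with Adam (β₁ = 0.5,
   β₂ = 0.9, lr = 10⁻⁴) on MSE, stage 2 with the frozen stage-1
   prediction as 19th input;
5. `dictionary_match()`, `vsi_mri()`, `vsi_histo()` — the comparators:
   maximum-R² fingerprint matching and the analytical vessel size index
   `VSI = 0.425 (ADC/(γΔχB₀))^{1/2} (ΔR2*/ΔR2)^{3/2}`;
6. `bhattacharyya()`, `mre()`, `bland_altman()`, `add_noise()`,
   `stitch_map()` — evaluation and parametric-map assembly;
7. `run_pipeline()` / the `inst/cli/vsdprint` script — one-config,
   seeded, end-to-end orchestration with a checksummed manifest.

See the methods vignette (`vignettes/vsd-imaging-methods.Rmd`) for the
models, numerical choices and limitations.

## Worked example

```r
library(vsdmri)

# a 115 µm VOI with 10% CBV and known per-vessel truth
g   <- voxel_grid(c(64, 64, 64), 1.8)          # voxels, µm
net <- generate_network(g, target_cbv = 0.10, seed = 3)
net$truth
#> <generative_truth> 18 tubes, CBV = 9.841%, 18 visible vessels

# simulate its GESFIDE signal ratio on a 2x coarsened grid
frac <- vsdmri:::downsample_mean_cpp(as.numeric(net$volume$mask),
                                     g$shape, 2L)
attr(frac, "grid") <- voxel_grid(c(32, 32, 32), 3.6)
curve <- simulate_gesfide(frac, sim_config())
round(curve$ratio[c(1, 4, 6, 12)], 3)
#> [1] 0.846 0.251 0.084 0.280
```

The ratio decays steeply over the free-induction echoes (0.85 → 0.08 by
60 ms: static dephasing around vessels), then partially recovers at the
refocused 120 ms spin echo (0.28) — exactly the radius-dependent contrast
the estimator exploits. Contrast-induced relaxation changes and the
analytic size index follow directly:

```r
delta_r2_star(curve)   # 1/s, from the 10 and 40 ms echoes
#> [1] 40.47073
delta_r2(curve)        # 1/s, from the 120 ms spin echo
#> [1] 10.59857
vsi_mri(delta_r2_star(curve), delta_r2(curve))  # µm
#> [1] 3.540032
```

Morphometry of the same mask recovers the generator's ground truth:

```r
m <- morphometry(net$volume, fill = FALSE)
c(cbv = m$cbv, vessels = nrow(m$table), mean_radius = m$mean_radius)
#>        cbv     vessels mean_radius
#> 0.09841156 44.00000000  5.45613391
bhattacharyya(net$truth$true_vsd, m$vsd)
#> [1] 0.9053793
```

A complete desk-scale study — generate, simulate, train both estimators,
evaluate against the dictionary baseline and under noise — runs from one
configuration:

```r
cfg <- default_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)   # writes dataset/, models.rds, metrics.json, manifest.json
```

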