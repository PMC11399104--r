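# prodolr

Cell-by-cell degree-of-labeling (DOL) estimation for protein tags
(SNAP-tag, HaloTag) from dual-channel diffraction-limited single-molecule
images.

Quantitative fluorescence microscopy needs to know which fraction of a
tagged protein actually carries a dye — labeling is never complete and
depends on substrate, concentration, incubation time, fixation and cell
type. `prodolr` measures this fraction with a calibration probe that pairs
the tag with an eGFP reference: every probe copy appears in the reference
channel, only labeled copies in the dye channel, and the DOL per cell is
the specific colocalized fraction corrected for density-dependent
detection losses,

```
DOL = ( F_c(T) − F_r(T) ) / ( CF_slope · ρ + CF_offset )
```

where `F_c(t)` is the one-to-one matched fraction of reference signals
within distance `t`, `F_r(t)` the same after rotating the target channel
90° (the random-colocalization null), `T` the tolerance maximizing
`z = F_c − F_r`, `ρ` the measured target-signal density, and
`CF_slope`/`CF_offset` the recall line calibrated on simulated data
processed with identical settings. A tag-free control probe turns
unspecific substrate binding into a density per µm² of cell area.

The package implements the full pipeline — cell segmentation, sub-pixel
spot localization with PSF-width filtering (compiled multi-emitter
Gaussian fitting), quality-gated affine chromatic registration, exact
one-to-one colocalization with cutoff optimization, density-recall
calibration, per-cell/per-condition reporting — plus a synthetic
dual-channel image simulator (blinking/bleaching photophysics, Gaussian
PSF, EMCCD noise, chromatic offset) so every stage is testable without
microscope data, and ensemble-DOL/copy-number arithmetic for antibody
calibration and cluster stoichiometry.

## Worked example

Calibrate the recall line once per analysis-settings/imaging-condition
combination (~2 min of simulation), then analyze a condition:

```r
library(prodolr)

cal <- calibrate_recall(sim_config(), analysis_config(), seed = 7)
cal
#> <density calibration> recall = -0.0394 x density + 0.9193 (R^2 = 0.142, range 0.04-0.44 /um^2)

# a simulated condition stands in for a folder of TIFFs (see read_image)
cfg   <- sim_config(true_dol = 0.4, probe_density_um2 = 0.2)
cells <- simulate_experiment(cfg, n_cells = 8, seed = 42)

ana <- analyze_experiment(cells, analysis_config(), calibration = cal)
ana$curve
#> <coloc curve> T = 310 nm, F_c(T) = 0.386, F_r(T) = 0.001, z(T) = 0.384 (n_ref = 1343)

head(ana$results[, c("cell_id", "n_reference", "degree_of_colocalization",
                     "dol", "unspec_density_um2", "qc_flags")], 4)
#>    cell_id n_reference degree_of_colocalization       dol unspec_density_um2 qc_flags
#> 1 cell_001         187                0.4171123 0.4561026         0.02181315
#> 2 cell_002         170                0.2764706 0.3017261         0.01567806
#> 3 cell_003         168                0.3809524 0.4162149         0.02424059
#> 4 cell_004         167                0.3592814 0.3923943         0.01938886

summarize_condition(ana$results, "Halo-TMR 100 nM")
#> Halo-TMR 100 nM: DOL 40.8 +/- 5.4% (median +/- s.d., n = 8 cells), unspecific 0.021 /um^2
```

The condition was simulated at a true DOL of 0.40: the pooled cutoff
lands at 310 nm where random colocalization is still ~0.1%, the per-cell
specific fractions scatter binomially around 0.38, and the recall
correction (≈0.91 at these densities) returns a condition median of
40.8%. The unspecific density matches the simulated 0.02/µm².

For antibody work, the ensemble arithmetic reproduces textbook hand
calculations, e.g. an absorbance-based ensemble DOL of 1.27 with a mean
of 1.38 dyes among labeled antibodies gives an unlabeled fraction of
`1 − 1.27/1.38 = 0.0797` → 8%:

```r
dol_percent(unlabeled_fraction(1.27, 1.38))
#> [1] 8
```

A thin command-line wrapper for the stage-by-stage workflow
(`simulate`, `segment`, `localize`, `register`, `coloc`, `ensemble-dol`)
ships in `inst/scripts/prodol`.

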