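# rifinger

Label-free detection and localization of nanoparticles inside live cells
from 3-D refractive-index (RI) stacks, as produced by optical diffraction
tomography (holotomography).

**Who it is for.** Nanotoxicology and bioimaging groups that need the
*intracellular* nanoparticle dose — not the exposure concentration — from
label-free microscopy, and need the image-analysis chain to be testable
without access to the original instrument data.

## The method

For each cell the package computes an **RI fingerprint**: the histogram of
in-cell voxel RI values on a fixed grid (default bin width 0.0025 RIU,
anchored at 1.3000), expressed as percent of in-cell voxels so cell size
cancels,

$$f_k = 100 \cdot \frac{\#\{v \in \text{cell} : b_k \le \mathrm{RI}(v) < b_k + w\}}{\#\{v \in \text{cell}\}}.$$

Control cells are tightly stereotyped (support 1.365–1.395, mode ≈ 1.3725,
99.5% of voxels in 1.365–1.39, 34% below the mode). Nanoparticles with RI
above cellular values shift the fingerprint right in a dose-dependent way.
Voxels in the **nanoparticle band 1.39 ≤ RI ≤ 1.41** are flagged, grouped
into 26-connected accumulations, and counted: the band voxel count (or
percent of cell voxels) is the relative uptake estimate, and the band mask
is the classical red overlay. A matched fluorescence channel validates the
detections (Manders M1, Dice; Otsu binarization with a bimodality guard)
and rules out the chromatin confounder (nuclear voxels can exceed RI 1.39
but are not fluorescent). Per-dose statistics use Student's t, one-way
ANOVA and Fisher's protected LSD.

Because no public dataset accompanies the workflow, the package ships a
calibrated **synthetic phantom** (ellipsoidal cell + nucleus, truncated
skew-normal compartment RI distributions fitted to the control fingerprint
statistics, perinuclear nanoparticle puncta, matched fluorescence, imaging
noise) with full ground truth; the entire pipeline is validated as a
parameter-recovery exercise. See `vignettes/methods.Rmd` for the model,
every tunable parameter, and the design decisions.

## Worked example

```r
library(rifinger)

cfg <- run_config(phantom = phantom_config(),   # full-size 96x256x256 phantom
                  doses = c(0, 0.25, 0.5),      # mg/mL
                  n_cells = 8, seed = 1, outdir = "demo_run")
rep <- run_pipeline(cfg)
print(rep)
```

Output (scaled phantom, 8 cells/dose, seed 1):

```
rifinger run: 24 cells across 3 dose(s)
Uptake by dose (band % of cell voxels):
 dose n mean_band_percent sem_band_percent
 0.00 8         0.5071012       0.01038544
 0.25 8         1.4546488       0.02372127
 0.50 8         2.3381252       0.01731030
Per-dose summary:
 dose n      mean         sem
 0.00 8  5.099369 0.001103705
 0.25 8 10.340439 0.051901350
 0.50 8 15.300671 0.057770765
One-way ANOVA: F(2, 21) = 12941.657, p = 3.49e-33
Fisher PLSD pairwise tests:
 dose_a dose_b      diff         t df            p
   0.00   0.25  5.241070  82.64555 21 6.981776e-28
   0.00   0.50 10.201302 160.86260 21 6.023785e-34
   0.25   0.50  4.960232  78.21706 21 2.211503e-27
```

Reading it: the control band load (~0.51% of voxels) is the genuine
high-RI tail of untreated cells; treated cohorts sit clearly above it and
scale with dose (≈ +0.9 pp per 1% planted NP fraction). Per-cell mean
fluorescence recovers the calibrated dose response (5.1 / 10.1 / 15.1 AU)
within cohort noise, and both treated doses differ from control at
p < 0.05. The dose-shift summary of the mean fingerprints:

```r
print(rep$shifts[["0.50"]])
#> Fingerprint shift (treated - control):
#>   peak height       -0.321 pp
#>   1.380-1.390 band    -0.238 pp
#>   high-RI (>1.390)   +1.840 pp
#>   area right of mode +1.101 pp
```

Other entry points: `generate_scene()` / `render_stacks()` (phantom with
ground truth), `segment_cell()`, `compute_fingerprint()` /
`fingerprint_stats()` / `compare_fingerprints()`, `detect_band()` /
`render_overlay()`, `binarize_fluorescence()` / `coloc_stats()` /
`classify_components()` / `group_compare()`, `read_ri_stack()` /
`write_ri_stack()` (multi-page float32 TIFF + JSON sidecar), and the CLI:

```sh
inst/cli/rifinger all      --seed 1 --outdir run --dose 0,0.25,0.5 --n-cells 8
inst/cli/rifinger simulate --seed 1 --outdir stacks --dose 0.5
inst/cli/rifinger analyze  --indir stacks --outdir results
inst/cli/rifinger report   --outdir results
```

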