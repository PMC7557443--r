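# adhesivect

Micro-CT quantification of the adhesive layer at the tooth/composite
restoration interface.

## What this is for

Composite restorations fail most often through microleakage along the
tooth/restoration interface, and the width/thickness *w* of the adhesive
film is the quantity that predicts that risk: the thinner and more uniform
the layer, the tighter the seal.  Micro-CT reconstructions give the full 3D
layer, and this package turns such a volume (or a synthetic phantom with
known ground truth) into the quantities used to compare restoration
protocols:

* the **local thickness field** of the segmented adhesive layer — per
  voxel, the diameter of the largest sphere fully inside the layer (the
  standard wall-thickness definition), computed exactly on the half-voxel
  grid;
* the **surface-area-versus-width distribution** S(w) — how much interface
  area carries each layer width — together with its anchor points
  (onset w0, peak (wM, SM), tail knot (wI, SI), terminal wmax);
* **piecewise linear/parabolic S(w) models** on width intervals
  (two template shapes: broad/late peak and sharp/early peak), fitted under
  C0 continuity constraints, with closed-form integrals;
* the **adhesive volume statistic** V = ∫ S(w) dw in its layer-cake reading
  Σᵢ areaᵢ·wᵢ (= physical layer volume), used to rank treatment groups;
* **Wilcoxon signed-rank** and **Mann–Whitney U** comparisons in the layout
  of standard statistics-package tables (rank counts, mean ranks, rank
  sums, tie-corrected p-values).

Four treatment groups are modelled by the built-in phantom presets: plain
adhesive (Group 1, widths 0.02–0.4 mm), adhesive doped with magnetic
nanoparticles (Group 2, 0.017–0.4 mm), and doped adhesive cured in a
magnetic field for 5 or 10 minutes (Group 3: 0.013–0.31 mm, Group 4:
0.011–0.032 mm) — the field pulls the film tight against the wall.

## Worked example

```r
library(adhesivect)

# Group 4 phantom (nanoparticle adhesive, 10 min field): 128^3 voxels at
# 2 um, analyzed end to end
report <- run_pipeline(run_config(preset = 4, seed = 1))
report
#> <run_report> group preset 4, seed 1
#>   thickness 0.002-0.02691 mm, peak width 0.016 mm
#>   V (layer-cake) = 0.0011198 mm^3; V_model (template B) = 0.0001308 mm^3
#>   true volume 0.0012124 mm^3 (V recovers 92.4%)
```

The report says: the segmented layer's widths run up to 0.027 mm with the
S(w) peak at 0.016 mm (inside the published 0.01–0.025 mm band for this
protocol); the physical adhesive volume V is 1.12·10⁻³ mm³, recovering 92%
of the ground-truth volume through a noisy segmentation.  Running all four
presets ranks the protocols:

```r
cmp <- run_group_comparison(seeds = 1)
cmp$runs[, c("group", "V", "wM", "dice")]
#>   group          V    wM      dice
#> 1     1 0.03809875 0.100 0.9985926
#> 2     2 0.03327425 0.070 0.9982249
#> 3     3 0.01629313 0.030 0.9969356
#> 4     4 0.00111976 0.016 0.9974473
cmp$ordering
#>    1
#> TRUE
```

Adhesive volume falls strictly from Group 1 to Group 4 — the longer the
magnetic field is applied, the less adhesive remains in the interface — and
the S(w) peak width shifts from 0.1 mm down to 0.016 mm.

The packaged per-sample width table (4 groups × 5 samples × 3 interface
areas × 2 methods) drives the statistics:

```r
t1 <- load_table1_fixture()
width_range(t1, 4, "micro-CT")
#>   min   max
#> 0.011 0.032
mann_whitney_u(t1$width_mm[t1$group == 1 & t1$method == "micro-CT"],
               t1$width_mm[t1$group == 4 & t1$method == "micro-CT"],
               labels = c("group 1", "group 4"))
```

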