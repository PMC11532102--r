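# fibertrace

Skeleton-based morphometry of muscle-fiber micrographs.

## What it measures, and for whom

Healthy skeletal muscle regenerates as straight, parallel myofibers; poorly
regenerating muscle (chronic pressure ulcers being the canonical case) shows
wavy, split, non-parallel fibers. `fibertrace` is for imaging and wound-repair
labs who want a reproducible, observer-independent score of that difference
from 2-D fluorescence micrographs.

Starting from a per-pixel edge-probability map P(E) — loaded from a file
produced by any edge detector, or computed by the built-in classical
gradient backend — the pipeline thins the map by non-maximum suppression,
cleans it by double thresholding (low/high thresholds t_l, t_h) with
hysteresis tracking, skeletonizes it to one-pixel width, traces the skeleton
into categorized edge segments (endpoint-to-endpoint, junction-to-endpoint,
junction-to-junction, isolated cycles), and excludes segments shorter than
100 µm in path length or 50 µm in end-to-end chord. Each image is then
summarized by:

| biomarker | definition |
|---|---|
| median tortuosity | median of τ = c/d, path length over chord, per segment |
| segment density | surviving segments per mm² |
| median edge segment distance | median traced path length c (µm) |
| orientation dispersion | SD and IQR of atan2(h, w) folded to [0, π) |

Treatment groups are compared with one-way ANOVA plus Tukey–Kramer post hoc
tests. A seeded synthetic fiber-scene generator with analytic ground truth
(orientation jitter, sinusoidal waviness with exact arc-chord tortuosity,
split events, shadow occluders) makes every stage verifiable without any
external dataset.

## Worked example

```r
library(fibertrace)

# six synthetic images per arm, emulating an acute injury (straight,
# parallel fibers) versus a chronic wound (short, wavy, split fibers)
cfg  <- pipeline_config(backend = "intensity")
tab  <- rbind(run_cohort(make_group_cohort("acute_like",   6, seed = 2), cfg),
              run_cohort(make_group_cohort("chronic_like", 6, seed = 3), cfg))
aggregate(cbind(median_tortuosity, median_segment_distance_um,
                iqr_orientation_rad) ~ group, tab, mean)
#>          group median_tortuosity median_segment_distance_um iqr_orientation_rad
#> 1   acute_like          1.002807                   285.5962          0.03567312
#> 2 chronic_like          1.034043                   128.4530          0.42372385

compare_groups(tab, biomarkers = "iqr_orientation_rad")
#> == iqr_orientation_rad ==
#> One-way ANOVA: F(1, 10) = 456.4, p = 1.125e-09
#>   acute_like vs chronic_like: diff = 0.3881, p_adj = 9.477e-10 ****
```

Read: chronic-like scenes produce higher tortuosity (wavier edges), much
shorter edge segments (fragmented fibers) and a ~10× larger orientation IQR
(loss of parallelism), with the acute/chronic contrast strongly significant
— the direction expected of real acute-injury versus chronic-wound tissue.

For real images: `run_pipeline("img.tif", pipeline_config(backend =
"gradient"), pixel_size_um = 1.24)`, or point `backend = "probfile"` at a
saved detector output (`invert = TRUE` if it has a white background).
`overlay()` writes the traced segments over the source image, one colour
per category. A thin command-line front end with `simulate`, `run`,
`compare` and `overlay` verbs is installed at `inst/cli/fibertrace.R`.

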