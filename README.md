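# perivasc

Multiscale quantification of nanocarrier delivery across the sonopermeated
blood-brain barrier from multichannel fluorescence microscopy.

After ultrasound + microbubble treatment (sonopermeation) transiently opens
the blood-brain barrier, drug delivery systems leave the vasculature and
penetrate into brain parenchyma. `perivasc` measures that process the way
the field reports it:

- **Penetration profiles** — the percentage of total nanocarrier
  fluorescence inside the vessel lumen and in consecutive 5 µm perivascular
  distance shells, in 2D cryosection fields and in 3D confocal stacks with
  anisotropic voxels. For a carrier channel *C*, segmented lumen *L*, and
  the exact Euclidean distance *d(x)* to the nearest lumen pixel, shell *k*
  is `S_k = { x : 5(k−1) < d(x) ≤ 5k }` µm and the profile entry is
  `100 · Σ_{S_k} max(C − bg, 0) / Σ_{L ∪ S_1..S_K} max(C − bg, 0)`.
- **Vessel-level metrics** — carrier-positive area fraction,
  extravasation-positive vessels per field-of-view, and the percentage of
  vessels with extravasated IgG (the biomarker of barrier opening), each
  via a gain-invariant ring-mean > k·MAD positivity rule.
- **Macroscale accumulation** — percent injected dose per 500 mm³ from a
  linear fluorescence calibration, plus treated-vs-control enhancement
  percentages.
- **Group statistics** — Student/Welch t-tests (raw samples or published
  mean ± SD summaries), two-way ANOVA over treatment × compartment with
  Bonferroni-corrected per-compartment comparisons, and `*`/`**`/`***`
  star formatting.

Because raw microscopy from such studies is rarely deposited, the package
ships a first-class **phantom generator**: seeded synthetic vessel fields
(discs in 2D, tilted cylinders in 3D slabs) whose penetration profiles,
leaky-vessel fractions and area fractions are known exactly, so every
stage of the pipeline is validated by parameter recovery.

## Worked example

Generate a 20-field cohort for the sonopermeated 10 nm polymer condition,
run the full pipeline (segmentation → distance shells → profile), and look
at the cohort means:

```r
library(perivasc)

spec   <- phantom_preset("polymer_US_2D", seed = 7)
cohort <- generate_cohort(spec, n_fields = 20, base_seed = 7)
tab    <- run_cohort(cohort$fields, pipeline_config())

round(colMeans(tab[grep("^pct_", names(tab))]), 2)
#>    pct_lumen      pct_0_5     pct_5_10    pct_10_15    pct_15_20
#>        52.54        17.79        11.89         9.89         7.89
```

The preset encodes the published condition means (lumen 53%, then
18/12/10/8% across the 5-20 µm shells, renormalized to sum to 100), and
the pipeline recovers them from noisy synthetic images to within a
fraction of a percentage point. Comparing against the untreated control
preset runs the statistics layer:

```r
ctrl     <- generate_cohort(phantom_preset("polymer_ctrl_2D", seed = 11), 20, base_seed = 11)
tab_ctrl <- run_cohort(ctrl$fields, pipeline_config(), condition = "control")
tab$condition <- "sonopermeated"
cmp <- compare_cohorts(tab, tab_ctrl)
tidy(cmp)[, c("compartment", "comparison", "estimate", "adjusted_p", "stars")]
#> pct_lumen (control vs sonopermeated): estimate 38.6, adjusted_p ≈ 0, ***
#> every 5 µm shell: higher under sonopermeation, adjusted_p ≈ 0, ***
```

`autoplot()` on a profile, `plot_cohort_profiles()` on cohort tables, and
`plot_shells()` on a shell map give the standard figures. Fields round-trip
to disk as 16-bit TIFF plus an OME companion XML carrying channel names and
physical pixel sizes (`write_field()` / `read_field()`); cohort tables are
CSV with units in the column names. A thin command-line wrapper lives in
`inst/cli/perivasc.R`.

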