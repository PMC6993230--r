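---
title: "Quantifying perivascular nanocarrier penetration with perivasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular nanocarrier penetration with perivasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivasc)
```

## The measurement problem

Opening the blood-brain barrier with ultrasound and microbubbles
(sonopermeation) lets nanocarriers leave the blood vessels and enter brain
parenchyma. The question a microscopist asks afterwards is not only *how
much* carrier arrived, but *how far* it travelled from the vessel wall.
The standard readout is a **penetration profile**: the percentage of total
nanocarrier fluorescence found inside the vessel lumen and in consecutive
5 µm distance shells around it, measured per field-of-view on
vessel-marker + carrier two-channel images (2D cryosections) or confocal
stacks (3D).

perivasc implements that readout end-to-end:

1. **Segmentation** (`segment_vessels()`): Gaussian smoothing with a
   physical-units sigma, Otsu thresholding, 1-pixel morphological closing,
   hole filling, minimum-size filtering, connected-component labeling
   (8-connectivity in 2D, 26 in 3D).
2. **Distance geometry** (`distance_map()`, `build_shells()`): an exact
   Euclidean distance transform from the lumen boundary outward, with
   per-axis physical sampling so 3D stacks with a z-step different from
   the in-plane pixel size are handled correctly; distances are binned
   into 5 µm compartments.
3. **Quantification** (`penetration_profile()`,
   `penetration_profile_3d()`, `area_fraction()`,
   `count_extravasation_positive_vessels()`, `igg_positive_vessel_pct()`,
   `percent_id()`).
4. **Statistics** (`two_group_ttest()`, `two_way_anova_bonferroni()`,
   `stars()`).
5. **Validation** (`phantom_spec()`, `generate_field()`,
   `generate_cohort()`): synthetic fields with exactly known ground truth.

## Coordinate and binning conventions

One set of conventions is used everywhere:

* Arrays are indexed `[y, x]` (2D) or `[y, x, z]` (3D); `pixel_size` is a
  per-axis vector in µm; all physical quantities are µm, µm², µm³ or
  percentages, and column names carry units.
* Distances are exact Euclidean distances between pixel centres, measured
  to the nearest **lumen pixel** (not the vessel centerline). The lumen is
  one pooled compartment at distance 0; rings grow from the vessel
  outline.
* Shell k collects distances in `(5(k-1), 5k]` — half-open,
  upper-inclusive, so a pixel at exactly 5 µm deterministically belongs to
  the inner shell.
* Pixels beyond the outermost shell are labeled `-1` and excluded from
  both the numerator and the denominator of the profile; their signal
  share is reported as `excluded_signal_pct` for transparency. Shell
  regions that touch the field border are quantified as-is and flagged
  `truncated` (no field-exclusion rule is applied).
* Shells of neighbouring vessels merge naturally through the
  nearest-vessel distance; `per_vessel_profiles()` offers an optional
  per-vessel split by nearest-vessel label, without double counting.

The distance transform is implemented as a separable lower-envelope
(parabola) scan per axis with squared per-axis spacings, which is exact for
Euclidean distance and also propagates the identity of the nearest lumen
pixel. Its exactness is not assumed: the test suite compares it against a
brute-force minimum-over-all-lumen-pixels oracle on dozens of random 2D
and anisotropic 3D instances, where both must agree to machine precision.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `smooth_sigma_um` | 0.5 | µm | sub-capillary smoothing; converted per axis so z-smoothing respects voxel anisotropy |
| threshold method | Otsu | — | parameter-free and invariant to uniform intensity scaling; an absolute threshold remains selectable for cross-study comparability |
| `min_size_um` | 10 (2D), 30 (3D) | µm², µm³ | suppresses speckle below capillary scale |
| `edges` | 5,10,15,20 (2D); 5..25 (3D) | µm | the conventional 5 µm ring spacing |
| `background` | median beyond outermost shell | counts | parenchyma far from any vessel is the cleanest per-field background estimate; a constant override is available |
| `positivity_k` | 2 | — | a vessel is extravasation-positive when its perivascular ring mean (background-subtracted) exceeds k × the MAD noise scale of far parenchyma; k = 2 holds the per-vessel false-positive rate below 5% on null phantoms (verified in the test suite) |
| `ring_um` | 5 | µm | the first shell is the natural "just outside the wall" region |

The vessel-positivity rule deserves a note: no published decision rule
exists for scoring a vessel as carrying extravasated carrier or IgG, so
the rule here is the package's own construction. It was chosen to be
invariant to uniform gain (both the ring mean and the noise scale rescale
together) and is exposed as a config knob; its default is validated
against the 5% false-positive bound on phantoms with no leaky vessels
rather than asserted.

## What the phantom generator emulates

`generate_field()` produces three channels — `vessel`, `carrier`, `igg` —
with exactly known ground truth:

* **Geometry.** 2D fields default to 512×512 pixels at 0.3 µm/pixel
  (~154 µm, a 20× field), 8-12 vessels of radius 3-10 µm. 3D stacks
  default to 256×256×60 voxels at 0.3×0.3×0.5 µm — a ~30 µm slab with a
  500 nm z-step — with 3-5 cylinders of radius 3-6 µm tilted within 20° of
  the slab plane. The smaller 3D vessel count/radius keeps the lumen
  fraction realistic and guarantees that the outermost shell exists
  laterally. The shell-fit requirement (twice radius-plus-outermost-edge
  must fit the field) is enforced in-plane; in z a thin slab truncates
  shells exactly as real 25-40 µm sections do, which is harmless because
  carrier mass is apportioned against the *realized* shell map.
* **Carrier placement.** The requested profile is realized exactly before
  noise: intensity mass per compartment is placed on the ground-truth
  shell map, with an exponential radial falloff (decay length 5 µm, one
  band width) inside each shell and a centre-weighted profile inside the
  lumen. Only per-band integrals are controlled; the sub-band texture is
  not a claim. The gentle falloff deliberately avoids concentrating mass
  at the lumen boundary, where a one-pixel segmentation error would
  otherwise move a disproportionate share of shell-1 signal.
  With `target_area_fraction` set, the carrier is instead placed as
  sparse puncta-like support occupying exactly that fraction of pixels.
* **IgG halos** (decay length 3 µm, range 10 µm) surround exactly the
  vessels flagged leaky. The leaky count uses randomized rounding of
  `fraction × n_vessels`, so the expected leaky fraction is exact.
* **Noise.** A camera model: baseline offset (100 counts), Poisson shot
  noise, Gaussian read noise with sd = 2% of the vessel peak, quantization
  to integer counts. The defaults keep SNR ≥ 5 so that segmentation
  accuracy, not noise modeling, is under test. The baseline matters:
  background-subtraction rules clip at zero, and the carrier total is
  scaled so that clipped read noise on dark compartment pixels stays below
  ~1% of the analyzed signal.

`phantom_preset()` bundles the study conditions: penetration-profile
presets for 10 nm polymers and 100 nm liposomes with and without
sonopermeation (2D and 3D), IgG leaky-vessel fractions (23.7% treated,
6.0% control), carrier area fractions (2.1% / 1.5%), and
extravasation-count conditions (6.8 / 0.6 positive vessels per FOV with 10
vessels per field). 2D profile presets are published group means
renormalized to sum to 100 (printed values sum to 100-102 because of
rounding; both raw and normalized values are stored). 3D presets print
only some compartments; the printed ones are generated exactly and the
residual is spread over unprinted shells with geometric decay (ratio 0.5
per shell outward, overridable) — untreated 3D conditions place no mass
beyond 10 µm.

**What the phantom does not emulate:** point-spread functions and
super-resolution optics, depth-dependent attenuation, vessel wall
thickness or pericyte coverage, tortuous or branching vasculature,
per-animal variance components (only per-field variation is modeled, with
group spreads arising from sampling), pharmacokinetics and barrier-closing
kinetics, and tomographic reconstruction. Passing recovery tests on
phantoms therefore demonstrates that the *computation* is correct and
unbiased under realistic noise and geometry — not that segmentation would
be equally accurate on arbitrary real stains.

## Statistics layer

Two-group comparisons use Student's pooled-variance t-test by default
(matching the two-group convention for these readouts); a Welch variant is
available, and the function suggests it when group SDs differ by more than
a factor of two. A `group_summary()` entry path reproduces tests from
published mean ± SD values with textbook formulas that agree with the
raw-data path to 1e-10 (tested). Because reported group sizes are not tied
to individual tests, the sample size for summary-based reproductions is
always an explicit argument; the IgG comparison in the examples uses n = 8
per pooled arm.

Treatment × compartment tables go through `two_way_anova_bonferroni()`:
classical sequential sums of squares when balanced, Type II (via car)
when not, followed by per-compartment treatment comparisons using the
pooled residual variance, Bonferroni-corrected over the number of
compartments (m = 4 or 5 for one panel). Stars follow *p<0.05, **p<0.01,
***p<0.001, strict inequalities.

## Numerical and degenerate-input choices

* Flat or empty vessel channels yield zero vessels with a warning, never
  an error; an empty lumen mask makes `distance_map()` fail loudly.
* A profile with zero total carrier signal above background is an error
  ("no carrier signal above background"), not a silent zero.
* Vessels whose perivascular ring is fully truncated away are excluded
  from positivity evaluation and reported.
* `enhancement_pct()` reports the unrounded value alongside a
  round-half-up integer, the convention used for printed enhancement
  percentages.
* Border-touching vessels are kept but flagged `on_border`.
* Otsu operates on a 512-bin histogram spanning the observed range, which
  preserves the scale-invariance property of the method.

## Problem sizes used in validation

The packaged validation runs at desk scale, chosen to finish in minutes on
one core while keeping the statistics meaningful: 20-field 2D cohorts
(512² px) per condition for profile recovery, segmentation accuracy and
vessel-level metrics; 10-stack 3D cohorts (256×256×60) per condition;
50 random instances (≤64 px per axis) for the distance-transform oracle;
200 resampled null comparisons for the empirical type-I error of the
t-test layer, which must land in [0.02, 0.09] at α = 0.05.

## Known limitations and open points

* The positivity rule and the segmentation recipe stand in for
  unpublished proprietary analyses; both are parameterized and validated
  on phantoms, but they are reconstructions, not re-implementations.
* Reported enhancement percentages for the liposome condition cannot be
  reproduced from the printed accumulation means (the printed means give
  roughly +23%, not the reported +35%, presumably because the published
  number was computed from unrounded or complementary data); likewise the
  ">600%" lumen-escape phrasing for treated polymers does not follow from
  the printed lumen percentages by an obvious formula. The package
  computes enhancements strictly from the supplied means and takes no
  position on those two numbers.
* Whether extravasation-positive vessels are best reported as counts per
  field-of-view or as a percentage of vessels is ambiguous in published
  panels; the pipeline reports both (`positive_vessels_per_fov` and the
  percentage form for IgG).
* The %ID conversion assumes a strictly linear fluorescence-amount
  calibration; depth-dependent attenuation is a tomography concern and is
  explicitly out of scope.

## A minimal session

```{r example, eval = FALSE}
library(perivasc)

spec <- phantom_preset("polymer_US_2D", seed = 7)
cohort <- generate_cohort(spec, n_fields = 20, base_seed = 7)

cfg <- pipeline_config()
tab <- run_cohort(cohort$fields, cfg, condition = "sonopermeated")
colMeans(tab[grep("^pct_", names(tab))])

ctrl <- generate_cohort(phantom_preset("polymer_ctrl_2D", seed = 11), 20,
                        base_seed = 11)
tab_ctrl <- run_cohort(ctrl$fields, cfg, condition = "control")
compare_cohorts(tab, tab_ctrl)

plot_cohort_profiles(dplyr::bind_rows(tab, tab_ctrl))
```
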