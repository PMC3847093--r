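---
title: "Quantifying membrane-bound amyloid-beta oligomers at the single-molecule level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-bound amyloid-beta oligomers at the single-molecule level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Amyloid-beta peptides (Abeta40 and Abeta42) bind neuronal membranes at
picomolar-to-nanomolar concentrations and assemble into small oligomers —
dimers, trimers, up to roughly decamers — whose size and peptide composition
are thought to govern their toxicity. At these concentrations each
diffraction-limited fluorescent spot on a neurite is a single oligomer, and
three quantities characterize it:

1. **Size** — how many labelled monomers the spot contains, obtained by
   dividing its integrated fluorescence intensity by the intensity of one
   monomer.
2. **Composition** — whether it contains Abeta40 (donor label, HiLyteFluor
   555), Abeta42 (acceptor label, HiLyteFluor 647), or both, decided by a
   three-channel FRET experiment.
3. **Identity** — whether it is a labelled peptide at all, decided by its
   fluorescence lifetime (cellular autofluorescence lives at a longer
   lifetime than the membrane-bound dye).

`smoligo` implements this entire chain as testable code, and pairs it with a
synthetic-field generator that produces images with exactly the statistical
structure the analysis assumes, plus complete ground truth. Every stage of
the pipeline can therefore be verified quantitatively without access to
microscopy data.

## The optical model

### Channels

Three acquisitions are modelled per field:

* **DD** — donor excitation (532 nm), donor emission band;
* **DA** — donor excitation, acceptor emission band (the FRET channel);
* **AA** — acceptor excitation (635 nm), acceptor emission band.

A homogeneous Abeta40 oligomer appears in DD only; homogeneous Abeta42 in AA
only; a heterogeneous (mixed) oligomer appears in DD and AA *and* produces
sensitized acceptor emission in DA because the two dyes sit within a few
nanometres of each other. Colocalized oligomers that do not FRET appear in
DD and AA without significant DA signal.

### Per-spot photon budgets

With `P40` the expected detected DD photons per unquenched Abeta40 monomer,
`q40 = tau_bound/tau_free` the membrane quench factor, and `E` the FRET
efficiency inside a mixed oligomer:

* DD: `n40 * P40 * q40 * (1 - E)`
* DA (sensitized): `n40 * P40 * q40 * E * (phi_A eta_A)/(phi_D eta_D)`
* AA: `n42 * P42 * q42`

where `phi` are quantum yields and `eta` detection efficiencies. The quench
factor multiplies both donor pathways: dynamic quenching is modelled as a
proportional reduction of the donor's effective emission yield. The DA
channel can additionally carry configurable donor bleed-through
(`alpha_bleed * I_DD`) and direct acceptor excitation
(`delta_direct * I_AA`); both default to zero and are estimated from
single-label control fields by `estimate_crosstalk()` when non-zero.

Spots are rendered as pixel-integrated isotropic Gaussians (error-function
differences per pixel, so the rendered mass equals the budget to machine
precision), background is added uniformly, and Poisson shot noise is applied
per pixel. With `noise = FALSE` the expected image is returned, which is how
the photon-conservation tests operate.

### Quenching correction

Binding to the membrane dynamically quenches both dyes. For dynamic
quenching the intensity ratio equals the lifetime ratio,
`I_q / I_0 = tau_q / tau_0`, so the solution-calibrated intensity per
molecule is scaled by the bound/free lifetime ratio before sizing:
0.48/0.75 = 0.64 for Abeta40-HL555 and 1.24/1.56 ≈ 0.795 for Abeta42-HL647.

### FRET-corrected donor sizing

Inside a mixed oligomer the donor loses the fraction `E` of its excitations
to the acceptor, so DD intensity alone underestimates the Abeta40 content.
`corrected_donor_counts()` recovers the total donor excitation events by
collecting both emission paths and undoing their yields:

    D_tot = I_DD / (phi_D eta_D) + F_sens / (phi_A eta_A)

The Abeta42 content is always sized from AA (direct 635 nm excitation),
which FRET does not affect. Without the correction, donor sizes in mixed
oligomers are underestimated by exactly the factor `1 - E` (a property the
test suite asserts).

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixel_nm` | 125 | nm/px | a 12-px ROI spans ~1.5 um |
| `psf_sigma_nm` | 110 | nm | diffraction limit for 532 nm at NA ~1.2 |
| `roi_px` | 12 | px | integration box of the sizing protocol |
| `max_dist_nm` | 500 | nm | membrane-bound definition: spot maxima on or within 500 nm of a neurite |
| `coloc_radius_nm` | 250 | nm | colocalization at the diffraction limit |
| `k_sigma` | 3 | – | detection and channel-presence significance |
| `quench_factor_40/42` | 0.64 / 0.795 | – | bound/free lifetime ratios |
| `fret_efficiency` | 0.5 | – | donor–acceptor spacing ≈ R0 (5.3 nm) |
| `lifetimes_ns` | 0.48/0.75, 1.24/1.56, 0.58 | ns | bound/free dye and autofluorescence lifetimes |
| `cutoff_ns` | 0.53 | ns | midpoint of the 0.48/0.58 lifetime peaks |
| `photons_per_monomer` | 1000 | counts | free photon-budget scale (acquisition power/time is setup-specific) |
| `background_rate` | 5 | photons/px | sparse-field confocal background |

Quantum yields and detection efficiencies of the two dyes in this setup are
not published; they are free configuration values (defaults 0.25/0.35 donor,
0.30/0.35 acceptor) and only their ratio enters the FRET correction. The
confocal calibration volume defaults to 1 fL; solution calibration series
are simulated at tens of nM so that tens of molecules occupy the volume
(at the sub-nM cell-incubation concentrations the volume averages less than
one molecule, which cannot anchor a slope).

## Study conditions encoded in the generator

`study_config("10min")` and `study_config("48h")` encode the two incubation
timepoints of the mixed 1:1 Abeta40:Abeta42 experiment. Class weights are
derived from the reported species percentages — at 10 min, 35% of
Abeta40-containing spots and 25% of Abeta42-containing spots are
heterogeneous and under 10% of either peptide colocalizes without FRET; by
48 h the heterogeneous share of Abeta40 reaches 45% with the total number of
Abeta40 spots unchanged and Abeta42 spots increased. This fixes the relative
weights hom40:hom42:hetero:coloc at 29.5:49.5:17.5:3 (10 min) and
24.5:64.5:22.5:3 (48 h), scaled to ~100 spots on a ~350 um neurite per
64 x 64 um field.

Composition tables are pinned at a few anchor values with the remaining
mass interpolated once: homogeneous species are mainly
dimeric (monomer–tetramer, mode at dimer); heterogeneous oligomers at 10 min
have ~5% dimers, a trimer/tetramer mode, and ~20% heptamer-or-larger
(supported sizes 2–10); the 48-h table shifts
modestly larger and more Abeta42-rich (the non-obligatory monomers of a
mixed `s`-mer are Abeta40 with probability 0.55 at 10 min, 0.40 at 48 h, so
the per-oligomer Abeta42/Abeta40 ratio crosses 1 between the timepoints).
Autofluorescent impostors (2.9 per 100 um, lifetime 0.58 ns, ~2000 DD
photons) are scattered uniformly over the field.

## Numerical and design choices

* **Spot detection** thresholds the Gaussian-smoothed image at the raw
  background median plus `k_sigma` raw MADs. The background scale is
  estimated on the *unsmoothed* image: thresholding at the smoothed noise
  scale would admit hundreds of false maxima per megapixel.
* **Background boxes**: the first of right/left/up/down that fits inside the
  image and contains no other detected spot; if all four are occupied the
  first in-image box is used. Spots whose ROI or all candidate boxes leave
  the image are edge-flagged and excluded.
* **Crowded ROIs**: when another detection sits close enough that the 12-px
  ROIs share photons, the spot's integrated size is inflated by its
  neighbour. Such spots are flagged (`crowded_flag`), classify normally, and
  are excluded from size statistics — the usual overlapping-ROI rejection of
  single-molecule intensity analysis. Size-structure experiments are run on
  dedicated sparser fields (~28 oligomers per field) where the flag rarely
  fires.
* **Crowding check**: the generator warns (or errors, on request) when the
  realized mean nearest-neighbour distance falls below twice the ROI width.
  At the study densities (~100 spots per field) this conservative rule
  always fires, so the multi-field driver proceeds silently by design; the
  warning is aimed at users pushing densities far beyond the study's.
* **Lifetime fitting** is maximum likelihood on binned counts (multinomial
  over truncated-exponential bin probabilities), which stays unbiased at low
  photon counts where least squares on log-counts fails; the standard error
  comes from the observed information. Decays under 50 photons are flagged
  unconverged and the spot is dropped. The instrument response function is
  not modelled: lifetimes (≥ 0.48 ns) are an order of magnitude above the
  50 ps bin width.
* **The FLIM gate** applies to donor-channel (532 nm) detections only, where
  autofluorescence competes with the 0.48-ns dye; bound Abeta42 (1.24 ns)
  is detected by direct 635 nm excitation and is not subject to the 0.53-ns
  cutoff. Heterogeneous spots pass the gate trivially: FRET *shortens* the
  donor lifetime (simulated as `tau_bound * (1 - E)`).
* **Channel presence** for classification requires a detection in that
  channel within the 250 nm colocalization radius *and* an ROI intensity
  above `k_sigma` background standard deviations. Intensity alone would
  declare colocalization at the 1.5-um ROI scale.
* **Rounding** of real monomer counts is to the nearest integer with halves
  away from zero; a heterogeneous size is the sum of the two rounded
  components, and records where both components round to zero are dropped.
* **Mann–Whitney** comparisons use full enumeration of label rearrangements
  (handles ties exactly) for up to 8 observations per group, and the
  tie-corrected normal approximation above that.
* **Skeleton length** walks the thinned mask end-to-end and measures the
  smoothed pixel path, avoiding the staircase inflation of raw pixel
  counting; branched or crossing skeletons fall back to unique-adjacency
  counting. Self-crossing neurite masks merge pixels, so the skeleton length
  of a heavily folded neurite can undershoot the generative arc length.
* **Per-peptide normalization** of species fractions counts a
  colocalized-no-FRET spot in both peptides' denominators (it contains
  both peptides).
* **Large-oligomer peptide share**: the monomer-weighted share of peptide in
  oligomers larger than tetramers is computed within the mixed
  (heterogeneous) species. Under the study composition the heterogeneous
  class is ~17% of spots while homogeneous species stay at or below
  tetramers, so an all-spot share can never exceed ~25%; the share within
  the newly formed mixed species is the quantity that exceeds one half.
* **Timepoints** are independent generator parameter sets; no kinetic model
  links them.

## What the generator does and does not emulate

Emulated: sparse diffraction-limited spots on and off a curvilinear neurite
band (smoothed random-walk polyline dilated to 1.5 um); four ground-truth
species classes with configurable composition; per-monomer photon budgets;
membrane quenching; a single scalar intra-oligomer FRET efficiency;
Poisson shot noise; autofluorescent impostors with a longer lifetime;
mono-exponential TCSPC decays truncated to the acquisition window.

Not emulated: diffusion and photobleaching, 3-D optics and defocus,
detector afterpulsing, instrument response convolution, geometry-resolved
FRET inside an oligomer, real neurite morphology (branching, varicosities),
spatially varying background, or chromatic misregistration between
channels. Passing the recovery tests therefore demonstrates that the
analysis is correct *under its own assumptions*; on real data, PSF
mismatch, background structure and registration errors would add systematic
components that the synthetic fields cannot expose.

## Problem sizes

The packaged experiments use 64 x 64 um fields (512 x 512 px) with ~100
spots on a ~350 um neurite, ten fields per condition for species censuses,
and ~500 oligomers on sparser dedicated fields for size-structure recovery;
unit tests run reduced 32 x 32 um fields. These sizes put binomial
uncertainties on recovered percentages at 2–4 points, comfortably inside
the recovery tolerances, while a full census-plus-sizing run completes in
about a minute.

## Known limitations

* The quenching correction assumes purely dynamic quenching; static
  quenching would break the lifetime–intensity proportionality.
* Calibration slopes are per channel and assumed transferable from solution
  to membrane after the quench correction; detector nonlinearity and
  saturation are out of scope (the slope fit refuses non-monotone series).
* Sub-pixel localization is not performed; positions are pixel-resolution,
  adequate for 250 nm matching but not for distance-resolved FRET.
* The exact photon-accounting constants of the original detection setup are
  unpublished; sizes are exact in simulation but on real data depend on the
  user's own calibration of `phi`, `eta` and intensity per molecule.

## A minimal session

```{r example}
library(smoligo)
library(dplyr)

cfg <- study_config("10min")
experiment <- run_experiment(cfg, n_fields = 4, seed = 1)

# species census, per peptide
experiment_fractions(experiment)

# heterogeneous size distribution (uncrowded spots only)
experiment$spots |>
  filter(class == "hetero", !crowded_flag) |>
  size_distribution(class_filter = "hetero") |>
  plot_size_distribution()

# stoichiometry of mixed oligomers
experiment$spots |>
  ratio_42_40() |>
  summarise(median_ratio = median(ratio_42_40))
```
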