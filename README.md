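# smoligo

Single-molecule quantification of membrane-bound amyloid-beta (Abeta)
oligomers from three-channel confocal data: intensity-based oligomer sizing
with lifetime-derived quenching correction, FLIM autofluorescence gating,
FRET classification of Abeta40/Abeta42 species, and the downstream size,
stoichiometry and density statistics. A synthetic-field generator with full
ground truth makes every stage of the pipeline verifiable without microscopy
data.

The package is for quantitative microscopists and amyloid biologists who
want a tested, reusable implementation of the single-molecule
oligomer-counting protocol — and for methodologists who want to probe where
that protocol breaks (crowding, autofluorescence, FRET losses) under
controlled synthetic conditions.

## The measurement model

At nM peptide concentrations each diffraction-limited spot on a neurite is
one oligomer. Three acquisitions are made per field: DD (532 nm excitation,
donor emission), DA (532 nm excitation, acceptor emission — the FRET
channel) and AA (635 nm excitation, acceptor emission). The pipeline:

1. **Detect** spots per channel (local maxima of the smoothed image above
   median + 3 MAD of the raw background), merge DD/AA detections within the
   250 nm colocalization radius into single particle records.
2. **Integrate** each spot in a 12 x 12 px (~1.5 um) ROI and subtract an
   equal-sized adjacent background box that contains no other spot.
3. **Gate** to membrane-bound spots (maxima on or within 500 nm of the
   neurite mask, by distance transform) and, for donor-channel spots, fit a
   single-exponential lifetime to the TCSPC decay (maximum likelihood on
   binned counts) and reject autofluorescence:

       cutoff = (tau_label + tau_autofluor) / 2 = (0.48 + 0.58)/2 = 0.53 ns

4. **Classify** each spot as homogeneous Abeta40 (DD only), homogeneous
   Abeta42 (AA only), heterogeneous (DD + AA with significant sensitized DA
   emission) or colocalized-without-FRET.
5. **Size** each species in monomer units. Intensity per molecule comes
   from a solution calibration slope, corrected for membrane quenching by
   the lifetime ratio (dynamic quenching):

       I_q / I_0 = tau_q / tau_0        (0.48/0.75 = 0.64 for Abeta40-HL555,
                                         1.24/1.56 = 0.795 for Abeta42-HL647)

   For heterogeneous oligomers the donor's FRET loss is undone by photon
   accounting over both emission paths,
   `D_tot = I_DD/(phi_D eta_D) + F_sens/(phi_A eta_A)`, while Abeta42 is
   always sized from direct 635 nm excitation. Real sizes are rounded to
   the nearest integer (halves away from zero) and summed per oligomer.
6. **Summarize**: per-peptide species fractions, oligomers per 100 um of
   neurite (skeleton length of the mask), normalized size distributions
   with an open "7+" bin, per-oligomer Abeta42/Abeta40 ratios, and exact
   Mann-Whitney U comparisons between size distributions.

FRET efficiency follows the Forster relation `E = 1/(1 + (r/R0)^6)` with
R0 = 5.3 nm for the HiLyteFluor 555/647 pair.

## Worked example

Simulate the 10-minute mixed-incubation study conditions (ten 64 x 64 um
fields, ~100 spots each on a ~350 um neurite) and run the full pipeline:

```r
library(smoligo)
library(dplyr)

cfg <- study_config("10min")
experiment <- run_experiment(cfg, n_fields = 10, seed = 1)
experiment
#> <smol_experiment> 10 fields, 971 classified spots
#> # A tibble: 4 × 2
#>   class            n
#>   <chr>        <int>
#> 1 coloc_noFRET    31
#> 2 hetero         161
#> 3 hom40          293
#> 4 hom42          486

experiment_fractions(experiment)
#> # A tibble: 6 × 6
#>   peptide class        n_fields mean_fraction sd_fraction n_spots
#>   <chr>   <chr>           <int>         <dbl>       <dbl>   <int>
#> 1 ab40    coloc_noFRET       10        0.0635      0.0342      31
#> 2 ab40    hetero             10        0.334       0.0731     161
#> 3 ab40    hom40              10        0.603       0.0445     293
#> 4 ab42    coloc_noFRET       10        0.0460      0.0275      31
#> 5 ab42    hetero             10        0.238       0.0521     161
#> 6 ab42    hom42              10        0.716       0.0396     486
```

A third of Abeta40-containing spots and a quarter of Abeta42-containing
spots are heterogeneous FRET pairs (the generator's configured truth is
35% and 25%), and colocalization without FRET stays below 10% for both
peptides. Sizes and stoichiometry of the mixed species:

```r
het <- filter(experiment$spots, class == "hetero", !crowded_flag)
size_distribution(het)
#> # A tibble: 7 × 3
#>   bin       n fraction
#>   <fct> <int>    <dbl>
#> 1 1         0   0
#> 2 2         2   0.0225
#> 3 3        18   0.202
#> 4 4        20   0.225
#> 5 5        15   0.169
#> 6 6        12   0.135
#> 7 7+       22   0.247

experiment$spots |> ratio_42_40() |> summarise(median_ratio = median(ratio_42_40))
#> # A tibble: 1 × 1
#>   median_ratio
#>          <dbl>
#> 1            1
```

Mixed oligomers peak at trimers/tetramers with a heavy heptamer-plus tail,
unlike the mainly dimeric homogeneous species — the size distributions
differ at any significance level:

```r
compare_distributions(
  filter(experiment$spots, class == "hom40", !crowded_flag)$total_size,
  het$total_size)
#> Mann-Whitney U = 1057 , two-sided p = 2.77e-29 ( normal approximation with tie correction )
```

`autoplot()` methods cover fields and decay histograms;
`plot_species_fractions()` and `plot_size_distribution()` render the
census summaries.

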