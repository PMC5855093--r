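# axonquant

Quantification pipeline for studies of topographic axon sorting in the
optic tract and the growth-cone biology behind it.

Retinal ganglion cell (RGC) axons sort by their retinal origin *before*
reaching their target: dorsal and ventral axons segregate into the two
brachia of the optic tract. Probing how that happens means quantifying very
different kinds of microscopy data — dual-dye tract images, single-particle
RNP-granule tracks, growth-cone time-lapse masks, encounter movies, puncta
and PLA dot maps. axonquant implements all of those measurements as tested,
scriptable R functions, plus seeded synthetic-data generators with ground
truth so every stage can be validated end to end without raw imaging data.

## What it computes

| Measurement | Functions | Core definition |
|---|---|---|
| Missorting index | `extract_profile`, `split_branches`, `missorting_index`, `projection_area` | mean dorsal-dye intensity across the two brachia along a reference line 70 um from the chiasm; `MI = Dm / (Dm + Ds)` |
| Granule transport | `classify_motion`, `motion_fractions`, `anterograde_flux`, `domain_distribution` | anterograde/retrograde if displaced **more than 2 um** in one direction from the origin, else static/oscillatory; flux = boundary crossings per 30-s bin in the 50-um segment before the growth cone, normalized per axon |
| Filopodia | `detect_filopodia`, `classify_dynamics`, `partition_domains`, `roi_intensity`, `tip_accumulation` | protrusion **>= 2 um** from the growth-cone periphery; formation / retraction / stable over a 5-min recording sampled every 5 s; lifetimes and active-phase speeds |
| Encounters | `classify_behavior`, `behavior_fractions`, `contact_stats`, `compare_groups` | fasciculation / crossing / tracking / stalling / retraction from trajectory geometry after contact, 30-s frames, 45-min window |
| Colocalization | `manders`, `puncta_association`, `pla_counts` | Manders `M1`/`M2` on thresholded masks; fraction of puncta within an association radius; PLA dots per growth-cone domain |
| Synthetic data | `make_tract_image`, `make_track_fixture`, `make_domain_timecourse`, `make_gc_mask`, `make_gc_sequence`, `make_encounter`, `make_puncta_fixture` | seeded generators emitting inputs plus machine-readable ground truth |
| Recipes | `run_config`, `run_recipe` | end-to-end figure-style tables with a provenance manifest |

The measurement models, all tunable parameters with their defaults, and the
limits of what the synthetic data demonstrate are documented in
`vignettes/axonquant-methods.Rmd`.

## Worked example

Classify a fixture of 53 RNP-granule tracks (61 samples at 1 Hz) with the
2-um displacement rule and tabulate motion-class fractions:

```r
library(axonquant)

fx <- make_track_fixture("fig6b", seed = 7)
motion_fractions(fx$tracks, threshold = 2.0)
#>                class  n percent percent_raw
#> 1        anterograde 11   20.75    20.75472
#> 2         retrograde 13   24.53    24.52830
#> 3 static_oscillatory 29   54.72    54.71698
```

Just over half of the granules are static/oscillatory (54.72%), the rest
move retrogradely (24.53%) or anterogradely (20.75%). The fixture's
29/13/11 composition is the integer reconstruction of those published
fractions, and the generator keeps every track at least 0.5 um away from
the 2-um decision boundary, so the classification recovers the ground-truth
labels exactly.

Measure missorting on a synthetic two-brachium tract image with 30% of the
dorsal-dye mass in the wrong brachium:

```r
tr <- make_tract_image(missorted_fraction = 0.3)
prof <- extract_profile(tr$image, tr$line)
sp <- split_branches(prof, manual_split = 50)
missorting_index(prof, sp)
#> missorting index: MI = 0.3032 (mean Dm = 6.077, mean Ds = 13.967)
```

The recovered index matches the programmed fraction to within 0.01 (band
tails across the split account for the remainder). On noisy images the
automatic split finds the valley between the brachia itself
(`split_branches(prof)`), and a positive noise floor inflates MI toward 0.5
unless it is removed with the `background` argument.

Classify a 23-event encounter fixture:

```r
enc <- make_encounter("fig2c", seed = 0)
behavior_fractions(enc$events)$summary[1:3, c("class", "n", "percent")]
#>           class  n percent
#> 1 fasciculation 11   47.83
#> 2      crossing  7   30.43
#> 3      tracking  5   21.74
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/axonquant.R` (recipes, MI from TIFF + ROI JSON, track tables).

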