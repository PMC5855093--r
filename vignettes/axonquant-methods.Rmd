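---
title: "Measurement models and design choices in axonquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and design choices in axonquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonquant)
```

axonquant quantifies how retinal ganglion cell (RGC) axons sort
topographically in the optic tract and the growth-cone cell biology behind
it: dual-dye tract images, RNP-granule transport, filopodia dynamics,
growth-cone/axon encounter behavior, and colocalization. This vignette
explains each measurement model, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators emulate (and
what they deliberately do not), and the numerical choices that make the
pipeline deterministic.

## Missorting index

Dorsal and ventral retina are labeled with different lipophilic dyes, so
after the tract splits into its two brachia the dorsal-dye channel should be
confined to the ventral brachium. A reference line is drawn across the full
tract width, conventionally 70 um from the chiasm, and the mean dorsal-dye
intensity is measured on each side of the brachium split. With `Dm` the mean
in the wrong (dorsal) brachium and `Ds` the mean in the correct one, the
missorting index is

$$MI = \frac{Dm}{Dm + Ds} \in [0, 1].$$

The index assumes mean fluorescence is proportional to the amount of labeled
axons; no correction for dye-loading variability is applied, because none is
defined for this preparation. `MI` is a ratio of means, so it is invariant
under any positive rescaling of the dorsal channel.

Numerical choices:

* **Sampling.** `extract_profile()` rasterizes the line at 0.5-pixel steps
  and interpolates bilinearly — standard, and checkable against a
  nearest-pixel oracle (the two agree to better than 1% of the channel
  maximum once the image is sampled finely relative to the band width).
* **Split.** The original measurement assigns brachia by eye. The faithful
  mode is a user-supplied `manual_split`. The automatic mode sums the two
  channels, smooths with a 2-um running mean, takes the global maximum plus
  the largest second peak separated from it by a prominent valley (the
  running minimum between them must drop below half the smaller peak), and
  places the split at the *center of the near-minimum plateau* (within 25%
  of the valley depth) between them. The plateau center rather than the
  argmin matters: between well-separated brachia the valley floor is flat
  and noise makes the argmin an arbitrary point of it, while the plateau
  center is stable to about one smoothing window. Whether the ventral
  channel should participate in locating the split is not specified
  anywhere; the automatic mode uses both channels, and this is flagged as a
  package choice. With a single detectable band (e.g. no missorting at all)
  the automatic mode refuses and asks for `manual_split` instead of
  guessing.
* **Background.** Background subtraction is off by default: background
  correction is part of the cell-culture ROI protocol, not the tract-image
  protocol. An optional scalar background is accepted and clipped at zero.
* `projection_area()` is a plain threshold mask area: pixels at or above
  threshold times pixel area.

The tract generator (`make_tract_image()`) builds the two brachia as
Gaussian bands (default centers 30 and 70 um, sd 4 um, peak 100) and splits
the dorsal channel's mass between them in proportion to the programmed
`missorted_fraction`, so on a noiseless image the recovered MI equals the
programmed fraction by conservation of mass (to within 0.01 over the whole
range; band tails across the midpoint contribute less than 1e-6 at these
defaults). It does not emulate tract curvature, depth attenuation, or
dye-loading differences — MI recovery on it validates the measurement
arithmetic, not robustness to those real-world effects.

## Granule motion classification and flux

Granules co-labeled in axon shafts are tracked for 1 min and classified by
the unidirectional-displacement rule: a granule is anterograde or retrograde
if it displaces **more than 2 um in one direction from its origin**, else
static/oscillatory. The rule names excursion from the starting point, so the
implementation uses the maximal excursion $d^+ = \max_t (x_t - x_0)$ and
$d^- = \max_t (x_0 - x_t)$, not the endpoint displacement; the inequality is
strict (an excursion of exactly 2 um stays static). If both excursions
exceed the threshold the larger wins, and an exact tie goes to anterograde —
a deterministic tie-break that in practice never fires on real kinematics.
Tracks shorter than the 1-min window are classified on the window they
cover (the source protocol does not say how such granules were handled;
requiring at least two samples and classifying what is there is this
package's documented choice).

`anterograde_flux()` counts, per 30-s bin, distinct granules that are
anterograde within the 50-um shaft segment proximal to the growth cone and
whose position crosses the growth-cone boundary (coordinate 0) in that bin,
then normalizes each axon's series by its own mean — so "constant
transport" reads as a flat series at 1 and the mean of a defined normalized
series is exactly 1. `domain_distribution()` converts per-30-s
central/peripheral counts (T = 0 at contact) into per-bin fractions; empty
bins are flagged `NA`, never imputed.

The track generator uses three kinematic archetypes: drift at 0.05 um/s
with 0.05-um positional noise (3 um displacement over the 61-sample, 1-Hz
window) and a reflected random walk (step sd 0.2 um) hard-clipped to 1.5 um
excursion. Every track therefore keeps at least 0.5 um of margin from the
2-um boundary, which makes the ground-truth labels recoverable exactly for
*any* seed — the fixture compositions, not the noise draws, carry the
statistics. The `fig6b` fixture's 29/13/11 composition of 53 tracks is the
minimal integer reconstruction of the published percentages
(54.72/24.53/20.75); it is labeled a reconstruction, not data. What the
generator does not emulate: granules pausing mid-window, photobleaching,
detection dropouts, or 2-D-to-1-D projection error (tracks arrive as 1-D
arc-length coordinates by contract).

The domain-count generator apportions an exact pooled composition (118
peripheral of 500 granules at the baseline occupancy 0.236) over bins by
largest remainder, with the seed breaking only apportionment ties. Pooled
fixture statistics are thus exact by construction — a deliberate deviation
from independent per-bin sampling, chosen because the pooled baseline
fraction is the published quantity the fixture exists to reproduce.
Contact profiles step the programmed occupancy to a sustained 0.45 plateau
from 3.5 min (heterotypic) or a transient 0.37 peak returning to baseline
by 8 min (homotypic), mirroring the reported kinetics qualitatively.

## Filopodia detection and dynamics

A filopodium is a protrusion from the growth-cone periphery **at least 2 um
long** (inclusive). On a binary mask, `detect_filopodia()` removes thin
protrusions by a morphological opening (disc radius 0.6 um by default —
above half the typical filopodium width, well below the body size), takes
connected components of mask minus opening, and measures each protrusion
from the body:

* the **tip** is located by geodesic propagation within the protrusion
  (16-neighborhood chamfer, within ~3% of Euclidean arc length at any
  orientation), which follows curved protrusions;
* the **reported length** is the Euclidean distance-transform value at that
  tip, i.e. the distance from the tip to the nearest body pixel. For
  straight protrusions this equals the geodesic base-to-tip length and the
  half-pixel center offsets at base and tip cancel, making axis-aligned
  geometry exact to the pixel; for strongly curved protrusions it is a
  lower bound, which should be kept in mind if masks of looping filopodia
  are analyzed.

Rasterization limits length accuracy to about one pixel (0.1 um at the
default resolution) at arbitrary orientations, so the generator-based count
tests keep programmed lengths at least 0.4 um away from the 2-um threshold;
threshold-boundary behavior (1.9 um excluded, 2.0 um included) is exercised
on grid-exact rectangular geometry instead. Raising the threshold can only
shrink the detected set (count monotonicity).

Dynamics over a 5-min recording sampled every 5 s: *formation* if the first
frame at or above 2 um comes after frame 0, *retraction* if the length
drops below 2 um and never recovers within the recording ("completely
retracted" is interpreted via the same 2-um rule that defines the
lifetime), *stable* if present in every frame; one trace may count as both
formation and retraction. Lifetime is the total time at or above 2 um.
Speeds use only active phases: the mean per-interval rate over the maximal
monotone run ending at the maximum (elongation) or at the first sub-2-um
frame (retraction); plateaus break runs and never contribute. A filopodium
that fully retracts and later re-extends is two traces if tracked as such —
whether the original protocol counted it once or twice is unknowable from
the text, so the package counts what the caller tracked. The schedule
generator quantizes programmed speeds so ramps span whole frames; recovered
active-phase speeds then match the schedule exactly, which tests the
estimator, not sub-frame interpolation (which the 5-s protocol cannot
resolve anyway).

Tip accumulation: the tip ROI is the distal 1 um of the protrusion
(geodesic coordinate), and a filopodium is called enriched when mean marker
intensity there is at least 1.5 times the mean over the rest of the
protrusion. Both numbers are operational stand-ins for by-eye scoring —
they are exposed as configuration (`enrichment_factor`, `tip_um`) and
echoed in the output attributes rather than buried.

Domain partition: manually traced central-domain polygons always take
precedence. The automatic mode (outline eroded by 3 um) is a stand-in for
manual tracing, implemented by rasterizing the polygon at 0.05 um/px,
eroding with a disc, and tracing the contour back to a polygon; there is no
installed polygon-offsetting library, and the raster route is accurate to
about 5% on smooth outlines at this resolution. The peripheral domain is
defined as outline minus central, so its area is the exact area difference
by construction.

ROI intensities are background-corrected by subtracting the mean of a
congruent ROI placed in an adjacent signal-free area; negative corrected
means are reported, never clipped, and overlap between the region and its
background ROI is an error. Pixel size always comes from the caller or file
metadata — the package never assumes 1 px = 1 um.

## Encounter behavior classification

Growth-cone/axon encounters, imaged every 30 s and terminated at the end of
a behavior or after 45 min, fall into five classes. The published
definitions are observational (merging, crossing over, filopodia-guided
following, arrest, withdrawal); making them computable requires explicit
geometry, and all tolerances below are this package's operational choices,
exposed in `encounter_params()`:

1. **fasciculation** — the post-contact trajectory lies within `merge_tol`
   (1 um) of the target axon for at least `min_follow` (10 um) of traveled
   arc;
2. **crossing** — the trajectory crosses the target path and proceeds at
   least `cross_dist` (5 um) beyond it with heading change under 30
   degrees;
3. **tracking** — at least 2 filopodial contacts and a turn of more than 20
   degrees toward the target's tangent while the centroid stays farther
   than `merge_tol` from it;
4. **retraction** — net displacement along the pre-contact heading below
   -5 um;
5. **stalling** — net advance within ±5 um over the full 45-min window.

The cascade order resolves overlaps deterministically (a merged trajectory
also "follows", so fasciculation is tested first). Events matching nothing
are reported as unclassified; events whose observation ended before the
45-min window without triggering rules 1–4 are censored
(`indeterminate_censored`), never silently dropped. Summary tables pool
stalling and retraction into one class, as the corresponding figure panels
do, with the split retained in the detail table. All decisions use only
relative geometry (distances, heading relative to the path tangent), so
classification is invariant under rigid motion of the whole event — a
property the test suite checks directly.

The encounter generator builds one canonical trajectory per class (straight
target axon, contact at T = 0, 30-s frames, 45 min of post-contact
observation) under a seeded random rigid transform, each with a wide margin
from every decision threshold: round-trip accuracy is exactly 100% by
construction, for any seed. The `fig2c` (11/7/5 of 23) and `fig2i_homo`
(51/43/6 of 100) fixtures are integer reconstructions of published
compositions; the event counts behind the homotypic 0.51/0.43 ratios are
not printed anywhere, so n = 100 is the smallest round composition
reproducing both ratios — explicitly a reconstruction. Real encounters
curve, pause and re-contact; the generator does not emulate that, so
passing round-trips validate the decision geometry, not tracking of messy
trajectories.

Group comparisons (`compare_groups()`) delegate to R's `fisher.test`,
`chisq.test` and `wilcox.test`, two-sided, matching the tests named in the
original figure legends; when chi-square expected counts fall below 5 the
result carries a note recommending Fisher's exact test.

## Colocalization, puncta association, PLA

Manders coefficients are computed on thresholded masks:
$M_1 = \sum_{M_1 \wedge M_2} I_1 / \sum_{M_1} I_1$ and symmetrically
$M_2$; both lie in [0, 1] and are invariant to positive channel scaling.
When no masks are given they default to Otsu thresholds per channel; manual
thresholds are accepted. Costes-style automatic thresholding and
Pearson-based measures are out of scope.

Puncta association: a punctum of channel A is associated when its nearest
channel-B centroid lies within the association radius. The radius is not
defined by the original by-eye scoring; the default 0.5 um (a typical
diffraction-limited punctum radius) is surfaced in the configuration and in
every output. The fraction is monotone nondecreasing in the radius. The
fixture places 84 of 100 A-puncta within half the radius of a B-granule and
the rest at more than twice the radius, so the 84% fraction is exact and
seed-invariant. Whether the published 84% pooled across experiments or
averaged per experiment is unstated; the fixture pools.

PLA dots are assigned by point-in-polygon against the central-domain and
outline polygons; dots on the shared boundary go to the central domain (a
documented tie-break), dots outside both are counted and reported rather
than dropped, and the central/peripheral ratio is undefined (flagged) when
the peripheral count is zero. Dot conservation
(central + peripheral + outside = total) is tested against an independent
ray-casting implementation.

## Determinism, problem sizes, limitations

Every generator draws from a locally seeded RNG stream and restores the
caller's random state; identical configuration gives bit-identical output,
and recipe CSVs (`run_recipe()`) reproduce byte-identically under a fixed
seed, with the configuration hash stamped into each table header. Test and
fixture sizes — 53 and 1,000 tracks, 200 encounter round-trips, 50 mask
fixtures at 0.1 um/px, 500-dot point-in-polygon checks — were chosen so the
entire suite exercises every decision boundary while running in well under
five minutes on a single core.

Known limitations, restated in one place: intensity-based MI inherits the
signal-proportional-to-axons assumption; automatic brachium splitting needs
two detectable bands; filopodium length is exact only for straight
protrusions; encounter tolerances are operational definitions, not
published constants; the synthetic data validate measurement arithmetic and
decision geometry, not robustness to optical artifacts they do not model
(PSF blur beyond Gaussian bands, camera noise models, drift, segmentation
error).
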