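---
title: "Monitoring carbon-ion therapy with secondary-ion fragment distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring carbon-ion therapy with secondary-ion fragment distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring problem

Scanned carbon-ion therapy deposits its dose in a sharp Bragg peak, which
makes the delivered dose exquisitely sensitive to density changes along the
beam path: mucous filling a nasal cavity, tissue swelling, or tumor shrinkage
between treatment fractions can shift the peak by millimeters and underdose
the target. Nuclear fragmentation of the primary ions offers a way to watch
the delivery from outside: a fraction of the carbon ions undergo nuclear
interactions in the patient, and the charged fragments they emit are
energetic enough to leave the body. Tracking those fragments back to their
production points — the *fragmentation vertices* — builds a
three-dimensional *fragment distribution* for each fraction, and
inter-fractional changes in the patient appear as localized differences
between fragment distributions.

`fragmon` implements the full analysis chain for a compact two-layer pixel
tracker ("mini-tracker") placed downstream of and diagonally above the
patient, together with a phenomenological generator that produces synthetic
acquisitions with the statistical structure this analysis relies on. The
package answers two questions: *does the reconstruction chain recover
vertices at the expected few-millimeter resolution*, and *does the
voxel-difference test detect a realistic internal density change while
staying quiet when nothing changed*?

## The reconstruction chain

**Clustering.** A fragment crossing a 500 um silicon layer spreads its
charge over neighboring pixels. `cluster_hits()` merges pixel signals that
are adjacent (8-connected by default) and coincident within a configurable
time window (100 ns default) into clusters, with the field-standard
definitions: cluster time = earliest constituent time of arrival, cluster
energy = summed pixel energies, cluster position = energy-weighted mean of
the pixel positions. Times of arrival are quantized to the 1.5625 ns clock
of the readout chip.

**Coincidence matching.** A track requires one cluster in each layer within
|dt| <= 75 ns. Ambiguities are resolved greedily by smallest |dt|, with ties
broken by the earlier front timestamp and then the earlier back timestamp —
this makes the matching deterministic and order-independent. The greedy rule
is compared against an exhaustive-search oracle in the test suite (problem
sizes up to 5 + 5 clusters, 300 random instances); it attains the optimal
matching in well over 95% of instances, and never matches more pairs than
the optimum.

**Vertexing.** Each track is associated with the pencil beam being delivered
at its front-layer timestamp (delivery intervals are treated as closed;
tracks falling in inter-spot gaps are excluded and counted rather than
snapped to the nearest spot, because projecting onto the wrong beam line is
worse than losing a track). The reconstructed vertex is the midpoint of the
shortest connecting segment between the track line and the beam line through
the *nominal logged* spot position — deliberately not the true primary
trajectory, since a real monitoring system only knows the nominal beam. The
lateral beam spread (sigma = 2 mm) times the 30 degree viewing angle is what
dominates the 3-5 mm projection uncertainty along the beam axis; the
scattering blur and the 55 um pixel pitch contribute less.

**Accidental coincidences.** At realistic delivery intensities a fraction of
order 0.2% of matched pairs combine clusters of two different fragments that
arrived within the coincidence window. Their "tracks" are geometrically
meaningless and show up as miss distances of tens of millimeters, far outside
the physical miss-distance distribution. The pipeline ships a miss-distance
veto (`miss_cut`, off by default; 20 mm where used) and the resolution
figures quoted by the package apply it, because a handful of 100 mm outliers
would otherwise dominate a root-mean-square over tens of thousands of
correct vertices.

## The significance test and its calibration

Two fragment distributions are compared voxel by voxel on an
8 x 8 x 10 mm grid. A voxel with counts $N_1$, $N_2$ is flagged when

$$|N_2 - N_1| \ge k \sqrt{N_1 + N_2}, \qquad k = 2,$$

i.e. when the difference exceeds twice the combined Poisson counting
uncertainty (95.4% confidence). Only voxels with more than 100 counts in
*both* distributions enter the test; sparsely populated voxels are pure
counting noise. (Whether the eligibility threshold should look at one or
both distributions is genuinely ambiguous; both modes are implemented,
`"both"` is the default as the more conservative choice.)

No multiple-testing correction is applied. Instead the test is *calibrated*:
`expected_chance_exceedances()` estimates, per eligible voxel with plug-in
Poisson mean taken from the reference counts, the probability that two
independent Poisson replicates would pass the threshold by chance, and sums
these over voxels. For ~200 voxels with means above 100 this expectation is
about 9 voxels — so single-digit significant-voxel counts in a null
comparison indicate a healthy threshold rather than a detected change, and
the package's null tests assert exactly that consistency.

## The synthetic-data generator

No public data exist for this kind of acquisition (raw pixel streams,
delivery logs and phantom CTs are all institutional), so the generator is a
first-class, tested component. It is deliberately *phenomenological* — a
single effective fragment species with exponential attenuation and a net
Gaussian scattering kernel, not a transport Monte Carlo. What it reproduces
is the statistical structure the analysis sees:

| parameter | default | meaning |
|---|---|---|
| `theta0` | 0.35 rad | forward-peaking scale; emission density falls as exp(-theta/theta0) |
| `production_rate` | 0.068 /primary/mm/density | fragment yield scale (see below) |
| `primary_att_length` | 250 mm | exponential attenuation of primaries |
| `fragment_att_length` | 400 mm | water-equivalent attenuation of fragments |
| `spot_sigma` | 2 mm | lateral pencil-beam spread (per spot, via the log) |
| `mcs_sigma` | 8 mrad | net multiple-Coulomb-scattering blur per fragment |
| `range_alpha`, `range_p` | R(250 MeV/u) = 270 mm, p = 1.77 | power-law range-energy mapping |
| `edep_median`, `edep_sdlog` | 40 keV, 0.5 | lognormal per-layer energy deposit |

Vertex depths follow local density times the surviving primary fraction,
truncated at the water-equivalent range; the phantom is a 160 mm soft-tissue
slab with a 25 x 25 x 10 mm nasopharynx cavity (about 6 mL) just upstream of
the isocenter, air-filled in the reference configuration and filled with
soft-tissue-equivalent material (density 0.98, about -20 HU) when the
insert is present. Filling the cavity has three effects, all emergent from
the model rather than scripted: more production inside the cavity, absorption
of upstream-produced fragments whose exit path toward the tracker traverses
it, and an upstream shift of the end of range that removes production in the
final millimeters of the stopping layers.

The default plan is a scaled-down raster field — 5 energy layers linearly
spaced over 153-250 MeV/u, 40 spots per layer, 2000 primaries per spot,
7 repeated deliveries (emulating a seven-tracker system) — chosen so that a
full simulated acquisition plus reconstruction runs in seconds. Detecting
the few-percent absorption deficits of the cavity filling, however, requires
the counting statistics of a clinical acquisition: of order 10^4 counts per
populated voxel, i.e. about 2 x 10^6 detected fragments in a summed
reference run. `signature_primaries` (150 000 per spot) reaches that regime;
the `production_rate` default was set once so that this full-statistics
reference acquisition lands at ~2.2 x 10^6 detected fragments, and was not
revisited.

**Variance reduction (exact).** Fewer than one fragment in 300 heads
anywhere near the tracker, so the generator Poisson-thins the fragment
population into an "in-band" part — directions inside a conservative
(theta, phi) box around the tracker, computed per spot and per depth bin from
the layer corners with margins covering the lateral beam spread at 5 sigma
and the scattering blur at more than 5 sigma — and an out-of-band part that
is only counted. Because a fragment's direction is independent of its vertex
and the same band function enters both the thinning probability and the
conditional sampling, the detected-fragment distribution is *identical in
law* to a full simulation; the band's conservativeness only costs runtime,
never correctness (the sole approximation is the 5 sigma truncation of the
lateral margins, a < 1e-6 effect). The test suite cross-checks the chain end
to end against ground truth, which would expose any inconsistency between
the thinning and the sampling.

**What the generator does not emulate.** Fragment species and energy
spectra, nuclear cross-section physics, CT-based heterogeneity (the phantom
is piecewise-uniform), detector depletion physics and per-pixel calibration,
time-walk corrections, and beam-line transport. Consequently, passing tests
demonstrate that the *analysis chain* behaves correctly on data with the
assumed statistical structure — they do not validate that structure against
real tissue or a real Timepix3.

## Numerical choices

* Lines are treated as parallel when the cross product of their unit
  directions falls below 1e-9 — double-precision geometry at mm scale.
  For parallel lines the midpoint is undefined (the perpendicular distance
  is still reported); coincident lines return the shared origin.
* Voxel and depth-profile intervals are half-open, `[edge, edge + size)`;
  a vertex exactly on an interior edge belongs to the higher voxel.
* Beam-association intervals are closed on both ends; a timestamp exactly at
  a spot boundary belongs to that spot.
* Pixel grids are 509 x 254 (area / pitch, rounded down); the two readout
  chips of a layer share one sensor, so columns are continuous across the
  chip boundary and the chip id is provenance only.
* The 1.6 degree in-support tilt is applied as a rotation about the focus
  line; the tilt axis is not observable from a single tracker position, and
  the choice is configurable.
* The depth-production grid uses 0.5 mm bins with uniform jitter inside the
  bin — negligible against the 10 mm comparison voxels.
* Region-integrated depth-profile differences apportion partially covered
  5 mm bins by overlap fraction.
* Matching ties (equal |dt|) are broken by earlier front, then earlier back
  timestamp; cluster labels are canonicalized by time so results are
  independent of input order.

## Problem sizes used by the shipped checks

The packaged tests run the scaled default plan for resolution and null
checks (tens of thousands of vertices; twenty independent reference pairs
for the chance-consistency check) and three full-statistics acquisitions
(reference, insert, zero-contrast null at `signature_primaries`) for the
density-change signature. These sizes were chosen as the smallest at which
each scientific claim has statistical power: the projection uncertainty
needs only ~10^4 vertices, while the upstream absorption deficit is a ~3%
effect that demands ~10^4 counts per voxel, the same regime as a clinical
acquisition.

## Known limitations

* The greedy coincidence rule can mis-pair simultaneous fragments
  (accidentals); they are vetoed by miss distance rather than resolved
  globally.
* The chance calibration uses plug-in Poisson means from the observed
  reference counts; at eligibility-threshold counts (~100) this slightly
  misestimates the per-voxel exceedance probability, which is why observed
  null counts are compared within +-3 sqrt(expected) rather than exactly.
* With the cavity filled, the *increase* of production inside the insert
  remains visible in the difference maps at full statistics; the package's
  blur (3-4 mm RMS along the beam axis) suppresses it less than a clinical
  system with additional positioning uncertainties would.
* The solid-angle acceptance and all resolution figures assume the single
  default tracker position (30 degrees, 167 mm); other geometries are
  configurable but untested against any reference.
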