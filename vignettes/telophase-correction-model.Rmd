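---
title: "The two-step division-orientation model and its measurement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-step division-orientation model and its measurement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telocorrect)
```

## The measurement conventions

All division and spindle angles in this package are acute angles between an
undirected axis (daughter–daughter vector, metaphase spindle, or cleavage
plane normal) and a *local* basement-membrane (BM) direction, folded into
[0°, 90°] (`fold_angle()`). Folding happens at construction; no downstream
statistic ever sees a raw angle. The BM is supplied as a local direction
vector, not a curve: on wrinkled tissue the caller chooses the local
tangent, because no robust general rule exists for estimating it from a
curved section, and the measurement is defined locally anyway.

Orientation bins are half-open — planar [0°, 30°), oblique [30°, 60°),
perpendicular [60°, 90°] — so every angle belongs to exactly one bin and
boundary values resolve deterministically (30° is oblique, 60° is
perpendicular). The published descriptions of these bins use overlapping
interval labels; the half-open convention is ours.

Signed LGN radial angles live in [−90°, +90°] with apical (+y) positive.
The deviation between a division axis and the LGN direction treats the axis
as an undirected line, so it is again in [0°, 90°].

Per-division correction is Δ = θ − φ, with φ the angle at anaphase onset
and θ the angle one hour later. Published figure legends alternate between
θ−φ and φ−θ; we fix Δ = θ − φ (negative = rotation toward planar) and
document it rather than guessing a plotting sign. "Correction" is defined
as a *bin change* (oblique entry exiting in the planar or perpendicular
bin), not a magnitude cutoff, matching how individual divisions are
reported as class transitions.

## The two-step generative model

`simulate_cohort()` generates division records in two steps.

**Step 1 — anaphase entry.** φ is drawn either uniformly on [0°, 90°]
(wild type at peak stratification: entry orientation is random) or from a
bin mixture (planar/oblique/perpendicular proportions, uniform within the
bin) for genotypes with biased entry. Apical LGN recruitment is Bernoulli
with probability `p_lgn_apical` and forced for perpendicular entries, since
those require apical LGN.

**Step 2 — telophase correction.** Basal contact of the (more) apical
daughter at anaphase onset is assigned: always retained for planar entries,
lost for perpendicular entries, Bernoulli(`p_contact_retained`) for oblique
entries. Oblique entries then relax toward a target angle by exponential
decay,

\[ \mathrm{angle}(t) = \mathrm{target} + (\varphi - \mathrm{target})
   e^{-t/\tau}, \]

sampled every 5 minutes over 0–60 min with independent per-frame Gaussian
noise folded back into [0°, 90°] (no noise at t = 0, so the trajectory
starts exactly at φ). The target is the planar target when contact is
retained and planar correction is enabled, the perpendicular target when
contact is lost and perpendicular correction is enabled, a uniformly random
angle when the early-stratification `random_correction_on_contact_loss`
flag replaces perpendicular correction, and φ itself otherwise. Planar and
perpendicular entries always relax toward φ — they are stable up to noise,
since such divisions show minimal radial change after anaphase onset.
θ is the final trajectory value.

The exponential form is the package's choice: the observation it encodes is
only that reorientation completes "within the first ~30 minutes". With the
default τ = 10 min, more than 95% of any excursion is complete by 30 min
and the noiseless settling time for the largest possible oblique excursion
(50° at tolerance 5°) is 10·ln(10) ≈ 23 min. With the default frame noise
(σ = 1.5° per frame) a noisy trajectory can re-cross the 5° settling
tolerance after 30 min — both the compared frame and the final frame are
noisy — so the *measured* settled-by-30-min fraction is around 85%, not
100%; the test suite checks this fraction against an independent
closed-form-plus-noise oracle rather than asserting the noiseless ideal.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `tau_correction` | 10 | min | ≥95% of the excursion done by 30 min |
| `angle_noise_sigma` | 1.5 | °/frame | small jitter; keeps stable entries inside ±3σ of φ |
| `target_planar` / `target_perpendicular` | 10 / 80 | ° | well inside their bins |
| `p_contact_retained` (WT E16.5) | 0.6 | — | ~60% of oblique entries correct to planar |
| `p_lgn_apical` (WT E16.5) | 0.5 | — | apical LGN in about half of mitoses |
| sampling grid | 0–60 by 5 | min | live-imaging frame interval |

Genotype presets encode the study conditions: `WT_E14.5` uses 47% oblique
entry, 72% contact retention and random correction on contact loss (no
perpendicular correction early in stratification); `Gpsm2_KD` uses the
75/23/2 entry mixture with perpendicular correction disabled and contact
retention 1, because LGN-knockdown oblique entries correct to planar
essentially without exception; `AJ_mutant` disables both corrections;
`Afdn_KD` additionally loses basal contact during telophase in 73% of
contact-retaining obliques (recorded in `contact_end`; conditioning always
uses contact at onset); `Gpsm2_Afdn` removes perpendicular entries and both
corrections. LGN apicality and contact retention are drawn independently —
whether they are correlated in tissue is unknown, and this assumption is
flagged here deliberately.

`simulate_snapshot()` converts the longitudinal model into fixed-tissue
pools by drawing a mitotic stage with probability proportional to stage
duration (default 10/10/50 min, making metaphase and anaphase each about
one fifth as frequent as telophase), using entry angles for
metaphase/anaphase and simulated θ for telophase.

## Distribution statistics

Uniformity is tested against Uniform[0°, 90°] (not the circle): all angles
are folded into one quadrant before any analysis. KS p-values are exact for
n < 35 and asymptotic otherwise.

`classify_distribution()` operationalizes the qualitative shape
vocabulary: *random* when the uniformity test does not reject at α = 0.05;
otherwise *bimodal* when the oblique bin is below both outer bins **and**
each outer bin exceeds its uniform share (1/3); otherwise
*planar-shifted*. The second clause matters: a pool like 97/1/2 (typical of
simulated LGN knockdown at one hour) has a tiny oblique bin but is not
bimodal in any meaningful sense — without the outer-bin requirement it
would be mislabelled. The rule is pinned by tests on 45/10/45 (bimodal),
80/15/5 (planar-shifted) and uniform (random) mixtures; it is a documented
operationalization, not a published definition.

Mann–Whitney, Student's t and the paired Wilcoxon test are exposed as thin
pass-throughs to the standard routines; nothing about them is re-derived.

## Synthetic micrographs and the image metrics

Generators always emit their ground truth next to the pixels, and every
metric has a recovery test against it. What they emulate — and what they
do not — bounds what a green test suite says about real data:

* **Junction images** are single-plane, two-channel ridges with Gaussian
  cross-section, square-wave punctum modulation (period and duty cycle are
  the zipper ground truth), constant offset, and Gaussian read noise. No
  point-spread function, no 3D stacks, no deconvolution artifacts, no
  curved or branching junctions. Continuity recovery within ±10 points on
  these images does not certify performance on confocal data with
  structured background.
* **Radial profiles** are cortical linescans anchored at the BM contact
  with the apical surface as the central 50% of the path, exactly the
  assumption the radial-fraction metric makes; real cells violate the 50%
  assumption in proportion to their shape anisotropy.
* **Section images** have a sinusoidal BM, a differentiated band of
  constant normal thickness (its per-column vertical extent is scaled by
  the local slope factor so band area = thickness × arc length), and
  Poisson-placed nuclei. Real sections add wrinkling beyond a single
  harmonic, staining gradients, and segmentation error, none of which are
  modelled.

Numerical choices in the metrics: along-path and scan sampling use bilinear
interpolation at 1-px steps; scans are 21 px, centered by the anchor
channel's maximum, and shifted along the path to the nearest punctum when
they land in a zipper gap (below half the along-path maximum); 5% of the
path is trimmed at each end as a tricellular-vertex guard; the continuity
threshold is 0.5 × the mean of three orthogonal-scan center intensities
(at 1.0× even a perfect noisy ridge would hover near 50%); center
intensity is the geometric mean of the 3 samples nearest the center, with
a zero sample flagged as degenerate rather than propagating −∞; LGN
recruitment calls use a peak-window mean (window ≈ L/20) against median +
3×MAD, because the raw maximum of ~100 noise samples exceeds 3 robust SDs
too often to be a usable crescent detector. Pixel coordinates are 1-based
(R matrix convention, x = column, y = row increasing apically).

## Clonal analysis

Clone classification follows the published binning exactly (balanced at
ratio 1, SB-rich above, basal-rich below, delamination at zero basal cells
up to the SG3 layer, excluded above SG3), with one case the publication
leaves open: clones with basal cells but no suprabasal cells have ratio
0 < 1 and are binned basal-rich. Density arrays cap both axes at 12 with
an overflow bin and exclude delamination/excluded clones.

The clone simulator couples division outcomes to fate: planar (and
corrected-oblique) divisions are symmetric (two basal daughters);
perpendicular and uncorrected-oblique divisions are asymmetric (one basal,
one suprabasal); delamination moves a basal cell up without division.
Suprabasal cells never divide — at these ages they are treated as
post-mitotic differentiating progeny. Three generations is the default,
matching a ~72-hour trace. This is a composition model only: no clone
geometry, no merging, no spatial interactions.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to be
statistically decisive while remaining quick on a single CPU: cohorts of
10⁴ divisions for distribution signatures and parameter recovery (bin
fractions are then estimated to ±1%), 10⁵ draws for entry-distribution
checks, 1000 replicates of n = 100 for the KS type-I calibration, 20 seeds
per duty cycle for continuity recovery, and 4–5 × 10³ clones per point on
fate-parameter grids. Every stochastic component is driven by a single
integer seed with a fixed draw order, so cohorts, images and clone tables
are reproducible bit-for-bit.

## Known limitations

* The correction dynamics are phenomenological; no forces, no endfoot
  mechanics, no neighbour interactions.
* Contact flags are inputs (or simulator ground truth); the package never
  infers contact from images.
* Angles are 2D, measured in the z-projected plane containing the
  apicobasal axis; fully 3D division axes are out of scope.
* The random/bimodal/planar-shifted call and the continuity threshold
  scale are documented operational choices; comparisons across packages
  should pin them explicitly.
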