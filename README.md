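# telocorrect

Quantification and simulation of mitotic division orientation in stratified
epithelia, built around the observation that in the embryonic epidermis the
division axis is not fixed at anaphase: obliquely oriented divisions are
*corrected* during telophase toward either a planar (in-plane, symmetric) or
perpendicular (out-of-plane, asymmetric) orientation, and the direction of
correction tracks whether the apical daughter keeps a basal endfoot on the
basement membrane.

The package is aimed at groups analysing live-imaging or fixed-section
division-angle data (and the associated junction/LGN/clone measurements) and
at anyone wanting a generative null model for those measurements.

## What it provides

* **Angle geometry** — division angles folded into [0°, 90°] relative to a
  local basement-membrane direction; orientation bins planar [0°, 30°),
  oblique [30°, 60°), perpendicular [60°, 90°]; signed LGN radial angles and
  axis–LGN deviation.
* **Distribution statistics** — radial histograms, cumulative frequency
  distributions, one- and two-sample Kolmogorov–Smirnov tests against
  uniformity on [0°, 90°], categorical χ² tests, and an operational
  random / bimodal / planar-shifted call for angle pools.
* **Correction analysis** — per-division correction Δ = θ − φ (φ = angle at
  anaphase onset, θ = one hour later), an outcome table over entry/exit
  bins, contact-conditioned outcome summaries, trajectory settling times,
  and contact-predicts-direction accuracy.
* **Two-step simulator** — step 1 draws φ (uniform, or an LGN-dependent
  planar/oblique/perpendicular mixture); step 2 relaxes oblique entries
  exponentially, `angle(t) = target + (φ − target)·exp(−t/τ)`, toward the
  planar target when basal contact is retained or the perpendicular target
  when it is lost, with per-frame folded Gaussian noise. Genotype presets:
  `WT_E16.5`, `WT_E14.5`, `Gpsm2_KD`, `AJ_mutant`, `Afdn_KD`, `Gpsm2_Afdn`.
* **Synthetic micrographs + image metrics** — ground-truth junction images
  (linear vs zipper morphologies), radial cortical profiles and annotated
  epidermis sections, with the matching measurements: junction continuity,
  orthogonal linescans and center intensities, background-subtracted channel
  ratios, radial intensity fraction and LGN recruitment calls, endfoot
  anisotropy, K10 thickness, densities, mitotic index.
* **Clonal analysis** — SB:basal ratios, clone classification (balanced /
  basal-rich / SB-rich / delamination / excluded), clonal density arrays,
  and a division-outcome-driven clone simulator.

## Worked example

```r
library(telocorrect)

co <- simulate_cohort("WT_E16.5", n = 10000, seed = 42)
classify_distribution(phi_sample(co))
#> distribution call: random (KS p = 0.208; planar/oblique/perp = 0.34/0.33/0.34)
classify_distribution(theta_sample(co))
#> distribution call: bimodal (KS p = 0; planar/oblique/perp = 0.53/0.01/0.46)

oc <- correction_outcome(co$divisions$phi, co$divisions$theta)
round(100 * table(oc$outcome[oc$entry_class == "oblique"]) /
        sum(oc$entry_class == "oblique"), 1)
#>        corrected_planar corrected_perpendicular
#>                    60.5                    39.5
contact_prediction_accuracy(co)
#> [1] 1

img <- make_junction_image("zipper", duty_cycle = 0.4, seed = 1)
junction_continuity(img)
#> [1] 40.6
```

The cohort reproduces the field's signature: the angle pool at anaphase
onset is indistinguishable from uniform ("random"), while one hour later the
pool is bimodal with the oblique bin nearly emptied. Of the oblique entries,
60.5% corrected to planar (the contact-retention probability is 0.6) and the
rest to perpendicular; under the model's defaults basal contact predicts the
direction perfectly. The zipper junction image, generated with 40% of its
length occupied by puncta, scores a continuity of 40.6%.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "telocorrect.R", package = "telocorrect"))')" \
  simulate WT_E16.5 1000 7 out/
```

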