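# melanoscene

Melanopsin and ipRGC excitation statistics of hyperspectral scenes.

Intrinsically photosensitive retinal ganglion cells (ipRGCs) blend an
intrinsic melanopsin signal with cone inputs and drive circadian
entrainment, the pupil reflex and other non-image-forming functions. This
package computes what everyday environments look like *through* that
channel: it takes hyperspectral scenes (radiance cubes, or reflectance
cubes plus an illuminant), produces per-pixel excitation maps for L, M and
S cones, melanopsin, photopic luminance and two ipRGC codification models,
pools them through raised-cosine receptive-field windows tiled as
non-overlapping patches, and derives local excitations, between-patch
Michelson contrasts and the group statistics that compare natural with
human-made environments. It is written for visual and circadian
neuroscientists working with hyperspectral imagery, and it ships everything
needed to exercise the full chain without external downloads: a synthetic
scene generator and silent-substitution validation stimuli.

## The model in brief

Per pixel, the excitation of photoreceptor class $c$ is the rectangle-rule
integral of radiance against a corneal sensitivity on a 5-nm grid over
400–700 nm:

$$E_c = \sum_\lambda L_e(\lambda)\, s_c(\lambda)\, \Delta\lambda .$$

Two ipRGC codifications combine the maps pixel-wise:

$$\mathrm{ipRGC}_1 = 0.667\,L + 0.333\,M + 0.69\,\mathrm{Mel} - 0.12\,S,
\qquad \mathrm{ipRGC}_2 = L + M + \mathrm{Mel} - S .$$

Receptive fields are raised-cosine windows
$\omega_i \propto \tfrac12(1 + \cos(\pi d_i/r))$, normalized to sum 1, of
diameter 1.37° (parafoveal ipRGC), 2.4° (peripheral ipRGC) and 0.36°
(parasol/luminance). The local excitation of patch $j$ is
$E_j = \sum_i \omega_i E_i$ and its between-patch contrast is the absolute
Michelson deviation from the scene mean of the patches,
$C_j = |E_j - E_s| / E_s$. The normalized relative difference across
illuminants, median/IQR summaries, t/F tests, one-way ANOVA with
Tukey–Kramer post-tests and Pearson excitation–contrast correlations make
up the statistics layer. See the methods vignette
(`vignettes/melanoscene-methods.Rmd`) for assumptions, parameter rationale
and design choices.

## Worked example

```r
library(melanoscene)

scene    <- generateScene(sceneGeneratorSpec("human_made", seed = 7))
radiance <- applyIlluminant(scene, cieDaylightSPD(6500))
maps     <- computeAllChannels(radiance)
layout   <- tilePatches(dim(mapValues(maps$Mel)), receptiveFieldSpec(1.37),
                        pixelsPerDegree(radiance), sceneId = sceneId(radiance))
contrasts <- betweenPatchContrast(localExcitation(maps$Mel, layout))
contrasts
#> SceneContrastSet 'human_made_seed7' Mel @ 1.37 deg: 16 patches, scene mean 5545, median contrast 0.06888
summarizeMedianIQR(contrastRecords(contrasts)$contrast)
#>     median        iqr
#> 0.06888213 0.07521835
```

A generated human-made scene (mean reflectance 0.5) under D65 daylight
yields a melanopsin scene-mean local excitation of 5545 relative units
across 16 parafoveal receptive fields, with a median between-patch contrast
of 0.069 — each field's local excitation deviates from the scene mean by
about 7% at the median. Pairing melanopsin (1.37°) with co-centred
luminance (0.36°) fields gives one contrast pair per receptive field:

```r
pairs <- pairChannelContrasts(maps, "Mel", "Lum", mode = "physiological")
head(pairs[, c("patch_index", "contrast_a", "contrast_b")], 4)
#>   patch_index contrast_a contrast_b
#> 1           1 0.15791450 0.24639079
#> 2           2 0.02121496 0.07235017
#> 3           3 0.03156650 0.24914892
#> 4           4 0.10300063 0.15330597
```

Photoreceptor-isolating validation stimuli confirm the chain end to end: a
melanopsin-only scene carries exactly the requested melanopsin contrast
while every other channel stays flat.

```r
r  <- renderValidationScene(silentSubstitutionSpec("Mel", 0.3), 128, 128, 32)
validationContrasts(r, receptiveFieldSpec(1.37))
#>            L            M            S          Mel          Lum
#> 1.856697e-16 2.133896e-16 1.350133e-16 3.000000e-01 0.000000e+00
```

The full pipeline — scenes to records, summaries, comparisons and NRD
tables — runs from a YAML configuration via `runPipeline()` or the thin CLI
at `inst/scripts/melanoscene.R` (verbs `synth`, `excite`, `run`).

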