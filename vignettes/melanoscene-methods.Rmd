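---
title: "Melanopsin scene statistics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melanopsin scene statistics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(melanoscene)
```

## The scientific question

Intrinsically photosensitive retinal ganglion cells (ipRGCs) combine an
intrinsic melanopsin photocurrent with extrinsic cone inputs (L and M
excitatory, S inhibitory) and drive non-image-forming vision: circadian
entrainment, the pupil reflex, mood. How the statistics of everyday visual
environments look *through* this channel — as opposed to through the
cone-driven luminance channel — is the question this package
operationalizes. It turns a hyperspectral scene (radiance per pixel per
wavelength, or reflectance plus an illuminant) into per-channel excitation
maps, pools them through receptive-field-sized windows, and compares local
excitation and between-patch contrast between natural and human-made
environments.

## From spectra to excitation

Every spectrum is linearly interpolated onto a uniform 5-nm grid over
400–700 nm (61 samples) — the spectral coverage of the outdoor hyperspectral
scene sets the analysis targets. Interpolation is linear: it is exactly
testable and is the common choice for a 10 nm to 5 nm refinement. Per pixel,
excitation of a photoreceptor class is the rectangle-rule integral

$$E = \sum_\lambda L_e(\lambda)\, s(\lambda)\, \Delta\lambda , \qquad
\Delta\lambda = 5\ \mathrm{nm},$$

with $s$ the class's corneal spectral sensitivity, peak-normalized to 1.
All outputs are in consistent *relative* units: no calibration constant to
absolute α-opic luminance is bundled, every cross-environment statistic in
the package is scale-free or within-unit, and a scene-level scaling factor
cancels from every contrast (this is tested as an invariant).

**Sensitivity tables.** No machine-readable colorimetric standards are
bundled with R, so the package ships its own plain-text tables under
`inst/extdata/sensitivities/`:

* L, M, S cone fundamentals and the melanopic sensitivity are **synthetic
  template curves** — the Govardovskii A1 visual-pigment nomogram evaluated
  at corneal peaks of 565, 535, 419 and 490 nm, tabulated at 1 nm and
  peak-normalized. Their filenames carry the `synthetic_` prefix: they are
  stand-ins with the right peaks, bandwidths and smoothness, not the
  official tabulations, and absolute excitation values will differ from
  analyses using the official curves. Relative and qualitative results
  (environment orderings, contrast structure, isolation properties) do not
  depend on the exact tabulation.
* V($\lambda$) derives from the CIE 1931 $\bar y$ 10-nm table,
  spline-interpolated to 1 nm.
* The CIE 1931 colour-matching functions and the CIE daylight components
  S0/S1/S2 are published 10-nm tables, used for chromaticity checks and
  daylight construction.

Sensitivities are truncated to 400–700 nm and **not** renormalized after
truncation; this affects only the (relative) absolute scale.

**Luminance** is the weighted sum of the L and M excitations,
$\mathrm{Lum} = a\,L + b\,M$ with the standard CIE pairing of the
10° fundamentals into the luminous efficiency function
($a = 0.6899$, $b = 0.3483$; `luminanceWeights()`), applied to the package's
fundamentals and peak-normalized. Defining luminance as an *exact* L+M
combination — rather than integrating the raw V($\lambda$) table — makes a
stimulus that silences L and M silence luminance identically, which the
silent-substitution validation below relies on; the two routes otherwise
agree up to the fundamentals-to-V($\lambda$) fit error, and the raw table
remains available as channel `"Vlambda"`.

**ipRGC codification.** Two pixel-wise models:

$$\mathrm{ipRGC}_1 = 0.667\,L + 0.333\,M + 0.69\,\mathrm{Mel} - 0.12\,S$$
$$\mathrm{ipRGC}_2 = L + M + \mathrm{Mel} - S$$

The first uses pupillometry-derived weights, the second equal weights with
the subtractive S input. Negative pixel values from the S term are retained
— no rectification is applied anywhere, since contrasts are taken on local
means where negativity is rare under daylight spectra.

**Illuminants.** `cieDaylightSPD(cct)` builds any daylight-series SPD for
4000–25000 K from the S0/S1/S2 components and the daylight-locus closed
form, normalized to 100 at 560 nm; the construction is validated against the
locus polynomial to within $10^{-3}$ in chromaticity. `equalEnergySPD()` is
the constant spectrum. Reflectance scenes are converted to radiance by the
per-pixel, per-wavelength product with an SPD.

## Receptive-field windowing and contrast

Receptive fields are circular cosine windows of diameter 1.37°
(parafoveal ipRGC dendritic fields), 2.4° (peripheral ipRGC) and 0.36°
(parasol cells, used for luminance), converted to pixels by the scene's
`pixelsPerDegree` (a required attribute: source imagery carries no universal
angular scale) and to retinal millimetres by the 0.291 mm/deg magnification
factor.

The default window profile is the raised cosine
$\omega_i \propto \tfrac12\!\left(1 + \cos(\pi d_i / r)\right)$, normalized
to sum 1 over the member pixels: non-negative, maximal at the centre, zero
at the rim. The plain-cosine profile (negative near the rim) is retained as
`window = "literal_cosine"` for replication studies, but a window with a
negative surround would contradict the premise that these cells pool without
spatial opponency, so it is not the default. A pixel belongs to a patch when
its centre (integer coordinates, 0-based, origin top-left) lies within the
patch radius.

Patches tile each image as a rectangular grid with spacing equal to the
field diameter rounded up to whole pixels, anchored top-left; partial
circles are discarded, so patches are pairwise non-overlapping and fully
inside the image. The grid is deterministic; `jitterSeed` draws random
non-overlapping centres instead for sensitivity analyses.

Local excitation is the windowed mean $E_j = \sum_i \omega_i E_i$; local
radiance is the *unweighted* in-circle mean of the wavelength-summed
radiance. The between-patch contrast of patch $j$ is the absolute Michelson
deviation from the scene mean of the patches,

$$C_j = \left|\frac{E_j - E_s}{E_s}\right|, \qquad
E_s = \frac1n \sum_j E_j \ \text{(unweighted)},$$

never truncated at 1 (truncation is a plotting choice, not an analysis
choice).

**Pairing melanopsin with luminance.** The physiological comparison uses
different field sizes per channel (1.37° vs 0.36°), so
`pairChannelContrasts(mode = "physiological")` computes the luminance local
values with 0.36° windows *co-centred* on the 1.37° melanopsin patch centres
— the only pairing that yields exactly one luminance value per melanopsin
field without arbitrary matching. `mode = "matched"` windows both channels
identically at 1.37°, the configuration under which melanopsin and luminance
contrasts correlate strongly. Binning of the paired contrasts
(`binContrastPairs`) defaults to deciles of the first channel's contrast
with median ± IQR per bin; the bin scheme is an argument because no
canonical scheme exists.

## Statistics

Group comparisons pair a pooled-variance independent-samples t-test with a
two-sample F-test for equality of variances (the classical procedure; Welch
by flag), optionally after a natural-log transform — the standard variance
stabilizer for right-skewed intensity data, applied to strictly positive
values only (non-positive values raise a named error with the offender
count). The transform choice is recorded in every output. Quantiles use the
linear-interpolation (type-7) convention. One-way ANOVA reports
$F(k-1, N-k)$ with Tukey HSD post-tests, which honour unequal group sizes
(Tukey–Kramer). The normalized relative difference across illuminants $k$,

$$\mathrm{NRD}_k = \frac{(X_k^{HM} - X_k^{Nat})/X_k^{Nat}}
{\max_k (X_k^{HM} - X_k^{Nat})/X_k^{Nat}},$$

is self-normalizing (maximum entry 1) and invariant to common rescaling of
the group means.

The calibration of the log-transformed t-test is itself tested: on 1000
null replicates of equal lognormal populations ($n = 20$ per group) the
type-I error at $\alpha = 0.05$ must land in [0.03, 0.07].

## The synthetic scene generator

The generator emulates the statistical structure the analysis assumes, not
photorealism. Per pixel, reflectance is

$$\rho(\lambda) = m + a\,s_1(\lambda) + b\,s_2(\lambda),$$

where $m$ is a mean-level field and $a, b$ modulate two smooth, zero-mean
spectral basis shapes (a sigmoidal red–green tilt and a mid-wavelength
band-pass), all three fields spatially correlated (1/f amplitude spectrum by
default, white by option), clipped to [0.001, 1]. Defaults encode the
empirical contrast between environments:

| parameter | natural | human-made | rationale |
|---|---|---|---|
| mean reflectance | 0.2 | 0.5 | built surfaces (walls, glass) reflect more than vegetation |
| reflectance sd | mean/4 | mean/4 | equal coefficient of variation, so *relative* (contrast) statistics are indistinguishable between environments, as observed empirically |
| size / scale | 180×180 px at 32 px/deg | same | tiles 4×4 parafoveal fields per scene |
| spatial correlation | 1/f | 1/f | natural-image scale invariance |

The realized scene mean must land within 10% of the request (clipping can
make extreme mean/sd combinations infeasible; these are rejected). A fixed
seed yields a bit-identical scene.

What the generator does *not* emulate: 3-D geometry, shadows, specular
highlights, camera noise, and the long-tailed luminance distributions of
real scenes. Passing the recovery tests therefore shows the pipeline
*detects the statistical structure it was built to detect* — it does not
certify results on real imagery, for which the external hyperspectral scene
sets are required.

## Silent-substitution validation

The validation stimuli confine contrast to one photoreceptor channel.
Given primary SPDs $P_j$ and the channel response matrix
$R_{cj} = \int P_j s_c \,d\lambda$, the solver finds the minimum-norm
primary-weight change $\Delta w$ with $R \Delta w = c\,E_t\,u_t$: the target
channel moves, every other channel among L, M, S, Mel (and luminance, being
an exact L+M combination) is silenced. The two stimulus spectra straddle the
background symmetrically, $E_t(1 \mp c)$, so the Michelson contrast between
them is exactly $c$ and the gamut excursion per arm is halved — standard
practice. The default background sits at the gamut-optimal point along the
modulation direction; with it, isolation contrasts up to ≈0.5 (L), ≈0.4 (M),
≈0.6 (Mel), ≈0.9 (S, Lum) are representable by non-negative spectra, and
infeasible requests raise a named error rather than clipping.

Five Gaussian primaries (440/480/500/560/630 nm, 30-nm FWHM) are the
default: with four primaries the system is exactly determined and the
minimum-norm freedom that keeps spectra in gamut is lost. "Luminance-only"
is implemented as an L+M-modulating, S- and Mel-silencing solution, since
luminance is not independent of L and M.

`renderValidationScene` builds a two-region (or checkerboard) radiance cube
from the solved pair, with region boundaries on whole pixels;
`validationContrasts` tiles receptive fields strictly inside each region and
verifies that only the target channel carries between-patch contrast — in
practice the non-target residual is at machine precision ($\sim 10^{-16}$),
far below the $10^{-6}$ contract.

## Numerical choices and degenerate inputs

* Extrapolation in wavelength is always an error, never silent.
* Contrast is undefined for a single patch or a zero scene mean (named
  errors); E_s is the unweighted mean of local values.
* Window weights must sum to 1 within $10^{-9}$; the all-rim literal-cosine
  window (zero denominator) is rejected.
* Reflectance above 1, negative radiance and non-finite pixels are rejected
  at construction with offender counts.
* Pipeline runs are deterministic given the configuration; every output
  file embeds a short hash of the analysis configuration, and the run log
  records window mode, transform, tiling and seeds.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated data:
40 scenes of 180×180 px for the environment recovery, 12 white-noise scenes
for the field-size comparison, 1000 replicates for the t-test calibration —
a few tens of seconds on one core. Scenes of the external hyperspectral
sets are ~10× larger per pixel count; the pipeline streams them one at a
time, so memory stays at one cube plus its channel maps.

## Known limitations

* Synthetic sensitivity templates, not the official tabulations (above).
* No ocular-media aging, pupil-size conversion, rod channel, chromatic
  opponency, or eccentricity-dependent field sizes within a scene.
* The environment label is input metadata; the package does not classify
  scenes.
* Absolute excitations are relative; comparisons across datasets require a
  user-supplied calibration.

## A worked example

```{r example, eval = FALSE}
scene <- generateScene(sceneGeneratorSpec("human_made", seed = 7))
radiance <- applyIlluminant(scene, cieDaylightSPD(6500))
maps <- computeAllChannels(radiance)
layout <- tilePatches(dim(mapValues(maps$Mel)), receptiveFieldSpec(1.37),
                      pixelsPerDegree(radiance), sceneId = sceneId(radiance))
contrasts <- betweenPatchContrast(localExcitation(maps$Mel, layout))
summarizeMedianIQR(contrastRecords(contrasts)$contrast)
```
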