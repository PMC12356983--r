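Package: melanoscene
Title: Melanopsin and ipRGC Excitation Statistics of Hyperspectral Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-pixel photoreceptor excitation maps (L, M and S
    cones, melanopsin, photopic luminance and two ipRGC codification models)
    from hyperspectral radiance or reflectance scenes, pools them through
    raised-cosine receptive-field windows tiled as non-overlapping patches,
    and derives between-patch Michelson contrasts and the group statistics
    that compare natural with human-made environments, including the
    normalized relative difference across illuminants. Ships CIE daylight
    illuminant construction, a synthetic hyperspectral scene generator, and
    silent-substitution validation stimuli with photoreceptor-isolating
    contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'spectra.R'
    'excitation.R'
    'receptive-field.R'
    'contrast.R'
    'statistics.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'melanoscene-package.R'
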