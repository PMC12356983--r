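#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("spectralValues", function(x) standardGeneric("spectralValues"))

#' @rdname accessors
#' @export
setGeneric("sceneCube", function(x) standardGeneric("sceneCube"))

#' @rdname accessors
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' @rdname accessors
#' @export
setGeneric("environmentLabel", function(x) standardGeneric("environmentLabel"))

#' @rdname accessors
#' @export
setGeneric("pixelsPerDegree", function(x) standardGeneric("pixelsPerDegree"))

#' @rdname accessors
#' @export
setGeneric("sceneId", function(x) standardGeneric("sceneId"))

#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setGeneric("patchCenters", function(x) standardGeneric("patchCenters"))

#' @rdname accessors
#' @export
setGeneric("patchWeights", function(x) standardGeneric("patchWeights"))

#' @rdname accessors
#' @export
setGeneric("sceneMean", function(x) standardGeneric("sceneMean"))

#' @rdname accessors
#' @export
setGeneric("contrastRecords", function(x) standardGeneric("contrastRecords"))

#' @rdname resampleSpectrum
#' @export
setGeneric("resampleSpectrum", function(f, targetGrid) standardGeneric("resampleSpectrum"))

#' @rdname resampleScene
#' @export
setGeneric("resampleScene", function(scene, stepNm = 5) standardGeneric("resampleScene"))

#' @rdname applyIlluminant
#' @export
setGeneric("applyIlluminant", function(scene, illuminant) standardGeneric("applyIlluminant"))

#' @rdname computeExcitation
#' @export
setGeneric("computeExcitation", function(scene, sensitivity, channel = "Mel")
  standardGeneric("computeExcitation"))

#' @rdname computeLuminance
#' @export
setGeneric("computeLuminance", function(scene) standardGeneric("computeLuminance"))

#' @rdname computeAllChannels
#' @export
setGeneric("computeAllChannels", function(scene) standardGeneric("computeAllChannels"))

#' @rdname tilePatches
#' @export
setGeneric("tilePatches", function(sceneShape, spec, pixelsPerDegree, ...)
  standardGeneric("tilePatches"))

#' @rdname localExcitation
#' @export
setGeneric("localExcitation", function(map, layout) standardGeneric("localExcitation"))

#' @rdname localRadiance
#' @export
setGeneric("localRadiance", function(scene, layout) standardGeneric("localRadiance"))

#' @rdname generateScene
#' @export
setGeneric("generateScene", function(spec) standardGeneric("generateScene"))

#' @rdname solveSilentSubstitution
#' @export
setGeneric("solveSilentSubstitution", function(spec) standardGeneric("solveSilentSubstitution"))

#' @rdname renderValidationScene
#' @export
setGeneric("renderValidationScene", function(spec, height = 128L, width = 128L,
                                             pixelsPerDegree = 32,
                                             sceneId = "validation")
  standardGeneric("renderValidationScene"))
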