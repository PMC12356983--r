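#' Accessors for the package's S4 classes
#'
#' Small extractor functions so user code never touches slots directly.
#'
#' @param x an object of one of the package's classes.
#' @return The corresponding component: numeric vectors/matrices for value
#'   accessors, character scalars for labels.
#' @name accessors
NULL

#' @rdname accessors
setMethod("wavelengths", "SpectralFunction", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "HyperspectralScene", function(x) x@wavelengths)
#' @rdname accessors
setMethod("spectralValues", "SpectralFunction", function(x) x@values)
#' @rdname accessors
setMethod("sceneCube", "HyperspectralScene", function(x) x@cube)
#' @rdname accessors
setMethod("quantity", "HyperspectralScene", function(x) x@quantity)
#' @rdname accessors
setMethod("environmentLabel", "HyperspectralScene", function(x) x@environment)
#' @rdname accessors
setMethod("pixelsPerDegree", "HyperspectralScene", function(x) x@pixelsPerDegree)
#' @rdname accessors
setMethod("pixelsPerDegree", "ChannelMap", function(x) x@pixelsPerDegree)
#' @rdname accessors
setMethod("sceneId", "HyperspectralScene", function(x) x@sceneId)
#' @rdname accessors
setMethod("sceneId", "ChannelMap", function(x) x@sceneId)
#' @rdname accessors
setMethod("sceneId", "PatchLayout", function(x) x@sceneId)
#' @rdname accessors
setMethod("channel", "ChannelMap", function(x) x@channel)
#' @rdname accessors
setMethod("mapValues", "ChannelMap", function(x) x@values)
#' @rdname accessors
setMethod("nPatches", "PatchLayout", function(x) nrow(x@centers))
#' @rdname accessors
setMethod("patchCenters", "PatchLayout", function(x) x@centers)
#' @rdname accessors
setMethod("patchWeights", "PatchLayout", function(x) x@weights)
#' @rdname accessors
setMethod("sceneMean", "SceneContrastSet", function(x) x@sceneMean)
#' @rdname accessors
setMethod("contrastRecords", "SceneContrastSet", function(x) x@records)

setMethod("show", "SpectralFunction", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectralFunction [%s]%s: %d samples, %g-%g nm, peak %.4g at %g nm\n",
              object@kind,
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              length(wl), wl[1], wl[length(wl)],
              max(object@values), wl[which.max(object@values)]))
})

setMethod("show", "HyperspectralScene", function(object) {
  d <- dim(object@cube)
  cat(sprintf("HyperspectralScene '%s': %d x %d px, %d bands (%g-%g nm), %s, %s, %.3g px/deg\n",
              object@sceneId, d[1], d[2], d[3],
              object@wavelengths[1], object@wavelengths[d[3]],
              object@quantity, object@environment, object@pixelsPerDegree))
})

setMethod("show", "ChannelMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ChannelMap %s of '%s': %d x %d px, range [%.4g, %.4g]\n",
              object@channel, object@sceneId, d[1], d[2],
              min(object@values), max(object@values)))
})

setMethod("show", "PatchLayout", function(object) {
  cat(sprintf("PatchLayout for '%s': %d patches, radius %.2f px (%.3g deg, %s window)\n",
              object@sceneId, nrow(object@centers), object@radiusPx,
              object@diameterDeg, object@window))
})

setMethod("show", "SceneContrastSet", function(object) {
  cat(sprintf("SceneContrastSet '%s' %s @ %.3g deg: %d patches, scene mean %.4g, median contrast %.4g\n",
              object@sceneId, object@channel, object@fieldDeg,
              nrow(object@records), object@sceneMean,
              stats::median(object@records$contrast)))
})
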