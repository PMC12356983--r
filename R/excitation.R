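#' ipRGC codification weights
#'
#' Weights on (L, M, S, Mel) for the two codification models: the
#' pupillometry-derived weighting (model 1) and the equal weighting with
#' subtractive S input (model 2).
#'
#' @format Named list with numeric vectors \code{ipRGC1} and \code{ipRGC2},
#'   each with elements L, M, S, Mel.
#' @export
iprgcWeights <- list(
  ipRGC1 = c(L = 0.667, M = 0.333, S = -0.12, Mel = 0.69),
  ipRGC2 = c(L = 1,     M = 1,     S = -1,    Mel = 1))

.check_radiance_grid <- function(scene) {
  if (scene@quantity != "radiance")
    stop("not_radiance: excitation needs a radiance scene, got ",
         scene@quantity, call. = FALSE)
  wl <- scene@wavelengths
  if (length(wl) < 2L || any(abs(diff(wl) - (wl[2] - wl[1])) > 1e-9))
    stop("grid_mismatch: scene must be on a uniform wavelength grid; ",
         "run resampleScene() first", call. = FALSE)
  wl[2] - wl[1]
}

.integrate_cube <- function(scene, sens_values, dl) {
  d <- dim(scene@cube)
  flat <- matrix(scene@cube, nrow = d[1] * d[2], ncol = d[3])
  matrix(as.vector(flat %*% sens_values) * dl, nrow = d[1], ncol = d[2])
}

#' Per-pixel excitation of one photoreceptor class
#'
#' Integrates every pixel's radiance spectrum against a spectral sensitivity
#' by the rectangle rule on the uniform grid:
#' excitation = sum_lambda radiance(lambda) * sensitivity(lambda) * dlambda.
#'
#' @param scene a radiance \linkS4class{HyperspectralScene} on a uniform grid.
#' @param sensitivity a \linkS4class{SpectralFunction}; resampled to the
#'   scene grid if needed (no extrapolation).
#' @param channel channel label recorded on the output map.
#' @return A \linkS4class{ChannelMap}.
#' @rdname computeExcitation
#' @export
setMethod("computeExcitation", signature("HyperspectralScene", "SpectralFunction"),
  function(scene, sensitivity, channel = "Mel") {
    dl <- .check_radiance_grid(scene)
    sens <- resampleSpectrum(sensitivity, scene@wavelengths)
    new("ChannelMap", values = .integrate_cube(scene, sens@values, dl),
        channel = channel, sceneId = scene@sceneId,
        pixelsPerDegree = scene@pixelsPerDegree)
  })

#' Per-pixel photopic luminance
#'
#' Luminance as the weighted sum of L and M cone excitations: radiance is
#' integrated against the effective luminance sensitivity, the L+M
#' combination fit to the V(lambda) luminous efficiency table (see
#' \code{\link{luminanceWeights}}).  Because the luminance channel is an
#' exact linear combination of the L and M maps, a stimulus that silences L
#' and M silences luminance identically; integrating against the raw
#' V(lambda) table instead agrees up to the fundamentals-to-V(lambda) fit
#' error.
#'
#' @param scene a radiance \linkS4class{HyperspectralScene} on a uniform grid.
#' @return A \linkS4class{ChannelMap} with channel \code{"Lum"}.
#' @rdname computeLuminance
#' @export
setMethod("computeLuminance", "HyperspectralScene", function(scene) {
  computeExcitation(scene, sensitivityFunction("Lum"), channel = "Lum")
})

.combine_maps <- function(maps, w, channel) {
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m@values), dim(ref@values)))
      stop("dimension_mismatch: channel maps differ in size", call. = FALSE)
    if (!identical(m@sceneId, ref@sceneId))
      stop("scene_mismatch: channel maps come from different scenes",
           call. = FALSE)
  }
  v <- w[["L"]] * maps$L@values + w[["M"]] * maps$M@values +
    w[["S"]] * maps$S@values + w[["Mel"]] * maps$Mel@values
  new("ChannelMap", values = v, channel = channel, sceneId = ref@sceneId,
      pixelsPerDegree = ref@pixelsPerDegree)
}

#' ipRGC codification model 1 (pupillometry-derived weights)
#'
#' Pixel-wise weighted sum
#' \code{0.667*L + 0.333*M + 0.69*Mel - 0.12*S}.  Negative values from the
#' subtractive S input are retained (no rectification).
#'
#' @param L,M,S,Mel \linkS4class{ChannelMap}s of one scene, equal dimensions.
#' @return A \linkS4class{ChannelMap} with channel \code{"ipRGC1"}.
#' @export
iprgc1 <- function(L, M, S, Mel) {
  .combine_maps(list(L = L, M = M, S = S, Mel = Mel),
                iprgcWeights$ipRGC1, "ipRGC1")
}

#' ipRGC codification model 2 (equal weights)
#'
#' Pixel-wise sum \code{L + M + Mel - S}; the S input stays subtractive and
#' negatives are retained.
#'
#' @inheritParams iprgc1
#' @return A \linkS4class{ChannelMap} with channel \code{"ipRGC2"}.
#' @export
iprgc2 <- function(L, M, S, Mel) {
  .combine_maps(list(L = L, M = M, S = S, Mel = Mel),
                iprgcWeights$ipRGC2, "ipRGC2")
}

#' All channel maps of a scene in one call
#'
#' Computes L, M, S, Mel, Lum and both ipRGC codifications; the ipRGC maps
#' are exactly the weighted combinations of the returned L/M/S/Mel maps.
#'
#' @param scene a radiance \linkS4class{HyperspectralScene} on a uniform grid.
#' @return Named list of \linkS4class{ChannelMap}s:
#'   L, M, S, Mel, Lum, ipRGC1, ipRGC2.
#' @rdname computeAllChannels
#' @export
setMethod("computeAllChannels", "HyperspectralScene", function(scene) {
  dl <- .check_radiance_grid(scene)
  sens <- vapply(c("L", "M", "S", "Mel", "Lum"), function(ch)
    resampleSpectrum(sensitivityFunction(ch), scene@wavelengths)@values,
    numeric(length(scene@wavelengths)))
  d <- dim(scene@cube)
  flat <- matrix(scene@cube, nrow = d[1] * d[2], ncol = d[3])
  ex <- flat %*% sens * dl
  mk <- function(col, channel) new("ChannelMap",
    values = matrix(ex[, col], d[1], d[2]), channel = channel,
    sceneId = scene@sceneId, pixelsPerDegree = scene@pixelsPerDegree)
  maps <- list(L = mk(1, "L"), M = mk(2, "M"), S = mk(3, "S"),
               Mel = mk(4, "Mel"), Lum = mk(5, "Lum"))
  maps$ipRGC1 <- iprgc1(maps$L, maps$M, maps$S, maps$Mel)
  maps$ipRGC2 <- iprgc2(maps$L, maps$M, maps$S, maps$Mel)
  maps
})
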