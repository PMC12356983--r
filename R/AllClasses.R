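#' @import methods
NULL

CHANNELS <- c("L", "M", "S", "Mel", "Lum", "ipRGC1", "ipRGC2", "Rad")
ENVIRONMENTS <- c("natural", "human_made")
WINDOW_MODES <- c("raised_cosine", "literal_cosine")

#' Sampled spectral function
#'
#' A function of wavelength sampled on a strictly increasing grid: a
#' photoreceptor sensitivity, an illuminant spectral power distribution, or a
#' single-pixel radiance/reflectance spectrum.  Sensitivities are
#' peak-normalized to 1; SPDs and radiances are in relative units.
#'
#' @slot wavelengths numeric, strictly increasing grid in nm within [380, 780].
#' @slot values numeric, non-negative for kinds other than \code{"signal"},
#'   same length as \code{wavelengths}.
#' @slot kind one of \code{"sensitivity"}, \code{"spd"}, \code{"radiance"},
#'   \code{"reflectance"}, \code{"signal"} (\code{"signal"} admits negative
#'   values, e.g. silent-substitution difference spectra).
#' @slot name short label used by \code{show}.
#'
#' @export
setClass("SpectralFunction",
  representation(wavelengths = "numeric", values = "numeric",
                 kind = "character", name = "character"),
  prototype(kind = "spd", name = ""))

setValidity("SpectralFunction", function(object) {
  wl <- object@wavelengths; v <- object@values
  if (length(wl) != length(v))
    return("wavelengths and values must have equal length")
  if (length(wl) < 1L) return("empty spectral function")
  if (any(!is.finite(wl)) || any(!is.finite(v)))
    return("wavelengths and values must be finite")
  if (any(diff(wl) <= 0)) return("wavelength grid must be strictly increasing")
  if (wl[1] < 380 || wl[length(wl)] > 780)
    return("wavelength grid must lie within [380, 780] nm")
  if (!object@kind %in% c("sensitivity", "spd", "radiance", "reflectance", "signal"))
    return("unknown spectral kind")
  if (object@kind != "signal" && any(v < 0))
    return("values must be non-negative")
  if (object@kind == "sensitivity" && abs(max(v) - 1) > 1e-9)
    return("sensitivity functions must be peak-normalized to 1")
  TRUE
})

#' Hyperspectral scene cube
#'
#' A height x width x wavelength cube of radiance or reflectance with the
#' metadata the analysis needs: the environment label (taken as input, not
#' inferred) and the angular sampling in pixels per degree.
#'
#' @slot cube numeric 3-d array, height x width x n_wavelengths.
#' @slot wavelengths numeric grid matching the third cube axis.
#' @slot quantity \code{"radiance"} or \code{"reflectance"}.
#' @slot environment \code{"natural"} or \code{"human_made"}.
#' @slot pixelsPerDegree positive scalar, pixels per degree of visual angle.
#' @slot sceneId scene identifier.
#'
#' @export
setClass("HyperspectralScene",
  representation(cube = "array", wavelengths = "numeric", quantity = "character",
                 environment = "character", pixelsPerDegree = "numeric",
                 sceneId = "character"))

setValidity("HyperspectralScene", function(object) {
  d <- dim(object@cube)
  if (length(d) != 3L) return("cube must be a 3-d array")
  if (d[3] != length(object@wavelengths))
    return("third cube axis must match the wavelength grid")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelength grid must be strictly increasing")
  n_nan <- sum(!is.finite(object@cube))
  if (n_nan > 0)
    return(sprintf("cube contains %d non-finite pixel value(s)", n_nan))
  if (!object@quantity %in% c("radiance", "reflectance"))
    return("quantity must be 'radiance' or 'reflectance'")
  if (any(object@cube < 0))
    return(sprintf("cube contains %d negative value(s)", sum(object@cube < 0)))
  if (object@quantity == "reflectance" && any(object@cube > 1))
    return(sprintf("reflectance above 1 at %d pixel value(s)",
                   sum(object@cube > 1)))
  if (!object@environment %in% ENVIRONMENTS)
    return("environment must be 'natural' or 'human_made'")
  if (length(object@pixelsPerDegree) != 1L || !is.finite(object@pixelsPerDegree) ||
      object@pixelsPerDegree <= 0)
    return("pixelsPerDegree must be a positive scalar")
  TRUE
})

#' Per-pixel excitation map for one channel
#'
#' @slot values numeric matrix, same height x width as the source scene.
#' @slot channel one of L, M, S, Mel, Lum, ipRGC1, ipRGC2, Rad.
#' @slot sceneId source scene identifier.
#' @slot pixelsPerDegree angular sampling inherited from the scene.
#'
#' @export
setClass("ChannelMap",
  representation(values = "matrix", channel = "character",
                 sceneId = "character", pixelsPerDegree = "numeric"))

setValidity("ChannelMap", function(object) {
  if (!object@channel %in% CHANNELS)
    return(sprintf("channel must be one of: %s", paste(CHANNELS, collapse = ", ")))
  if (any(!is.finite(object@values))) return("map values must be finite")
  # ipRGC maps may be negative (subtractive S input); the rest may not
  if (!object@channel %in% c("ipRGC1", "ipRGC2") && any(object@values < 0))
    return(sprintf("%s map must be non-negative", object@channel))
  if (object@pixelsPerDegree <= 0) return("pixelsPerDegree must be positive")
  TRUE
})

#' Receptive-field specification
#'
#' Diameter in degrees of visual angle plus the window form.  Defaults follow
#' ipRGC dendritic-field sizes in the parafovea (1.37 deg) and periphery
#' (2.4 deg) and the 0.36 deg parasol field used for luminance.
#'
#' @slot diameterDeg positive field diameter in degrees.
#' @slot window \code{"raised_cosine"} (default; non-negative, zero at the rim)
#'   or \code{"literal_cosine"} (plain cosine profile, negative at the rim,
#'   kept for replication studies).
#'
#' @export
setClass("ReceptiveFieldSpec",
  representation(diameterDeg = "numeric", window = "character"),
  prototype(diameterDeg = 1.37, window = "raised_cosine"))

setValidity("ReceptiveFieldSpec", function(object) {
  if (length(object@diameterDeg) != 1L || !is.finite(object@diameterDeg) ||
      object@diameterDeg <= 0)
    return("diameterDeg must be a positive scalar")
  if (!object@window %in% WINDOW_MODES)
    return("window must be 'raised_cosine' or 'literal_cosine'")
  TRUE
})

#' Layout of non-overlapping circular receptive-field patches
#'
#' Centers, radius and per-patch normalized pixel weights for a set of
#' pairwise non-overlapping circular patches fully inside one image.
#' Coordinates are 0-based (row, column), origin top-left; pixel centers sit
#' at integer coordinates.
#'
#' @slot centers n x 2 matrix, columns \code{y0} (row) and \code{x0} (column).
#' @slot radiusPx patch radius in pixels.
#' @slot diameterDeg field diameter in degrees that produced the layout.
#' @slot window window mode used for the weights.
#' @slot pixels list of integer vectors: 1-based linear indices (column-major)
#'   of the member pixels of each patch.
#' @slot weights list of numeric vectors parallel to \code{pixels}; each sums
#'   to 1.
#' @slot sceneShape integer (height, width) of the image the layout tiles.
#' @slot sceneId scene identifier.
#'
#' @export
setClass("PatchLayout",
  representation(centers = "matrix", radiusPx = "numeric", diameterDeg = "numeric",
                 window = "character", pixels = "list", weights = "list",
                 sceneShape = "integer", sceneId = "character"))

setValidity("PatchLayout", function(object) {
  n <- nrow(object@centers)
  if (n < 1L) return("layout must contain at least one patch")
  if (length(object@pixels) != n || length(object@weights) != n)
    return("pixels and weights must have one entry per patch")
  r <- object@radiusPx
  if (r <= 0) return("radiusPx must be positive")
  h <- object@sceneShape[1]; w <- object@sceneShape[2]
  if (any(object@centers[, 1] - r < -0.5 - 1e-9) ||
      any(object@centers[, 1] + r > h - 0.5 + 1e-9) ||
      any(object@centers[, 2] - r < -0.5 - 1e-9) ||
      any(object@centers[, 2] + r > w - 0.5 + 1e-9))
    return("every patch must lie fully inside the image")
  if (n > 1L) {
    dmat <- as.matrix(stats::dist(object@centers))
    if (any(dmat[upper.tri(dmat)] < 2 * r - 1e-9))
      return("patches must be pairwise non-overlapping")
  }
  for (j in seq_len(n)) {
    wt <- object@weights[[j]]
    if (abs(sum(wt) - 1) > 1e-9)
      return(sprintf("weights of patch %d do not sum to 1", j))
    if (object@window == "raised_cosine" && any(wt < -1e-12))
      return(sprintf("negative weight in raised_cosine patch %d", j))
  }
  TRUE
})

#' Between-patch contrasts of one scene and channel
#'
#' Holds the scene-level mean of the local values (the Michelson reference)
#' and the per-patch records with the contrast column filled.
#'
#' @slot sceneId scene identifier.
#' @slot channel channel the contrasts were computed on.
#' @slot fieldDeg receptive-field diameter in degrees.
#' @slot sceneMean mean of the patches' local values (unweighted).
#' @slot records data.frame with columns \code{scene_id}, \code{channel},
#'   \code{field_deg}, \code{patch_index}, \code{x0}, \code{y0},
#'   \code{local_value}, \code{contrast}.
#'
#' @export
setClass("SceneContrastSet",
  representation(sceneId = "character", channel = "character",
                 fieldDeg = "numeric", sceneMean = "numeric",
                 records = "data.frame"))

setValidity("SceneContrastSet", function(object) {
  rec <- object@records
  need <- c("scene_id", "channel", "field_deg", "patch_index", "x0", "y0",
            "local_value", "contrast")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns: %s", paste(need, collapse = ", ")))
  if (abs(mean(rec$local_value) - object@sceneMean) > 1e-9 * max(1, abs(object@sceneMean)))
    return("sceneMean must equal the mean of the records' local values")
  if (any(rec$contrast < 0)) return("contrasts must be non-negative")
  TRUE
})

#' Synthetic-scene generator specification
#'
#' Parameters of the reflectance-scene generator that emulates the statistical
#' structure the analysis assumes: environment-dependent mean reflectance
#' (human-made above natural), smooth per-pixel spectra from a small basis,
#' spatially correlated structure, and a known angular scale.
#'
#' @slot environment \code{"natural"} or \code{"human_made"}.
#' @slot height,width image size in pixels.
#' @slot pixelsPerDegree angular sampling.
#' @slot meanReflectance target scene-mean reflectance in (0, 1).
#' @slot reflectanceSd spatial standard deviation of pixel mean reflectance.
#' @slot spatialCorrelation \code{"white"} or \code{"one_over_f"}.
#' @slot seed integer RNG seed; a fixed seed gives a bit-identical scene.
#'
#' @export
setClass("SceneGeneratorSpec",
  representation(environment = "character", height = "integer", width = "integer",
                 pixelsPerDegree = "numeric", meanReflectance = "numeric",
                 reflectanceSd = "numeric", spatialCorrelation = "character",
                 seed = "integer"))

setValidity("SceneGeneratorSpec", function(object) {
  if (!object@environment %in% ENVIRONMENTS)
    return("environment must be 'natural' or 'human_made'")
  if (object@height < 1L || object@width < 1L) return("height/width must be positive")
  if (object@pixelsPerDegree <= 0) return("pixelsPerDegree must be positive")
  if (object@meanReflectance <= 0 || object@meanReflectance >= 1)
    return("meanReflectance must lie in (0, 1)")
  if (object@reflectanceSd < 0) return("reflectanceSd must be non-negative")
  if (!object@spatialCorrelation %in% c("white", "one_over_f"))
    return("spatialCorrelation must be 'white' or 'one_over_f'")
  TRUE
})

#' Silent-substitution stimulus specification
#'
#' Defines a photoreceptor-isolating stimulus: which channel carries contrast,
#' how much (Michelson, relative to the background), the primary spectra, the
#' background weights on the primaries, and the spatial layout of the rendered
#' validation scene.
#'
#' @slot targetChannel \code{"L"}, \code{"M"}, \code{"S"}, \code{"Mel"} or
#'   \code{"Lum"} (luminance: L+M modulated jointly with S and Mel silenced).
#' @slot targetContrast Michelson contrast (>= 0) on the target channel.
#' @slot primaries list of >= 4 SpectralFunction SPDs.
#' @slot backgroundWeights positive weights of the primaries in the background.
#' @slot layout \code{"two_region"} or \code{"checkerboard"}.
#'
#' @export
setClass("SilentSubstitutionSpec",
  representation(targetChannel = "character", targetContrast = "numeric",
                 primaries = "list", backgroundWeights = "numeric",
                 layout = "character"))

setValidity("SilentSubstitutionSpec", function(object) {
  if (!object@targetChannel %in% c("L", "M", "S", "Mel", "Lum"))
    return("targetChannel must be one of L, M, S, Mel, Lum")
  if (object@targetContrast < 0 || object@targetContrast >= 1)
    return("targetContrast must lie in [0, 1)")
  if (length(object@primaries) < 4L)
    return("at least 4 primaries are required")
  if (!all(vapply(object@primaries, is, logical(1), "SpectralFunction")))
    return("primaries must be SpectralFunction objects")
  nw <- length(object@backgroundWeights)
  if (nw != 0L && nw != length(object@primaries))
    return("one background weight per primary is required (or none for the gamut-optimal default)")
  if (any(object@backgroundWeights <= 0))
    return("background weights must be positive")
  if (!object@layout %in% c("two_region", "checkerboard"))
    return("layout must be 'two_region' or 'checkerboard'")
  TRUE
})
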