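#' Receptive-field size conversions
#'
#' Visual angle to pixels via a scene's angular sampling, and to retinal
#' distance via the retinal magnification factor of 0.291 mm/deg.
#'
#' @param diameterDeg field diameter in degrees (> 0).
#' @param pixelsPerDegree angular sampling of the scene (> 0).
#' @return \code{degToPx}: diameter in pixels; \code{degToMm}: retinal
#'   diameter in mm.
#' @examples
#' degToPx(1.37, 30)  # 41.1 px
#' degToMm(1)         # 0.291 mm
#' @export
degToPx <- function(diameterDeg, pixelsPerDegree) {
  if (any(diameterDeg <= 0) || any(pixelsPerDegree <= 0))
    stop("nonpositive_size: diameterDeg and pixelsPerDegree must be positive",
         call. = FALSE)
  diameterDeg * pixelsPerDegree
}

#' @rdname degToPx
#' @export
degToMm <- function(diameterDeg) {
  if (any(diameterDeg <= 0))
    stop("nonpositive_size: diameterDeg must be positive", call. = FALSE)
  diameterDeg * 0.291
}

#' Construct a ReceptiveFieldSpec
#'
#' @param diameterDeg field diameter in degrees; the analyses use 1.37
#'   (ipRGC parafovea), 2.4 (ipRGC periphery) and 0.36 (parasol/luminance).
#' @param window \code{"raised_cosine"} (default) or \code{"literal_cosine"}.
#' @return A \linkS4class{ReceptiveFieldSpec}.
#' @export
receptiveFieldSpec <- function(diameterDeg = 1.37, window = "raised_cosine") {
  new("ReceptiveFieldSpec", diameterDeg = diameterDeg, window = window)
}

.window_profile <- function(dist, radius, window) {
  if (window == "raised_cosine") 0.5 * (1 + cos(pi * dist / radius))
  else cos(pi * dist / radius)
}

#' Raised-cosine window weights over a pixel set
#'
#' Weights of the circular cosine window centred at \code{center}, normalized
#' to sum 1 over the supplied pixels.  In \code{"raised_cosine"} mode (the
#' default) the profile is (1 + cos(pi d / r)) / 2: non-negative, maximal at
#' the centre, zero at the rim; the normalization makes the 1/2 immaterial.
#' \code{"literal_cosine"} evaluates the plain cosine profile (negative near
#' the rim) and is kept for replication studies only.
#'
#' @param radiusPx window radius r in pixels.
#' @param center numeric length-2 centre (y0, x0), 0-based.
#' @param pixelCoords n x 2 matrix of pixel coordinates (y, x), all within
#'   distance r of the centre.
#' @param window window mode.
#' @return Numeric weights summing to 1, one per pixel.
#' @examples
#' raisedCosineWeights(2, c(0, 0), rbind(c(0, 0)))  # single pixel: weight 1
#' @export
raisedCosineWeights <- function(radiusPx, center, pixelCoords,
                                window = c("raised_cosine", "literal_cosine")) {
  window <- match.arg(window)
  pixelCoords <- matrix(pixelCoords, ncol = 2)
  d <- sqrt((pixelCoords[, 1] - center[1])^2 + (pixelCoords[, 2] - center[2])^2)
  if (any(d > radiusPx + 1e-9))
    stop("pixel_outside_radius: ", sum(d > radiusPx + 1e-9),
         " pixel(s) beyond the window radius", call. = FALSE)
  w <- .window_profile(d, radiusPx, window)
  s <- sum(w)
  if (abs(s) < 1e-12)
    stop("degenerate_window: window weights sum to zero", call. = FALSE)
  w / s
}

#' Tile an image with non-overlapping receptive-field patches
#'
#' Places circle centres on a rectangular grid with spacing equal to the
#' field diameter (rounded up to whole pixels), anchored at the top-left-most
#' fitting position; partial circles at the borders are discarded.  The
#' layout is deterministic for fixed inputs; \code{jitterSeed} instead draws
#' random non-overlapping centres (dart throwing) for sensitivity analyses.
#' A pixel belongs to a patch when its centre (integer coordinates, 0-based,
#' origin top-left) lies within the patch radius.
#'
#' @param sceneShape integer (height, width) in pixels.
#' @param spec a \linkS4class{ReceptiveFieldSpec}.
#' @param pixelsPerDegree angular sampling used to size the field.
#' @param sceneId identifier stored on the layout.
#' @param jitterSeed optional integer; random placement with this seed.
#' @param ... unused.
#' @return A \linkS4class{PatchLayout}.
#' @examples
#' nPatches(tilePatches(c(100L, 100L), receptiveFieldSpec(5), 10))  # 4
#' @rdname tilePatches
#' @export
setMethod("tilePatches", signature("numeric", "ReceptiveFieldSpec", "numeric"),
  function(sceneShape, spec, pixelsPerDegree, sceneId = "scene",
           jitterSeed = NULL, ...) {
    h <- as.integer(sceneShape[1]); w <- as.integer(sceneShape[2])
    d_px <- degToPx(spec@diameterDeg, pixelsPerDegree)
    s <- ceiling(d_px)            # integer-pixel spacing (bounding box)
    r <- d_px / 2
    if (s > h || s > w)
      stop("no_patch_fits: a ", s, "-px field does not fit a ", h, "x", w,
           " image", call. = FALSE)
    if (is.null(jitterSeed)) {
      k_y <- seq(0, floor(h / s) - 1)
      k_x <- seq(0, floor(w / s) - 1)
      centers <- as.matrix(expand.grid(y0 = k_y * s + (s - 1) / 2,
                                       x0 = k_x * s + (s - 1) / 2))
    } else {
      centers <- .jitter_centers(h, w, s, floor(h / s) * floor(w / s), jitterSeed)
    }
    .build_layout(centers, r, spec, c(h, w), sceneId)
  })

.jitter_centers <- function(h, w, s, n_target, seed) {
  withr::with_seed(seed, {
    lo <- (s - 1) / 2
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_target && tries < 200L * n_target) {
      cand <- c(stats::runif(1, lo, h - 1 - lo), stats::runif(1, lo, w - 1 - lo))
      ok <- nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= s)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
    }
    if (nrow(centers) == 0L)
      stop("no_patch_fits: jittered placement found no valid centre",
           call. = FALSE)
    colnames(centers) <- c("y0", "x0")
    centers
  })
}

.build_layout <- function(centers, r, spec, shape, sceneId) {
  h <- shape[1]; w <- shape[2]
  pixels <- vector("list", nrow(centers))
  weights <- vector("list", nrow(centers))
  for (j in seq_len(nrow(centers))) {
    y0 <- centers[j, 1]; x0 <- centers[j, 2]
    ys <- max(0, ceiling(y0 - r)):min(h - 1, floor(y0 + r))
    xs <- max(0, ceiling(x0 - r)):min(w - 1, floor(x0 + r))
    gg <- expand.grid(y = ys, x = xs)
    keep <- sqrt((gg$y - y0)^2 + (gg$x - x0)^2) <= r
    gg <- gg[keep, , drop = FALSE]
    pixels[[j]] <- as.integer(gg$y + 1L + gg$x * h)   # column-major 1-based
    weights[[j]] <- raisedCosineWeights(r, c(y0, x0), cbind(gg$y, gg$x),
                                        spec@window)
  }
  new("PatchLayout", centers = centers, radiusPx = r,
      diameterDeg = spec@diameterDeg, window = spec@window, pixels = pixels,
      weights = weights, sceneShape = as.integer(shape), sceneId = sceneId)
}

#' Layout with smaller windows co-centred on an existing layout
#'
#' Builds the 0.36-degree luminance windows on the same centres as an ipRGC
#' layout, so each ipRGC receptive field has exactly one paired luminance
#' value (the pairing used by the physiological-mode contrast comparison).
#'
#' @param layout an existing \linkS4class{PatchLayout}.
#' @param spec a \linkS4class{ReceptiveFieldSpec} with a smaller diameter.
#' @param pixelsPerDegree angular sampling.
#' @return A \linkS4class{PatchLayout} with the same centres.
#' @export
coCenteredLayout <- function(layout, spec, pixelsPerDegree) {
  r <- degToPx(spec@diameterDeg, pixelsPerDegree) / 2
  if (r > layout@radiusPx + 1e-9)
    stop("field_too_large: co-centred field exceeds the host patch radius",
         call. = FALSE)
  .build_layout(layout@centers, r, spec, layout@sceneShape, layout@sceneId)
}

#' Local (windowed) excitation of each patch
#'
#' Per patch, the weighted mean of the channel-map pixels under the patch's
#' normalized window: E_j = sum_i w_i E_i.
#'
#' @param map a \linkS4class{ChannelMap}.
#' @param layout a \linkS4class{PatchLayout} built for the map's dimensions.
#' @return data.frame with one row per patch: \code{scene_id},
#'   \code{channel}, \code{field_deg}, \code{patch_index}, \code{x0},
#'   \code{y0}, \code{local_value}, \code{contrast} (NA until filled by
#'   \code{\link{betweenPatchContrast}}).
#' @rdname localExcitation
#' @export
setMethod("localExcitation", signature("ChannelMap", "PatchLayout"),
  function(map, layout) {
    if (!identical(dim(map@values), as.integer(layout@sceneShape)))
      stop("dimension_mismatch: layout built for ",
           paste(layout@sceneShape, collapse = "x"), ", map is ",
           paste(dim(map@values), collapse = "x"), call. = FALSE)
    v <- map@values
    vals <- vapply(seq_len(nPatches(layout)), function(j)
      sum(layout@weights[[j]] * v[layout@pixels[[j]]]), numeric(1))
    data.frame(scene_id = map@sceneId, channel = map@channel,
               field_deg = layout@diameterDeg,
               patch_index = seq_along(vals),
               x0 = layout@centers[, "x0"], y0 = layout@centers[, "y0"],
               local_value = vals, contrast = NA_real_,
               row.names = NULL)
  })

#' Local radiance of each patch
#'
#' The unweighted mean over the in-circle pixels of the wavelength-integrated
#' radiance (sum over lambda of radiance times the grid step).
#'
#' @param scene a radiance \linkS4class{HyperspectralScene} on a uniform grid.
#' @param layout a \linkS4class{PatchLayout} for the scene's dimensions.
#' @return data.frame as \code{\link{localExcitation}}, channel \code{"Rad"}.
#' @rdname localRadiance
#' @export
setMethod("localRadiance", signature("HyperspectralScene", "PatchLayout"),
  function(scene, layout) {
    dl <- .check_radiance_grid(scene)
    d <- dim(scene@cube)
    total <- matrix(rowSums(matrix(scene@cube, nrow = d[1] * d[2])), d[1], d[2]) * dl
    rad_map <- new("ChannelMap", values = total, channel = "Rad",
                   sceneId = scene@sceneId,
                   pixelsPerDegree = scene@pixelsPerDegree)
    if (!identical(dim(total), as.integer(layout@sceneShape)))
      stop("dimension_mismatch: layout does not match the scene", call. = FALSE)
    vals <- vapply(seq_len(nPatches(layout)), function(j)
      mean(total[layout@pixels[[j]]]), numeric(1))
    out <- localExcitation(rad_map, layout)
    out$local_value <- vals
    out
  })
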