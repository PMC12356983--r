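#' Construct a scene-generator specification
#'
#' Defaults encode the statistical structure the analysis assumes: human-made
#' surfaces reflect more light on average than natural ones (mean reflectance
#' 0.5 vs 0.2), while the spatial coefficient of variation is the same in
#' both environments (reflectanceSd defaults to a quarter of the mean), so
#' relative (contrast) statistics are indistinguishable at defaults.  Scenes
#' default to 180 x 180 px at 32 px/deg, which tiles 4 x 4 parafoveal
#' (1.37 deg) receptive fields per scene, and to 1/f spatial correlation.
#'
#' @param environment \code{"natural"} or \code{"human_made"}.
#' @param height,width image size in pixels.
#' @param pixelsPerDegree angular sampling.
#' @param meanReflectance target scene-mean reflectance; defaults 0.2
#'   (natural) / 0.5 (human-made).
#' @param reflectanceSd spatial sd of pixel mean reflectance; default
#'   \code{meanReflectance / 4}.
#' @param spatialCorrelation \code{"one_over_f"} (default) or \code{"white"}.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SceneGeneratorSpec}.
#' @export
sceneGeneratorSpec <- function(environment = c("natural", "human_made"),
                               height = 180L, width = 180L,
                               pixelsPerDegree = 32,
                               meanReflectance = NULL, reflectanceSd = NULL,
                               spatialCorrelation = c("one_over_f", "white"),
                               seed = 1L) {
  environment <- match.arg(environment)
  spatialCorrelation <- match.arg(spatialCorrelation)
  if (is.null(meanReflectance))
    meanReflectance <- if (environment == "natural") 0.2 else 0.5
  if (is.null(reflectanceSd)) reflectanceSd <- meanReflectance / 4
  new("SceneGeneratorSpec", environment = environment,
      height = as.integer(height), width = as.integer(width),
      pixelsPerDegree = as.numeric(pixelsPerDegree),
      meanReflectance = meanReflectance, reflectanceSd = reflectanceSd,
      spatialCorrelation = spatialCorrelation, seed = as.integer(seed))
}

# zero-mean, unit-sd random field; "one_over_f" filters white noise with a
# 1/f amplitude spectrum (scale-invariant structure), "white" is iid
.random_field <- function(h, w, type) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (type == "white") return((z - mean(z)) / stats::sd(z))
  fy <- c(0:floor(h / 2), -rev(seq_len(ceiling(h / 2) - 1))) / h
  fx <- c(0:floor(w / 2), -rev(seq_len(ceiling(w / 2) - 1))) / w
  f <- sqrt(outer(fy^2, fx^2, "+"))
  f[1, 1] <- Inf                       # drop the DC term
  field <- Re(stats::fft(stats::fft(z) / f, inverse = TRUE)) / (h * w)
  (field - mean(field)) / stats::sd(field)
}

# smooth reflectance basis: zero-mean sigmoidal (red-green tilt) and
# band-pass shapes over the working grid
.reflectance_basis <- function(grid) {
  s1 <- tanh((grid - 550) / 60)
  s2 <- exp(-((grid - 540) / 50)^2)
  cbind(tilt = s1 - mean(s1), band = s2 - mean(s2))
}

#' Generate a synthetic reflectance scene
#'
#' Per-pixel reflectance is a mean-level field plus spatially correlated
#' mixtures of two smooth spectral basis shapes, clipped to [0.001, 1].  The
#' realized scene mean must land within 10% of the requested mean (otherwise
#' the mean/sd combination is rejected as infeasible after clipping).  A
#' fixed seed yields a bit-identical scene.
#'
#' @param spec a \linkS4class{SceneGeneratorSpec}.
#' @return A reflectance \linkS4class{HyperspectralScene} on the 5-nm grid.
#' @examples
#' sc <- generateScene(sceneGeneratorSpec("natural", 32, 32, seed = 7))
#' @rdname generateScene
#' @export
setMethod("generateScene", "SceneGeneratorSpec", function(spec) {
  grid <- workingGrid()
  basis <- .reflectance_basis(grid)
  h <- spec@height; w <- spec@width
  cube <- withr::with_seed(spec@seed, {
    level <- spec@meanReflectance +
      spec@reflectanceSd * .random_field(h, w, spec@spatialCorrelation)
    a <- 0.4 * spec@reflectanceSd * .random_field(h, w, spec@spatialCorrelation)
    b <- 0.4 * spec@reflectanceSd * .random_field(h, w, spec@spatialCorrelation)
    flat <- as.vector(level) %o% rep(1, length(grid)) +
      as.vector(a) %o% basis[, "tilt"] + as.vector(b) %o% basis[, "band"]
    array(pmin(pmax(flat, 0.001), 1), dim = c(h, w, length(grid)))
  })
  realized <- mean(cube)
  if (abs(realized - spec@meanReflectance) > 0.1 * spec@meanReflectance)
    stop("infeasible_reflectance: realized mean ", signif(realized, 4),
         " deviates more than 10% from requested ", spec@meanReflectance,
         " (clipping too severe for this mean/sd)", call. = FALSE)
  hyperspectralScene(cube, grid, quantity = "reflectance",
                     environment = spec@environment,
                     pixelsPerDegree = spec@pixelsPerDegree,
                     sceneId = sprintf("%s_seed%d", spec@environment, spec@seed))
})

#' Default Gaussian stimulation primaries
#'
#' Five Gaussian SPDs peaking at 440, 480, 500, 560 and 630 nm with 30-nm
#' FWHM: a well-conditioned basis for the five-channel (L, M, S, Mel and
#' table-based luminance) silent-substitution system.  The fifth primary
#' gives the solver the freedom to silence V(lambda) luminance exactly
#' alongside the cones when isolating melanopsin; with only four primaries
#' the luminance constraint is dropped and a small residual luminance
#' modulation remains.
#'
#' @param peaksNm peak wavelengths.
#' @param fwhmNm full width at half maximum, recycled over peaks.
#' @return List of \linkS4class{SpectralFunction} SPDs.
#' @export
gaussianPrimaries <- function(peaksNm = c(440, 480, 500, 560, 630), fwhmNm = 30) {
  grid <- workingGrid()
  sd <- rep_len(fwhmNm, length(peaksNm)) / (2 * sqrt(2 * log(2)))
  lapply(seq_along(peaksNm), function(i)
    spectralFunction(grid, exp(-((grid - peaksNm[i])^2) / (2 * sd[i]^2)),
                     kind = "spd", name = sprintf("primary %g nm", peaksNm[i])))
}

#' Construct a silent-substitution specification
#'
#' @param targetChannel \code{"L"}, \code{"M"}, \code{"S"}, \code{"Mel"} or
#'   \code{"Lum"}.
#' @param targetContrast Michelson contrast on the target channel, in [0, 1).
#' @param primaries list of >= 4 primary SPDs.
#' @param backgroundWeights positive primary weights of the background; when
#'   omitted the solver places the background at the gamut-optimal point for
#'   the requested isolation direction.
#' @param layout \code{"two_region"} or \code{"checkerboard"}.
#' @return A \linkS4class{SilentSubstitutionSpec}.
#' @export
silentSubstitutionSpec <- function(targetChannel, targetContrast = 0.3,
                                   primaries = gaussianPrimaries(),
                                   backgroundWeights = NULL,
                                   layout = "two_region") {
  if (is.null(backgroundWeights)) backgroundWeights <- numeric(0)
  new("SilentSubstitutionSpec", targetChannel = targetChannel,
      targetContrast = targetContrast, primaries = primaries,
      backgroundWeights = backgroundWeights, layout = layout)
}

.response_matrix <- function(primaries, channels) {
  grid <- workingGrid()
  dl <- grid[2] - grid[1]
  P <- vapply(primaries, function(p)
    resampleSpectrum(p, grid)@values, numeric(length(grid)))
  S <- vapply(channels, function(ch) sensitivityFunction(ch)@values,
              numeric(length(grid)))
  list(R = t(S) %*% P * dl, P = P, grid = grid)
}

#' Solve a silent-substitution modulation
#'
#' Finds a pair of spectra straddling the nominal background symmetrically
#' (the standard practice that maximizes gamut headroom): on the target
#' channel their excitations are E_bg (1 - c) and E_bg (1 + c), so the
#' Michelson contrast between the pair is exactly c, while every non-target
#' channel among L, M, S, Mel is identical in both (silenced).  A
#' \code{"Lum"} target modulates L and M jointly (luminance is not
#' independent of them) while silencing S and Mel, taking the minimum-norm
#' primary-weight change for the remaining freedom.  At c = 0 both spectra
#' equal the background.
#'
#' @param spec a \linkS4class{SilentSubstitutionSpec}.
#' @return List: \code{background} (low arm) and \code{modulated} (high arm)
#'   \linkS4class{SpectralFunction}s, the primary \code{weights} (matrix,
#'   rows bg/mod), achieved per-channel excitations (\code{excitation},
#'   rows bg/mod over L, M, S, Mel, Lum) and \code{achievedContrast}.
#' @rdname solveSilentSubstitution
#' @export
setMethod("solveSilentSubstitution", "SilentSubstitutionSpec", function(spec) {
  chans <- c("L", "M", "S", "Mel", "Lum")
  core <- c("L", "M", "S", "Mel")
  rm_ <- .response_matrix(spec@primaries, chans)
  np <- ncol(rm_$R)
  qrR <- qr(t(rm_$R[core, , drop = FALSE]))
  if (qrR$rank < length(core)) {
    dep <- core[qrR$pivot[(qrR$rank + 1):length(core)]]
    stop("rank_deficient_primaries: primaries cannot independently control ",
         "channel(s): ", paste(dep, collapse = ", "), call. = FALSE)
  }
  # constraint rows: silenced channels plus the target row; table-based
  # luminance is silenced too whenever the primary set has the rank for it
  silenced <- if (spec@targetChannel == "Lum") c("S", "Mel")
  else setdiff(chans, spec@targetChannel)
  A <- rm_$R[c(silenced, spec@targetChannel), , drop = FALSE]
  if (qr(t(A))$rank < nrow(A) && "Lum" %in% silenced) {
    silenced <- setdiff(silenced, "Lum")
    A <- rm_$R[c(silenced, spec@targetChannel), , drop = FALSE]
  }
  qrA <- qr(t(A))
  if (qrA$rank < nrow(A)) {
    dep <- rownames(A)[qrA$pivot[(qrA$rank + 1):nrow(A)]]
    stop("rank_deficient_primaries: primaries cannot independently control ",
         "channel(s): ", paste(dep, collapse = ", "), call. = FALSE)
  }
  # minimum-norm modulation direction giving unit change on the target
  u <- c(numeric(length(silenced)), 1)
  v <- as.vector(t(A) %*% solve(A %*% t(A), u))
  w_bg <- spec@backgroundWeights
  if (length(w_bg) == 0L)          # gamut-optimal background along |v|
    w_bg <- abs(v) / max(abs(v))
  e_bg <- as.vector(rm_$R %*% w_bg)          # L M S Mel Lum
  names(e_bg) <- chans
  cc <- spec@targetContrast
  dw <- cc * e_bg[[spec@targetChannel]] * v
  w_lo <- w_bg - dw
  w_hi <- w_bg + dw
  e_lo <- as.vector(rm_$R %*% w_lo); names(e_lo) <- c(core, "Lum")
  e_hi <- as.vector(rm_$R %*% w_hi); names(e_hi) <- c(core, "Lum")
  lo_spd <- as.vector(rm_$P %*% w_lo)
  hi_spd <- as.vector(rm_$P %*% w_hi)
  if (any(lo_spd < -1e-9) || any(hi_spd < -1e-9))
    stop("negative_spd: requested contrast drives a modulation spectrum ",
         "negative; lower the contrast or choose broader primaries",
         call. = FALSE)
  achieved <- (e_hi[spec@targetChannel] - e_lo[spec@targetChannel]) /
    (e_hi[spec@targetChannel] + e_lo[spec@targetChannel])
  list(background = spectralFunction(rm_$grid, pmax(lo_spd, 0),
                                     kind = "radiance", name = "background"),
       modulated = spectralFunction(rm_$grid, pmax(hi_spd, 0),
                                    kind = "radiance", name = "modulated"),
       weights = rbind(bg = w_lo, mod = w_hi),
       excitation = rbind(bg = e_lo, mod = e_hi),
       achievedContrast = unname(achieved))
})

#' Render a photoreceptor-isolating validation scene
#'
#' Builds a radiance cube from a solved silent substitution: two vertical
#' half-regions (background left, modulated right) or a 2 x 2 checkerboard of
#' the two spectra.  Region boundaries fall on whole pixels so receptive
#' fields tiled inside each region never straddle a boundary.
#'
#' @param spec a \linkS4class{SilentSubstitutionSpec}.
#' @param height,width scene size in pixels (width split into regions).
#' @param pixelsPerDegree angular sampling.
#' @param sceneId identifier.
#' @return List: \code{scene} (radiance \linkS4class{HyperspectralScene}),
#'   \code{regions} (data.frame of 0-based inclusive pixel bounds with a
#'   \code{role} column) and the \code{solution} from
#'   \code{\link{solveSilentSubstitution}}.
#' @rdname renderValidationScene
#' @export
setMethod("renderValidationScene", "SilentSubstitutionSpec",
  function(spec, height = 128L, width = 128L, pixelsPerDegree = 32,
           sceneId = "validation") {
    sol <- solveSilentSubstitution(spec)
    grid <- workingGrid()
    h <- as.integer(height); w <- as.integer(width)
    cube <- array(0, dim = c(h, w, length(grid)))
    if (spec@layout == "two_region") {
      half <- w %/% 2L
      regions <- data.frame(y0 = c(0L, 0L), y1 = c(h - 1L, h - 1L),
                            x0 = c(0L, half), x1 = c(half - 1L, w - 1L),
                            role = c("background", "modulated"))
    } else {
      hy <- h %/% 2L; hx <- w %/% 2L
      regions <- data.frame(
        y0 = c(0L, 0L, hy, hy), y1 = c(hy - 1L, hy - 1L, h - 1L, h - 1L),
        x0 = c(0L, hx, 0L, hx), x1 = c(hx - 1L, w - 1L, hx - 1L, w - 1L),
        role = c("background", "modulated", "modulated", "background"))
    }
    for (i in seq_len(nrow(regions))) {
      spd <- if (regions$role[i] == "background")
        sol$background@values else sol$modulated@values
      ys <- (regions$y0[i]:regions$y1[i]) + 1L
      xs <- (regions$x0[i]:regions$x1[i]) + 1L
      cube[ys, xs, ] <- rep(spd, each = length(ys) * length(xs))
    }
    list(scene = hyperspectralScene(cube, grid, quantity = "radiance",
                                    environment = "human_made",
                                    pixelsPerDegree = pixelsPerDegree,
                                    sceneId = sceneId),
         regions = regions, solution = sol)
  })

#' Per-channel between-patch contrasts of a validation scene
#'
#' Tiles receptive fields inside each region of a rendered validation scene
#' (so no field straddles a region boundary), computes every channel map and
#' the between-patch contrast per channel: the isolation check that only the
#' target channel carries contrast.
#'
#' @param rendered list from \code{\link{renderValidationScene}}.
#' @param spec a \linkS4class{ReceptiveFieldSpec} for the tiling.
#' @return Named numeric: maximum between-patch contrast per channel
#'   (L, M, S, Mel, Lum).
#' @export
validationContrasts <- function(rendered, spec = receptiveFieldSpec(1.37)) {
  scene <- rendered$scene
  regions <- rendered$regions
  maps <- computeAllChannels(scene)
  ppd <- pixelsPerDegree(scene)
  d_px <- ceiling(degToPx(spec@diameterDeg, ppd))
  small <- regions$y1 - regions$y0 + 1L < d_px | regions$x1 - regions$x0 + 1L < d_px
  if (any(small))
    stop("field_exceeds_region: the ", spec@diameterDeg,
         "-deg field does not fit inside every region", call. = FALSE)
  out <- vapply(c("L", "M", "S", "Mel", "Lum"), function(ch) {
    recs <- lapply(seq_len(nrow(regions)), function(i) {
      ys <- (regions$y0[i]:regions$y1[i]) + 1L
      xs <- (regions$x0[i]:regions$x1[i]) + 1L
      sub <- new("ChannelMap",
                 values = mapValues(maps[[ch]])[ys, xs, drop = FALSE],
                 channel = ch, sceneId = sceneId(scene),
                 pixelsPerDegree = ppd)
      layout <- tilePatches(dim(mapValues(sub)), spec, ppd,
                            sceneId = sceneId(scene))
      localExcitation(sub, layout)
    })
    pooled <- do.call(rbind, recs)
    pooled$patch_index <- seq_len(nrow(pooled))
    max(contrastRecords(betweenPatchContrast(pooled))$contrast)
  }, numeric(1))
  out
}
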