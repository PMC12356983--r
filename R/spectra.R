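#' Construct a SpectralFunction
#'
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param values sampled values, same length as the grid.
#' @param kind one of \code{"sensitivity"}, \code{"spd"}, \code{"radiance"},
#'   \code{"reflectance"}, \code{"signal"}.
#' @param name optional label.
#' @return A \linkS4class{SpectralFunction}.
#' @examples
#' spectralFunction(seq(400, 700, 5), rep(1, 61), kind = "spd", name = "EES")
#' @export
spectralFunction <- function(wavelengths, values, kind = "spd", name = "") {
  new("SpectralFunction", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values), kind = kind, name = name)
}

#' Construct a HyperspectralScene
#'
#' @param cube height x width x n_wavelengths non-negative array.
#' @param wavelengths grid matching the third cube axis.
#' @param quantity \code{"radiance"} or \code{"reflectance"}.
#' @param environment \code{"natural"} or \code{"human_made"}.
#' @param pixelsPerDegree positive angular sampling (the source imagery has no
#'   universal default; it must be supplied).
#' @param sceneId identifier.
#' @return A \linkS4class{HyperspectralScene}.
#' @export
hyperspectralScene <- function(cube, wavelengths, quantity = "radiance",
                               environment = "natural", pixelsPerDegree,
                               sceneId = "scene") {
  new("HyperspectralScene", cube = cube, wavelengths = as.numeric(wavelengths),
      quantity = quantity, environment = environment,
      pixelsPerDegree = as.numeric(pixelsPerDegree), sceneId = sceneId)
}

#' The working 5-nm wavelength grid
#'
#' The analysis operates on 400-700 nm at 5 nm (61 samples), matching the
#' spectral coverage of the hyperspectral scene sets.
#'
#' @param stepNm grid step in nm (default 5).
#' @return Numeric wavelength grid.
#' @export
workingGrid <- function(stepNm = 5) seq(400, 700, by = stepNm)

#' Resample a spectral function onto a new grid
#'
#' Linear interpolation; values at grid points shared with the source grid are
#' unchanged.  Extrapolation is refused.
#'
#' @param f a \linkS4class{SpectralFunction}.
#' @param targetGrid strictly increasing grid inside the convex hull of
#'   \code{f}'s grid.
#' @return A \linkS4class{SpectralFunction} on \code{targetGrid}.
#' @examples
#' f <- spectralFunction(c(400, 410), c(0, 10), kind = "signal")
#' spectralValues(resampleSpectrum(f, 405))  # 5
#' @rdname resampleSpectrum
#' @export
setMethod("resampleSpectrum", "SpectralFunction", function(f, targetGrid) {
  wl <- f@wavelengths
  targetGrid <- as.numeric(targetGrid)
  if (min(targetGrid) < wl[1] - 1e-9 || max(targetGrid) > wl[length(wl)] + 1e-9)
    stop("spectral_extrapolation: target grid [", min(targetGrid), ", ",
         max(targetGrid), "] exceeds source grid [", wl[1], ", ",
         wl[length(wl)], "]", call. = FALSE)
  v <- stats::approx(wl, f@values, xout = targetGrid, method = "linear",
                     ties = "ordered")$y
  new("SpectralFunction", wavelengths = targetGrid, values = v,
      kind = f@kind, name = f@name)
})

#' Resample every pixel spectrum of a scene to a uniform grid
#'
#' Interpolates the cube to a uniform wavelength sampling (default 5 nm over
#' the intersection of [400, 700] with the scene's own span), so every scene
#' in a dataset shares one spectral resolution.  Metadata are preserved; a
#' scene already on the target grid is returned with a bitwise-equal cube.
#'
#' @param scene a \linkS4class{HyperspectralScene} whose grid spans [400, 700].
#' @param stepNm target step in nm (default 5).
#' @return The resampled scene.
#' @rdname resampleScene
#' @export
setMethod("resampleScene", "HyperspectralScene", function(scene, stepNm = 5) {
  wl <- scene@wavelengths
  if (wl[1] > 400 + 1e-9 || wl[length(wl)] < 700 - 1e-9)
    stop("spectral_extrapolation: scene grid [", wl[1], ", ", wl[length(wl)],
         "] does not span [400, 700] nm", call. = FALSE)
  target <- workingGrid(stepNm)
  if (length(wl) == length(target) && all(wl == target)) return(scene)
  d <- dim(scene@cube)
  flat <- matrix(scene@cube, nrow = d[1] * d[2], ncol = d[3])
  # interpolation of all pixels at once: weights of the two bracketing bands
  idx <- findInterval(target, wl, rightmost.closed = TRUE)
  idx <- pmin(idx, length(wl) - 1L)
  frac <- (target - wl[idx]) / (wl[idx + 1L] - wl[idx])
  out <- flat[, idx, drop = FALSE] * rep(1 - frac, each = nrow(flat)) +
    flat[, idx + 1L, drop = FALSE] * rep(frac, each = nrow(flat))
  new("HyperspectralScene", cube = array(out, dim = c(d[1], d[2], length(target))),
      wavelengths = target, quantity = scene@quantity,
      environment = scene@environment, pixelsPerDegree = scene@pixelsPerDegree,
      sceneId = scene@sceneId)
})

# ---- bundled spectral tables ----------------------------------------------

.spectral_cache <- new.env(parent = emptyenv())

.read_two_col <- function(file) {
  path <- system.file("extdata", "sensitivities", file, package = "melanoscene",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

#' Bundled spectral sensitivity functions
#'
#' Returns one of the package's sensitivity tables resampled to the working
#' 5-nm grid and peak-normalized.  The L/M/S cone fundamentals and the
#' melanopic sensitivity are synthetic template curves (Govardovskii A1
#' visual-pigment nomogram at corneal peaks 565/535/419/490 nm) standing in
#' for the tabulated standards; V(lambda) derives from the CIE 1931 ybar
#' table.  Truncation to 400-700 nm is not followed by renormalization of the
#' integral, so absolute excitation scale is relative throughout.
#'
#' @param channel \code{"L"}, \code{"M"}, \code{"S"}, \code{"Mel"},
#'   \code{"Vlambda"} (the raw table) or \code{"Lum"} (the effective
#'   luminance sensitivity: the L+M combination that reproduces V(lambda) in
#'   least squares, so luminance is an exact weighted sum of L and M cone
#'   excitations).
#' @param stepNm grid step (default 5).
#' @return A \linkS4class{SpectralFunction} of kind \code{"sensitivity"}.
#' @examples
#' wavelengths(sensitivityFunction("Mel"))[which.max(spectralValues(
#'   sensitivityFunction("Mel")))]  # corneal melanopic peak near 490 nm
#' @export
sensitivityFunction <- function(channel = c("L", "M", "S", "Mel", "Vlambda",
                                            "Lum"),
                                stepNm = 5) {
  channel <- match.arg(channel)
  key <- paste0(channel, "@", stepNm)
  if (!is.null(.spectral_cache[[key]])) return(.spectral_cache[[key]])
  if (channel == "Lum") {
    out <- .luminance_sensitivity(stepNm)
    assign(key, out, envir = .spectral_cache)
    return(out)
  }
  file <- switch(channel,
    L = "synthetic_l_cone_fundamental_1nm.tsv",
    M = "synthetic_m_cone_fundamental_1nm.tsv",
    S = "synthetic_s_cone_fundamental_1nm.tsv",
    Mel = "synthetic_melanopic_sensitivity_1nm.tsv",
    Vlambda = "vlambda_1nm.tsv")
  tab <- .read_two_col(file)
  f <- spectralFunction(tab$wavelength_nm, tab$value, kind = "signal",
                        name = channel)
  f <- resampleSpectrum(f, workingGrid(stepNm))
  v <- f@values / max(f@values)
  out <- new("SpectralFunction", wavelengths = f@wavelengths, values = v,
             kind = "sensitivity", name = channel)
  assign(key, out, envir = .spectral_cache)
  out
}

# effective luminance sensitivity: the fixed L+M pairing, peak-normalized
.luminance_sensitivity <- function(stepNm = 5) {
  ab <- luminanceWeights()
  comb <- ab[["L"]] * sensitivityFunction("L", stepNm)@values +
    ab[["M"]] * sensitivityFunction("M", stepNm)@values
  new("SpectralFunction", wavelengths = sensitivityFunction("L", stepNm)@wavelengths,
      values = comb / max(comb), kind = "sensitivity", name = "Lum")
}

#' Weights of the L and M fundamentals in the luminance channel
#'
#' Luminance is the weighted sum Lum = a L + b M with the standard CIE
#' pairing of the 10-degree fundamentals into the luminous efficiency
#' function (a = 0.68990272, b = 0.34832189, roughly 2:1), applied to the
#' package's fundamentals and peak-normalized as a sensitivity.  Defining
#' luminance as an exact L+M combination (rather than integrating the raw
#' V(lambda) table) makes a stimulus that silences L and M silence luminance
#' identically, which the silent-substitution validation relies on; the raw
#' table remains available as channel \code{"Vlambda"}.
#'
#' @return Named numeric \code{c(L, M)}.
#' @export
luminanceWeights <- function() {
  c(L = 0.68990272, M = 0.34832189)
}

#' Load a sensitivity or illuminant from a two-column text file
#'
#' Plain-text interface for user-supplied tables: lines of
#' \code{wavelength_nm<TAB>value}, \code{#} comments allowed.
#'
#' @param path file path.
#' @param kind spectral kind of the result.
#' @param name optional label (defaults to the file name).
#' @return A \linkS4class{SpectralFunction}.
#' @export
readSpectrum <- function(path, kind = "spd", name = basename(path)) {
  tab <- utils::read.delim(path, comment.char = "#")
  if (ncol(tab) < 2L)
    stop("spectrum_format: expected two columns (wavelength_nm, value) in ",
         path, call. = FALSE)
  v <- as.numeric(tab[[2]])
  if (kind == "sensitivity") v <- v / max(v)
  spectralFunction(as.numeric(tab[[1]]), v, kind = kind, name = name)
}

.daylight_components <- function() {
  if (is.null(.spectral_cache$daylight)) {
    assign("daylight", .read_two_col("cie_daylight_components_10nm.tsv"),
           envir = .spectral_cache)
  }
  .spectral_cache$daylight
}

.cmf_table <- function() {
  if (is.null(.spectral_cache$cmf)) {
    assign("cmf", .read_two_col("cie1931_cmf_10nm.tsv"), envir = .spectral_cache)
  }
  .spectral_cache$cmf
}

#' Daylight-locus chromaticity for a correlated colour temperature
#'
#' The closed-form CIE daylight-locus polynomial: x from CCT, y from x.
#' Exposed so the daylight SPD construction can be checked independently.
#'
#' @param cctKelvin correlated colour temperature in K, 4000-25000.
#' @return Named numeric \code{c(x, y)}.
#' @export
daylightLocusXY <- function(cctKelvin) {
  if (cctKelvin < 4000 || cctKelvin > 25000)
    stop("cct_out_of_range: supported CCT range is 4000-25000 K, got ",
         cctKelvin, call. = FALSE)
  t <- cctKelvin
  x <- if (t <= 7000)
    0.244063 + 0.09911e3 / t + 2.9678e6 / t^2 - 4.6070e9 / t^3
  else
    0.237040 + 0.24748e3 / t + 1.9018e6 / t^2 - 2.0064e9 / t^3
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  c(x = x, y = y)
}

#' CIE daylight illuminant SPD for a given CCT
#'
#' Builds the relative spectral power distribution of the CIE daylight series
#' from the tabulated daylight components S0, S1, S2 and the daylight-locus
#' closed form, on the 5-nm working grid, normalized to 100 at 560 nm.  Any
#' CCT in 4000-25000 K is supported (the scene analyses use 25000, 6500 and
#' 4000 K); for bit-exact replication of an external table use
#' \code{\link{readSpectrum}} instead.
#'
#' @param cctKelvin correlated colour temperature in K, 4000-25000.
#' @param stepNm grid step (default 5).
#' @return A \linkS4class{SpectralFunction} of kind \code{"spd"}.
#' @examples
#' d65 <- cieDaylightSPD(6500)
#' spectralValues(d65)[wavelengths(d65) == 560]  # 100 by convention
#' @export
cieDaylightSPD <- function(cctKelvin, stepNm = 5) {
  xy <- daylightLocusXY(cctKelvin)
  x <- xy[["x"]]; y <- xy[["y"]]
  m0 <- 0.0241 + 0.2562 * x - 0.7341 * y
  m1 <- (-1.3515 - 1.7703 * x + 5.9114 * y) / m0
  m2 <- (0.0300 - 31.4424 * x + 30.0717 * y) / m0
  comp <- .daylight_components()
  grid <- workingGrid(stepNm)
  s0 <- stats::approx(comp$wavelength_nm, comp$S0, grid)$y
  s1 <- stats::approx(comp$wavelength_nm, comp$S1, grid)$y
  s2 <- stats::approx(comp$wavelength_nm, comp$S2, grid)$y
  spd <- s0 + m1 * s1 + m2 * s2
  spd <- spd / spd[grid == 560] * 100
  spectralFunction(grid, spd, kind = "spd",
                   name = sprintf("CIE daylight %g K", cctKelvin))
}

#' Equal-energy spectrum illuminant
#'
#' Constant relative power at every wavelength of the working grid,
#' normalized to 100 (so all illuminants share the 560-nm convention).
#'
#' @param stepNm grid step (default 5).
#' @return A \linkS4class{SpectralFunction} of kind \code{"spd"}.
#' @export
equalEnergySPD <- function(stepNm = 5) {
  grid <- workingGrid(stepNm)
  spectralFunction(grid, rep(100, length(grid)), kind = "spd", name = "EES")
}

#' Chromaticity coordinates of a spectrum
#'
#' Integrates an SPD against the bundled CIE 1931 colour-matching functions
#' (interpolated to the SPD's grid) and returns (x, y).  Used to validate the
#' daylight construction and the equal-energy illuminant.
#'
#' @param spd a \linkS4class{SpectralFunction}.
#' @return Named numeric \code{c(x, y)}.
#' @export
chromaticity <- function(spd) {
  cmf <- .cmf_table()
  wl <- spd@wavelengths
  if (min(wl) < min(cmf$wavelength_nm) || max(wl) > max(cmf$wavelength_nm))
    stop("spectral_extrapolation: SPD grid exceeds the CMF table range",
         call. = FALSE)
  xb <- stats::approx(cmf$wavelength_nm, cmf$xbar, wl)$y
  yb <- stats::approx(cmf$wavelength_nm, cmf$ybar, wl)$y
  zb <- stats::approx(cmf$wavelength_nm, cmf$zbar, wl)$y
  v <- spd@values
  X <- sum(v * xb); Y <- sum(v * yb); Z <- sum(v * zb)
  c(x = X / (X + Y + Z), y = Y / (X + Y + Z))
}

#' Convert a reflectance scene to radiance under an illuminant
#'
#' Per pixel and wavelength, radiance = reflectance x illuminant SPD.  Both
#' are first resampled to the 5-nm working grid; the result is flagged as
#' radiance.  Linear in the illuminant.
#'
#' @param scene a reflectance \linkS4class{HyperspectralScene}.
#' @param illuminant a \linkS4class{SpectralFunction} SPD covering the grid.
#' @return A radiance \linkS4class{HyperspectralScene}.
#' @rdname applyIlluminant
#' @export
setMethod("applyIlluminant", signature("HyperspectralScene", "SpectralFunction"),
  function(scene, illuminant) {
    if (scene@quantity != "reflectance")
      stop("not_reflectance: applyIlluminant needs a reflectance scene, got ",
           scene@quantity, call. = FALSE)
    scene <- resampleScene(scene)
    ill <- resampleSpectrum(illuminant, scene@wavelengths)
    if (!isTRUE(all.equal(ill@wavelengths, scene@wavelengths)))
      stop("grid_mismatch: illuminant grid does not match the scene grid",
           call. = FALSE)
    d <- dim(scene@cube)
    cube <- scene@cube * rep(ill@values, each = d[1] * d[2])
    new("HyperspectralScene", cube = cube, wavelengths = scene@wavelengths,
        quantity = "radiance", environment = scene@environment,
        pixelsPerDegree = scene@pixelsPerDegree, sceneId = scene@sceneId)
  })
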