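test_that("resampleSpectrum interpolates linearly and refuses extrapolation", {
  # constant function stays constant on a refined grid
  f <- spectralFunction(seq(400, 700, 10), rep(3, 31), kind = "spd")
  out <- resampleSpectrum(f, seq(400, 700, 5))
  expect_equal(spectralValues(out), rep(3, 61))

  # closed-form linear interpolation between two samples
  g <- spectralFunction(c(400, 410), c(0, 10), kind = "signal")
  expect_equal(spectralValues(resampleSpectrum(g, 405)), 5)

  # identity on the source grid
  out2 <- resampleSpectrum(f, wavelengths(f))
  expect_identical(spectralValues(out2), spectralValues(f))

  # idempotent on its own output grid
  once <- resampleSpectrum(f, seq(405, 695, 5))
  twice <- resampleSpectrum(once, wavelengths(once))
  expect_identical(spectralValues(once), spectralValues(twice))

  expect_error(resampleSpectrum(f, seq(390, 700, 5)), "spectral_extrapolation")
})

test_that("resampleScene matches per-pixel resampleSpectrum and preserves metadata", {
  # constant cube on a 10-nm grid
  wl10 <- seq(400, 700, 10)
  cube <- array(2, dim = c(2, 2, 31))
  sc <- hyperspectralScene(cube, wl10, pixelsPerDegree = 10, sceneId = "c",
                           environment = "human_made")
  out <- resampleScene(sc)
  expect_equal(sceneCube(out), array(2, dim = c(2, 2, 61)))
  expect_identical(environmentLabel(out), "human_made")
  expect_identical(sceneId(out), "c")

  # already on the 5-nm grid: bitwise identical
  sc5 <- flat_scene(2, 2, value = 0.5)
  expect_identical(sceneCube(resampleScene(sc5)), sceneCube(sc5))

  # single-pixel scene agrees with the spectrum-level oracle
  withr::with_seed(4, v <- runif(31))
  one <- hyperspectralScene(array(v, dim = c(1, 1, 31)), wl10,
                            pixelsPerDegree = 10, sceneId = "p")
  got <- as.vector(sceneCube(resampleScene(one)))
  oracle <- spectralValues(resampleSpectrum(
    spectralFunction(wl10, v, kind = "radiance"), grid5))
  expect_equal(got, oracle, tolerance = 1e-12)

  # grid not spanning 400-700 is refused
  short <- hyperspectralScene(array(1, dim = c(1, 1, 21)), seq(450, 650, 10),
                              pixelsPerDegree = 10)
  expect_error(resampleScene(short), "spectral_extrapolation")
})

test_that("bundled sensitivities are non-negative, peak-normalized, peaks in stated bands", {
  bands <- list(L = c(560, 570), M = c(530, 540), S = c(415, 425),
                Mel = c(480, 500), Vlambda = c(550, 560), Lum = c(550, 565))
  for (ch in names(bands)) {
    f <- sensitivityFunction(ch)
    v <- spectralValues(f)
    expect_true(all(v >= 0), label = paste(ch, "non-negative"))
    expect_equal(max(v), 1)
    peak <- wavelengths(f)[which.max(v)]
    expect_gte(peak, bands[[ch]][1])
    expect_lte(peak, bands[[ch]][2])
  }
})

test_that("luminance sensitivity is the stated L+M combination", {
  ab <- luminanceWeights()
  comb <- ab[["L"]] * spectralValues(sensitivityFunction("L")) +
    ab[["M"]] * spectralValues(sensitivityFunction("M"))
  expect_equal(spectralValues(sensitivityFunction("Lum")), comb / max(comb),
               tolerance = 1e-12)
})

test_that("CIE daylight SPD matches the daylight-locus closed form", {
  for (cct in c(4000, 6500, 25000)) {
    spd <- cieDaylightSPD(cct)
    # normalization convention
    expect_equal(spectralValues(spd)[wavelengths(spd) == 560], 100)
    # chromaticity against the independently evaluated locus polynomial
    xy <- chromaticity(spd)
    locus <- daylightLocusXY(cct)
    expect_lt(max(abs(xy - locus)), 1e-3)
  }
  # blue shift with CCT
  r450 <- function(spd) {
    v <- spectralValues(spd); wl <- wavelengths(spd)
    v[wl == 450] / v[wl == 650]
  }
  expect_gt(r450(cieDaylightSPD(25000)), r450(cieDaylightSPD(4000)))
  expect_error(cieDaylightSPD(3000), "cct_out_of_range")
  expect_error(cieDaylightSPD(30000), "cct_out_of_range")
})

test_that("equal-energy SPD is constant with equal-energy chromaticity", {
  ees <- equalEnergySPD()
  v <- spectralValues(ees)
  expect_true(all(v == v[1]))
  # chromaticity equals the CMF-integral equal-energy point
  cmf <- read.delim(system.file("extdata", "sensitivities",
                                "cie1931_cmf_10nm.tsv",
                                package = "melanoscene"), comment.char = "#")
  xb <- approx(cmf$wavelength_nm, cmf$xbar, grid5)$y
  yb <- approx(cmf$wavelength_nm, cmf$ybar, grid5)$y
  zb <- approx(cmf$wavelength_nm, cmf$zbar, grid5)$y
  oracle <- c(x = sum(xb), y = sum(yb)) / (sum(xb) + sum(yb) + sum(zb))
  expect_equal(chromaticity(ees), oracle, tolerance = 1e-6)
})

test_that("applyIlluminant multiplies pixel-wise and is linear in the illuminant", {
  ones <- flat_scene(2, 2, value = 1, quantity = "reflectance")
  ees <- equalEnergySPD()
  out <- applyIlluminant(ones, ees)
  expect_identical(quantity(out), "radiance")
  expect_equal(as.vector(sceneCube(out)[1, 1, ]), spectralValues(ees))

  zero <- flat_scene(2, 2, value = 0, quantity = "reflectance")
  expect_true(all(sceneCube(applyIlluminant(zero, ees)) == 0))

  # scalar product: reflectance 0.5 under EES of value 2
  half <- flat_scene(1, 1, value = 0.5, quantity = "reflectance")
  ill2 <- spectralFunction(grid5, rep(2, 61), kind = "spd")
  expect_equal(as.vector(sceneCube(applyIlluminant(half, ill2))), rep(1, 61))

  # doubling the SPD doubles every radiance value
  refl <- flat_scene(2, 2, value = 0.3, quantity = "reflectance")
  d65 <- cieDaylightSPD(6500)
  doubled <- spectralFunction(wavelengths(d65), 2 * spectralValues(d65))
  expect_equal(sceneCube(applyIlluminant(refl, doubled)),
               2 * sceneCube(applyIlluminant(refl, d65)))

  # radiance input is refused
  expect_error(applyIlluminant(flat_scene(1, 1), ees), "not_reflectance")
})

test_that("scene invariants reject reflectance above 1 and non-finite pixels", {
  cube <- array(0.5, dim = c(2, 2, 61))
  cube[1, 1, 3] <- 1.2
  expect_error(hyperspectralScene(cube, grid5, quantity = "reflectance",
                                  pixelsPerDegree = 10),
               "reflectance above 1 at 1")
  cube2 <- array(1, dim = c(2, 2, 61))
  cube2[2, 2, c(1, 5)] <- NaN
  expect_error(hyperspectralScene(cube2, grid5, pixelsPerDegree = 10),
               "2 non-finite")
})
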