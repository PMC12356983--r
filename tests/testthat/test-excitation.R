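test_that("excitation integrates radiance x sensitivity by the rectangle rule", {
  mel <- sensitivityFunction("Mel")

  # zero radiance gives a zero map
  z <- computeExcitation(flat_scene(2, 2, value = 0), mel)
  expect_true(all(mapValues(z) == 0))

  # radiance in a single band: excitation = v * sens(lambda0) * 5
  cube <- array(0, dim = c(1, 1, 61))
  cube[1, 1, grid5 == 500] <- 7
  sc <- hyperspectralScene(cube, grid5, pixelsPerDegree = 10)
  got <- mapValues(computeExcitation(sc, mel))[1, 1]
  expect_equal(got, 7 * spectralValues(mel)[grid5 == 500] * 5)

  # random 3x3 cube against an explicit per-pixel loop
  sc3 <- random_scene(3, 3, seed = 11)
  got3 <- mapValues(computeExcitation(sc3, mel))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in seq_along(grid5))
      s <- s + sceneCube(sc3)[i, j, k] * spectralValues(mel)[k] * 5
    oracle[i, j] <- s
  }
  expect_equal(got3, oracle, tolerance = 1e-12)

  # reflectance scenes are refused
  expect_error(computeExcitation(flat_scene(1, 1, quantity = "reflectance"), mel),
               "not_radiance")
})

test_that("luminance matches an independent summation and favors 555 over 450 nm", {
  # EES radiance of 1 everywhere: Lum = 5 * sum(sensitivity)
  sc <- flat_scene(2, 2, value = 1)
  lum <- computeLuminance(sc)
  expect_identical(channel(lum), "Lum")
  oracle <- 0
  for (v in spectralValues(sensitivityFunction("Lum"))) oracle <- oracle + 5 * v
  expect_equal(mapValues(lum)[1, 1], oracle, tolerance = 1e-12)

  mono <- function(nm) {
    cube <- array(0, dim = c(1, 1, 61)); cube[1, 1, grid5 == nm] <- 1
    hyperspectralScene(cube, grid5, pixelsPerDegree = 10)
  }
  expect_gt(mapValues(computeLuminance(mono(555)))[1, 1],
            mapValues(computeLuminance(mono(450)))[1, 1])
})

test_that("ipRGC codifications apply the stated pixel-wise weights", {
  mk <- function(v) new("ChannelMap", values = matrix(v, 2, 2), channel = "L",
                        sceneId = "m", pixelsPerDegree = 10)
  zero <- mk(0); one <- mk(1)

  expect_true(all(mapValues(iprgc1(zero, zero, zero, zero)) == 0))
  # 0.667 + 0.333 + 0.69 - 0.12
  expect_equal(mapValues(iprgc1(one, one, one, one))[1, 1], 1.57)
  # L = M = 1, S = Mel = 0
  expect_equal(mapValues(iprgc1(one, one, zero, zero))[1, 1], 1.0)

  expect_true(all(mapValues(iprgc2(zero, zero, zero, zero)) == 0))
  # 1 + 1 + 1 - 1
  expect_equal(mapValues(iprgc2(one, one, one, one))[1, 1], 2.0)
  # subtractive S alone
  expect_equal(mapValues(iprgc2(zero, zero, one, zero))[1, 1], -1.0)

  bad <- new("ChannelMap", values = matrix(0, 3, 3), channel = "M",
             sceneId = "m", pixelsPerDegree = 10)
  expect_error(iprgc1(one, bad, zero, zero), "dimension_mismatch")
})

test_that("computeAllChannels is consistent with the standalone operations", {
  sc <- random_scene(4, 4, seed = 21)
  maps <- computeAllChannels(sc)
  expect_setequal(names(maps), c("L", "M", "S", "Mel", "Lum", "ipRGC1", "ipRGC2"))

  # zero scene: all maps zero
  z <- computeAllChannels(flat_scene(2, 2, value = 0))
  for (m in z) expect_true(all(mapValues(m) == 0))

  # every map matches its standalone operation
  for (ch in c("L", "M", "S", "Mel")) {
    expect_equal(mapValues(maps[[ch]]),
                 mapValues(computeExcitation(sc, sensitivityFunction(ch), ch)),
                 tolerance = 1e-12)
  }
  expect_equal(mapValues(maps$Lum), mapValues(computeLuminance(sc)),
               tolerance = 1e-12)

  # ipRGC maps are recomputable from the returned L/M/S/Mel
  expect_equal(mapValues(maps$ipRGC1),
               mapValues(iprgc1(maps$L, maps$M, maps$S, maps$Mel)),
               tolerance = 1e-12)
  expect_equal(mapValues(maps$ipRGC2),
               mapValues(iprgc2(maps$L, maps$M, maps$S, maps$Mel)),
               tolerance = 1e-12)
})

test_that("channel computation is linear in radiance", {
  sc <- random_scene(3, 3, seed = 5)
  scaled <- hyperspectralScene(sceneCube(sc) * 3.7, grid5,
                               pixelsPerDegree = 10, sceneId = "rand")
  m1 <- computeAllChannels(sc)
  m2 <- computeAllChannels(scaled)
  for (ch in names(m1))
    expect_equal(mapValues(m2[[ch]]), 3.7 * mapValues(m1[[ch]]),
                 tolerance = 1e-12)
})

test_that("equal-weight codification exceeds the pupillometry weighting on daylight scenes", {
  # ipRGC2 >= ipRGC1 pixel-wise in the generator's regime (S input modest)
  sc <- applyIlluminant(generateScene(sceneGeneratorSpec("natural", 32, 32,
                                                         seed = 9)),
                        equalEnergySPD())
  maps <- computeAllChannels(sc)
  expect_true(all(mapValues(maps$ipRGC2) >= mapValues(maps$ipRGC1)))
})
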