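test_that("degree conversions use the scene scale and 0.291 mm/deg", {
  expect_equal(degToPx(1.37, 30), 41.1)
  expect_equal(degToMm(1), 0.291)
  expect_error(degToPx(0, 30), "nonpositive_size")
  expect_error(degToMm(-1), "nonpositive_size")
})

test_that("raised-cosine weights normalize, respect symmetry and vanish at the rim", {
  # single pixel at the centre carries all the weight
  expect_equal(raisedCosineWeights(2, c(0, 0), rbind(c(0, 0))), 1)

  # weights over a disc sum to one
  px <- as.matrix(expand.grid(y = -3:3, x = -3:3))
  px <- px[sqrt(rowSums(px^2)) <= 3.5, ]
  w <- raisedCosineWeights(3.5, c(0, 0), px)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))

  # equidistant pixels get equal weights; rim weight is zero
  w2 <- raisedCosineWeights(2, c(0, 0), rbind(c(0, 1), c(1, 0), c(0, 2)))
  expect_equal(w2[1], w2[2])
  expect_equal(w2[3], 0)

  # pixel outside the radius is refused
  expect_error(raisedCosineWeights(1, c(0, 0), rbind(c(0, 2))),
               "pixel_outside_radius")

  # the literal printed profile differs from the raised-cosine window
  lit <- raisedCosineWeights(2, c(0, 0), rbind(c(0, 0), c(0, 1)),
                             window = "literal_cosine")
  rc <- raisedCosineWeights(2, c(0, 0), rbind(c(0, 0), c(0, 1)))
  expect_equal(lit, c(1, 0))           # cos(pi/2) = 0 at half radius
  expect_equal(rc, c(2 / 3, 1 / 3))    # (1 + cos(pi/2)) / 2 = 1/2, normalized
  # an all-rim literal window degenerates (zero denominator) and is refused
  expect_error(raisedCosineWeights(2, c(0, 0), rbind(c(0, 0), c(0, 2)),
                                   window = "literal_cosine"),
               "degenerate_window")
})

test_that("tiling places non-overlapping full circles deterministically", {
  # 100x100 image, 50-px field: floor(100/50)^2 = 4 patches
  lay <- tilePatches(c(100L, 100L), receptiveFieldSpec(5), 10)
  expect_equal(nPatches(lay), 4)

  # nothing fits in a 49x49 image
  expect_error(tilePatches(c(49L, 49L), receptiveFieldSpec(5), 10),
               "no_patch_fits")

  # patch count non-increasing in diameter
  counts <- vapply(c(1, 2, 3, 5), function(d)
    nPatches(tilePatches(c(100L, 100L), receptiveFieldSpec(d), 10)), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # per-patch weights sum to one
  for (w in patchWeights(lay)) expect_equal(sum(w), 1, tolerance = 1e-9)

  # deterministic
  lay2 <- tilePatches(c(100L, 100L), receptiveFieldSpec(5), 10)
  expect_identical(patchCenters(lay), patchCenters(lay2))

  # jittered placement is reproducible under a fixed seed
  j1 <- tilePatches(c(100L, 100L), receptiveFieldSpec(5), 10, jitterSeed = 3L)
  j2 <- tilePatches(c(100L, 100L), receptiveFieldSpec(5), 10, jitterSeed = 3L)
  expect_identical(patchCenters(j1), patchCenters(j2))
  expect_gte(nPatches(j1), 1)
})

test_that("local excitation is the windowed weighted mean", {
  lay <- tilePatches(c(40L, 40L), receptiveFieldSpec(2), 10, sceneId = "m")

  # constant map: every E_j equals the constant
  cm <- new("ChannelMap", values = matrix(3.25, 40, 40), channel = "Mel",
            sceneId = "m", pixelsPerDegree = 10)
  rec <- localExcitation(cm, lay)
  expect_equal(rec$local_value, rep(3.25, nPatches(lay)))

  # single-pixel impulse: E_j equals that pixel's weight
  j <- 1
  pix <- lay@pixels[[j]][5]
  imp <- matrix(0, 40, 40); imp[pix] <- 1
  im <- new("ChannelMap", values = imp, channel = "Mel", sceneId = "m",
            pixelsPerDegree = 10)
  expect_equal(localExcitation(im, lay)$local_value[j], lay@weights[[j]][5])

  # random map against the explicit loop
  rm_ <- random_map(40, 40, seed = 7)
  got <- localExcitation(rm_, lay)$local_value
  oracle <- numeric(nPatches(lay))
  for (k in seq_len(nPatches(lay))) {
    s <- 0
    for (i in seq_along(lay@pixels[[k]]))
      s <- s + lay@weights[[k]][i] * mapValues(rm_)[lay@pixels[[k]][i]]
    oracle[k] <- s
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # dimension mismatch is refused
  small <- random_map(10, 10, seed = 1)
  expect_error(localExcitation(small, lay), "dimension_mismatch")
})

test_that("local radiance is the unweighted in-circle mean of summed radiance", {
  sc <- flat_scene(40, 40, value = 2, id = "m")
  lay <- tilePatches(c(40L, 40L), receptiveFieldSpec(2), 10, sceneId = "m")
  rec <- localRadiance(sc, lay)
  expect_identical(unique(rec$channel), "Rad")
  # uniform scene: summed radiance = 2 * 61 bands * 5 nm
  expect_equal(rec$local_value, rep(2 * 61 * 5, nPatches(lay)))

  # two-valued patch: arithmetic mean, irrespective of the window
  cube <- array(0, dim = c(40, 40, 61))
  pix <- lay@pixels[[1]]
  half <- seq_len(floor(length(pix) / 2) * 2)  # even split
  a <- 1; b <- 3
  flat <- matrix(0, 40 * 40, 61)
  flat[pix[half[seq(1, length(half), 2)]], ] <- a
  flat[pix[half[seq(2, length(half), 2)]], ] <- b
  if (length(pix) %% 2 == 1) flat[pix[length(pix)], ] <- (a + b) / 2
  sc2 <- hyperspectralScene(array(flat, dim = c(40, 40, 61)), grid5,
                            pixelsPerDegree = 10, sceneId = "m")
  expect_equal(localRadiance(sc2, lay)$local_value[1],
               (a + b) / 2 * 61 * 5, tolerance = 1e-9)

  # agreement with an explicit mean over the in-circle pixels
  sc3 <- random_scene(40, 40, seed = 13, id = "m")
  total <- apply(sceneCube(sc3), c(1, 2), function(v) sum(v) * 5)
  got <- localRadiance(sc3, lay)$local_value
  oracle <- vapply(lay@pixels, function(p) mean(total[p]), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("windowing cannot change a constant and pooling shrinks patch variance", {
  # same E_j for any field size and window mode on a constant map
  cm <- new("ChannelMap", values = matrix(1.5, 120, 120), channel = "Lum",
            sceneId = "m", pixelsPerDegree = 20)
  for (d in c(0.36, 1.37, 2.4)) for (wm in c("raised_cosine", "literal_cosine")) {
    lay <- tilePatches(c(120L, 120L), receptiveFieldSpec(d, wm), 20,
                       sceneId = "m")
    expect_equal(localExcitation(cm, lay)$local_value,
                 rep(1.5, nPatches(lay)), tolerance = 1e-9,
                 label = sprintf("d=%g %s", d, wm))
  }

  # on spatially white maps, larger windows flatten local variation
  withr::with_seed(42, {
    v_small <- c(); v_large <- c()
    for (i in 1:8) {
      m <- random_map(120, 120, seed = i, ppd = 20)
      lay_s <- tilePatches(c(120L, 120L), receptiveFieldSpec(1.37), 20,
                           sceneId = "m")
      lay_l <- tilePatches(c(120L, 120L), receptiveFieldSpec(2.4), 20,
                           sceneId = "m")
      v_small <- c(v_small, var(localExcitation(m, lay_s)$local_value))
      v_large <- c(v_large, var(localExcitation(m, lay_l)$local_value))
    }
    expect_lt(mean(v_large), mean(v_small))
  })
})
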