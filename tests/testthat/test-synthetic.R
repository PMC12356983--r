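test_that("scene generator honours its mean, determinism and degenerate cases", {
  # zero spatial sd: uniform cube at the requested mean
  sc0 <- generateScene(sceneGeneratorSpec("natural", 16, 16,
                                          meanReflectance = 0.3,
                                          reflectanceSd = 0, seed = 1))
  expect_true(all(abs(sceneCube(sc0) - 0.3) < 1e-12))

  # same seed twice: bit-identical; different seeds differ
  a <- generateScene(sceneGeneratorSpec("natural", 24, 24, seed = 5))
  b <- generateScene(sceneGeneratorSpec("natural", 24, 24, seed = 5))
  c_ <- generateScene(sceneGeneratorSpec("natural", 24, 24, seed = 6))
  expect_identical(sceneCube(a), sceneCube(b))
  expect_false(identical(sceneCube(a), sceneCube(c_)))

  # realized mean within 10% of the request
  for (env in c("natural", "human_made")) {
    sc <- generateScene(sceneGeneratorSpec(env, 48, 48, seed = 2))
    target <- if (env == "natural") 0.2 else 0.5
    expect_lt(abs(mean(sceneCube(sc)) - target), 0.1 * target)
  }

  # infeasible mean/sd after clipping is refused
  expect_error(generateScene(sceneGeneratorSpec("natural", 24, 24,
                                                meanReflectance = 0.97,
                                                reflectanceSd = 0.9, seed = 3)),
               "infeasible_reflectance")

  # white-noise mode produces spatially uncorrelated structure
  w <- generateScene(sceneGeneratorSpec("natural", 48, 48,
                                        spatialCorrelation = "white",
                                        seed = 4))
  expect_s4_class(w, "HyperspectralScene")
  expect_identical(quantity(w), "reflectance")
})

test_that("silent-substitution solution isolates the target channel", {
  # zero contrast: both spectra equal
  s0 <- solveSilentSubstitution(silentSubstitutionSpec("Mel", 0))
  expect_equal(spectralValues(s0$background), spectralValues(s0$modulated),
               tolerance = 1e-12)

  # melanopsin target at 0.3: non-target channels silent to 1e-8 relative
  sol <- solveSilentSubstitution(silentSubstitutionSpec("Mel", 0.3))
  e <- sol$excitation
  for (ch in c("L", "M", "S", "Lum")) {
    rel <- abs(e["mod", ch] - e["bg", ch]) / abs(e["bg", ch])
    expect_lt(rel, 1e-8, label = paste("silenced", ch))
  }
  expect_equal(sol$achievedContrast, 0.3, tolerance = 1e-9)

  # independent verification: integrate the solved spectra against the
  # sensitivity tables directly
  for (ch in c("L", "M", "S", "Mel")) {
    s <- spectralValues(sensitivityFunction(ch))
    e_bg <- sum(spectralValues(sol$background) * s * 5)
    e_mod <- sum(spectralValues(sol$modulated) * s * 5)
    if (ch == "Mel") {
      expect_equal((e_mod - e_bg) / (e_mod + e_bg), 0.3, tolerance = 1e-8)
    } else {
      expect_lt(abs(e_mod - e_bg) / e_bg, 1e-8)
    }
  }

  # independent linear-solve oracle: the minimum-norm weight change for the
  # (L, M, S, Mel) system, built from scratch, matches the solver's
  prim <- gaussianPrimaries()
  P <- vapply(prim, spectralValues, numeric(61))
  S <- vapply(c("L", "M", "S", "Mel"), function(ch)
    spectralValues(sensitivityFunction(ch)), numeric(61))
  R <- t(S) %*% P * 5
  w_lo <- sol$weights["bg", ]; w_hi <- sol$weights["mod", ]
  w_ctr <- (w_lo + w_hi) / 2
  e_ctr <- as.vector(R %*% w_ctr)
  dw_oracle <- as.vector(t(R) %*% solve(R %*% t(R),
                                        c(0, 0, 0, 0.3 * e_ctr[4])))
  expect_equal((w_hi - w_lo) / 2, dw_oracle, tolerance = 1e-9)

  # rank-deficient primaries are refused with the channel named
  dup <- gaussianPrimaries(peaksNm = c(560, 560, 560, 560))
  expect_error(solveSilentSubstitution(
    silentSubstitutionSpec("Mel", 0.1, primaries = dup)),
    "rank_deficient_primaries")
})

test_that("validation scenes confine contrast to the intended channel", {
  # melanopsin-only scene through the full pipeline
  r <- renderValidationScene(silentSubstitutionSpec("Mel", 0.3), 128, 128, 32)
  vc <- validationContrasts(r, receptiveFieldSpec(1.37))
  expect_equal(vc[["Mel"]], 0.3, tolerance = 1e-6)
  for (ch in c("L", "M", "S", "Lum"))
    expect_lt(vc[[ch]], 1e-6)

  # luminance-only scene: the converse (S and Mel silent)
  r2 <- renderValidationScene(silentSubstitutionSpec("Lum", 0.3), 128, 128, 32)
  vc2 <- validationContrasts(r2, receptiveFieldSpec(1.37))
  expect_equal(vc2[["Lum"]], 0.3, tolerance = 1e-6)
  expect_lt(vc2[["S"]], 1e-6)
  expect_lt(vc2[["Mel"]], 1e-6)

  # zero-contrast spec: every channel flat
  r0 <- renderValidationScene(silentSubstitutionSpec("Mel", 0), 96, 96, 16)
  vc0 <- validationContrasts(r0, receptiveFieldSpec(1.37))
  expect_true(all(vc0 < 1e-9))

  # checkerboard layout carries the same isolation
  rc <- renderValidationScene(silentSubstitutionSpec("Mel", 0.2,
                                                     layout = "checkerboard"),
                              128, 128, 32)
  vcc <- validationContrasts(rc, receptiveFieldSpec(1.37))
  expect_equal(vcc[["Mel"]], 0.2, tolerance = 1e-6)
  expect_lt(vcc[["Lum"]], 1e-6)

  # a field larger than a region is refused
  expect_error(validationContrasts(r, receptiveFieldSpec(4)),
               "field_exceeds_region")
})

test_that("generator defaults recover the environment ordering end to end", {
  # small-scale version of the natural vs human-made recovery: higher
  # human-made melanopsin at matched contrast statistics
  vals <- list()
  for (env in c("natural", "human_made")) {
    per_scene <- c()
    for (s in 1:6) {
      sc <- applyIlluminant(generateScene(
        sceneGeneratorSpec(env, 90, 90, seed = 300 + s +
                             ifelse(env == "natural", 0, 50))),
        equalEnergySPD())
      maps <- computeAllChannels(sc)
      lay <- tilePatches(dim(mapValues(maps$Mel)), receptiveFieldSpec(1.37),
                         32, sceneId = sceneId(sc))
      per_scene <- c(per_scene, localExcitation(maps$Mel, lay)$local_value)
    }
    vals[[env]] <- per_scene
  }
  cmp <- compareGroups(vals$natural, vals$human_made, transform = "log")
  tt <- cmp[cmp$kind == "t_independent", ]
  expect_lt(tt$statistic, 0)          # human-made higher
  expect_lt(tt$p_value, 0.001)
  expect_gt(median(vals$human_made) / median(vals$natural), 1.5)
})
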