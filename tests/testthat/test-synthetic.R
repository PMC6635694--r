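# Synthetic bone generator: contracts, determinism, damage operator.

test_that("generated bones are watertight with consistent ground truth", {
  b <- fixtureBone()
  expect_true(isWatertight(b$mesh))
  expect_equal(boundaryEdgeCount(b$mesh), 0L)
  expect_gt(volume(b$mesh), 0)
  expect_relative(b$truth@volume, volume(b$mesh), 0.01)
  expect_equal(unname(b$truth@grooveCD), c(8, 8))
  expect_error(boneParams(grooveRadiusMedial = 11), "head radius")
  expect_error(boneParams(meshResolution = 1), "meshResolution")
})

test_that("generation is deterministic for identical parameters", {
  p <- boneParams(meshResolution = 2, bumpAmplitude = 0.08, seed = 5)
  b1 <- makeBone(p)
  b2 <- makeBone(p)
  expect_identical(vertices(b1$mesh), vertices(b2$mesh))
  expect_identical(faces(b1$mesh), faces(b2$mesh))
  # a different seed changes the bump field
  b3 <- makeBone(boneParams(meshResolution = 2, bumpAmplitude = 0.08,
                            seed = 6))
  expect_false(isTRUE(all.equal(volume(b1$mesh), volume(b3$mesh),
                                tolerance = 1e-12)))
})

test_that("overlapping grooves are rejected", {
  expect_error(makeBone(boneParams(grooveRadiusMedial = 8,
                                   grooveRadiusLateral = 8,
                                   groovePolarAngle = 15,
                                   meshResolution = 2)),
               "overlap")
})

test_that("the damage operator removes the requested volume fraction", {
  dmg <- fixtureDamaged() # fraction 0.2
  expect_true(isWatertight(dmg$mesh))
  expect_gte(dmg$removedFraction, 0.18)
  expect_lte(dmg$removedFraction, 0.22)
  b <- fixtureBone()$mesh
  expect_relative(volume(dmg$mesh), volume(b) * (1 - dmg$removedFraction),
                  0.02)
  expect_error(damageBone(b, fraction = 0.7), "fraction")
  expect_error(damageBone(b, fraction = 0), "fraction")
})

test_that("damage is deterministic and vanishes in the small-fraction limit", {
  b <- fixtureBone()$mesh
  d1 <- damageBone(b, "sphere_bite", fraction = 0.05, seed = 11, pitch = 0.4)
  d2 <- damageBone(b, "sphere_bite", fraction = 0.05, seed = 11, pitch = 0.4)
  expect_identical(vertices(d1$mesh), vertices(d2$mesh))
  small <- damageBone(b, "plane_clip", fraction = 0.01, seed = 2, pitch = 0.4)
  expect_relative(volume(small$mesh), volume(b), 0.02)
})

test_that("three-bone subjects honour the configured proportions", {
  sub <- makeSubject(params = boneParams(meshResolution = 2),
                     phalanxVolumeRatio = 1.83)
  ratio <- volume(sub$proximal) / volume(sub$distal)
  expect_relative(ratio, 1.83, 0.05)
  sub2 <- makeSubject(scale = 2, params = boneParams(meshResolution = 2),
                      phalanxVolumeRatio = 1.83)
  expect_relative(volume(sub2$metatarsal), 8 * volume(sub$metatarsal), 1e-6)
  set <- standardizeSubject(sub$metatarsal, sub$proximal, sub$distal)
  rec <- measureSubject(set)
  expect_equal(rec$length[rec$bone == "metatarsal"], 100, tolerance = 1e-6)
  expect_error(makeSubject(scale = -1), "positive")
})
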