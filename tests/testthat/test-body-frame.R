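# Principal-axes body frames, alignment, extents, standardization.

test_that("the long axis of an elongated box is its longest edge", {
  f <- principalFrame(meshBox(10, 4, 2))
  expect_gt(abs(frameAxes(f)[1, 1]), 1 - 1e-9)
  expect_gt(abs(frameAxes(f)[2, 2]), 1 - 1e-9)
  expect_equal(det(frameAxes(f)), 1, tolerance = 1e-9)
  # orthonormality
  expect_equal(frameAxes(f) %*% t(frameAxes(f)), diag(3), tolerance = 1e-9)
})

test_that("a known rotation is recovered by the principal frame", {
  b <- fixtureBone()$mesh
  f0 <- principalFrame(b)
  R <- BoneFrame:::rotationAboutAxis(c(2, -1, 0.5), 47)
  f1 <- principalFrame(rotateMesh(b, R))
  for (i in 1:3)
    expect_gt(abs(sum((R %*% frameAxes(f0)[i, ]) * frameAxes(f1)[i, ])),
              1 - 1e-6)
})

test_that("a sphere triggers the degeneracy fallback with a warning", {
  expect_warning(f <- principalFrame(meshIcosphere(1, 3)), "degenerate")
  expect_equal(frameAxes(f), diag(3))
  expect_true(f@degenerate)
})

test_that("toBodyFrame is idempotent and centres the COM", {
  b <- fixtureBone()$mesh
  m1 <- toBodyFrame(b)
  expect_lt(max(abs(centerOfMass(massProperties(m1)))), 1e-6)
  m2 <- toBodyFrame(m1)
  expect_lt(max(abs(vertices(m2) - vertices(m1))), 1e-6)
  # frame axes diagonalize the inertia tensor
  I1 <- inertiaTensor(massProperties(m1))
  offdiag <- abs(I1[upper.tri(I1)])
  expect_lt(max(offdiag), 1e-6 * max(abs(I1)))
})

test_that("body-frame alignment absorbs arbitrary rigid motions", {
  b <- fixtureBone()$mesh
  moved <- translateMesh(rotateMesh(b, axis = c(1, 1, 2), angle = 71),
                         c(12, -5, 30))
  e0 <- boneExtents(toBodyFrame(b))
  e1 <- boneExtents(toBodyFrame(moved))
  expect_equal(e1, e0, tolerance = 1e-6)
  # symmetric-difference volume of the two aligned copies is tiny
  iou <- voxelIoU(toBodyFrame(b), toBodyFrame(moved), pitch = 0.5)
  expect_gt(iou, 0.995)
})

test_that("extents follow the long/second/third axis order and scaling", {
  e <- boneExtents(toBodyFrame(meshBox(10, 4, 2)))
  expect_equal(unname(e), c(10, 4, 2), tolerance = 1e-9)
  e2 <- boneExtents(scaleMesh(toBodyFrame(meshBox(10, 4, 2)), 2))
  expect_equal(unname(e2), c(20, 8, 4), tolerance = 1e-9)
})

test_that("standardization forces metatarsal length 100 and scales set-wide", {
  met <- meshBox(50, 8, 6)
  pro <- meshBox(25, 7, 5)
  dis <- meshBox(15, 6, 5)
  set <- standardizeSubject(met, pro, dis)
  expect_equal(set@scale, 2, tolerance = 1e-9)
  expect_equal(unname(boneExtents(set@metatarsal)["length"]), 100,
               tolerance = 1e-6)
  # one uniform scale for all bones: volumes scale by s^3
  expect_equal(volume(set@proximal), (25 * 7 * 5) * 8, tolerance = 1e-6)
  rec <- measureSubject(set)
  expect_equal(rec$length[rec$bone == "metatarsal"], 100, tolerance = 1e-6)
})

test_that("standardization preserves dimensionless shape ratios", {
  sub <- makeSubject(params = boneParams(meshResolution = 2))
  set1 <- standardizeSubject(sub$metatarsal, sub$proximal, sub$distal)
  # pre-scaling the whole subject must not change the standardized record
  set2 <- standardizeSubject(scaleMesh(sub$metatarsal, 2),
                             scaleMesh(sub$proximal, 2),
                             scaleMesh(sub$distal, 2))
  r1 <- measureSubject(set1)
  r2 <- measureSubject(set2)
  for (col in c("length", "width", "height", "surface_area", "volume"))
    expect_equal(r2[[col]], r1[[col]], tolerance = 1e-6)
  # width/length ratio unchanged by standardization itself
  w0 <- boneExtents(toBodyFrame(sub$metatarsal))
  w1 <- boneExtents(set1@metatarsal)
  expect_equal(w1[["width"]] / w1[["length"]], w0[["width"]] / w0[["length"]],
               tolerance = 1e-9)
})
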