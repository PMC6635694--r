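# Overlap, defect detection, completion, scale restoration.

test_that("a bone overlapped with a rotated copy of itself aligns", {
  b <- fixtureBone()$mesh
  moved <- translateMesh(rotateMesh(b, axis = c(0.3, 1, -2), angle = 38),
                         c(10, -4, 2))
  ov <- overlapInBodyFrames(b, moved)
  expect_gt(ov$iou, 0.98)
  # donor = damaged: essentially the identity once aligned
  ov2 <- overlapInBodyFrames(b, b)
  expect_gt(ov2$iou, 0.99)
  expect_equal(dim(ov2$transform), c(4L, 4L))
})

test_that("defect detection is empty for an undamaged bone", {
  b <- fixtureBone()$mesh
  ov <- overlapInBodyFrames(b, b)
  expect_message(patch <- detectDefect(ov$damaged, ov$donor), "no defect")
  expect_true(patch$empty)
  expect_equal(patch$area, 0)
  expect_error(detectDefect(ov$damaged, ov$donor, distanceThreshold = 0),
               "positive")
  far <- translateMesh(b, c(500, 0, 0))
  expect_error(detectDefect(ov$damaged, far), "no overlap")
})

test_that("the detected patch matches the clipped-away donor area", {
  b <- fixtureBone()$mesh
  dmg <- fixtureDamaged()
  ov <- overlapInBodyFrames(dmg$mesh, b)
  patch <- detectDefect(ov$damaged, ov$donor)
  expect_false(patch$empty)
  # oracle: donor faces beyond the cut plane (cut known to the generator,
  # expressed in the damaged bone's frame via the overlap transform)
  fd <- principalFrame(dmg$mesh)
  donor_truth <- toBodyFrame(b, fd)
  V <- vertices(donor_truth)
  F <- faces(donor_truth)
  ctr <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  # map the construction-frame cut plane into the damaged body frame
  n <- as.vector(frameAxes(fd) %*% dmg$cut$direction)
  off <- dmg$cut$offset - sum(dmg$cut$direction * frameOrigin(fd))
  beyond <- as.vector(ctr %*% n) > off
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  oracle_area <- sum(sqrt(rowSums(cr[beyond, ]^2))) / 2
  expect_relative(patch$area, oracle_area, 0.25)
})

test_that("completion with an empty patch is a volume-preserving no-op", {
  b <- fixtureBone()$mesh
  ov <- overlapInBodyFrames(b, b)
  suppressMessages(patch <- detectDefect(ov$damaged, ov$donor))
  cm <- completeMesh(ov$damaged, ov$donor, patch, pitch = 0.35)
  expect_true(isWatertight(cm$completed))
  expect_relative(volume(cm$completed), volume(b), 0.01)
  expect_equal(cm$report@boundaryLoops, 0L)
})

test_that("a clipped bone completed from its intact twin is recovered", {
  b <- fixtureBone()$mesh
  dmg <- fixtureDamaged()
  rec <- reconstructBone(dmg$mesh, b, pitch = 0.25, neighborhood = 1.5)
  expect_true(isWatertight(rec$completed))
  expect_equal(boundaryEdgeCount(rec$completed), 0L)
  expect_relative(volume(rec$completed), volume(b), 0.02)
  e0 <- boneExtents(toBodyFrame(b))
  e1 <- boneExtents(toBodyFrame(rec$completed))
  expect_relative(e1, e0, 0.02)
  # reconstruction never removes damaged material: every interior
  # damaged voxel (surface-jitter layer eroded away) stays inside
  dam <- rec$overlap$damaged
  lo <- pmin(apply(vertices(dam), 2, min), apply(vertices(rec$completed), 2, min))
  hi <- pmax(apply(vertices(dam), 2, max), apply(vertices(rec$completed), 2, max))
  bb <- rbind(lo - 1, hi + 1)
  gd <- voxelizeMesh(dam, 0.5, bbox = bb)
  gc <- voxelizeMesh(rec$completed, 0.5, bbox = bb)
  occ <- gd$occ
  n <- dim(occ)
  core <- occ
  core[] <- FALSE
  core[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)] <-
    occ[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)] &
    occ[1:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)] &
    occ[3:n[1], 2:(n[2] - 1), 2:(n[3] - 1)] &
    occ[2:(n[1] - 1), 1:(n[2] - 2), 2:(n[3] - 1)] &
    occ[2:(n[1] - 1), 3:n[2], 2:(n[3] - 1)] &
    occ[2:(n[1] - 1), 2:(n[2] - 1), 1:(n[3] - 2)] &
    occ[2:(n[1] - 1), 2:(n[2] - 1), 3:n[3]]
  covered <- sum(core & gc$occ) / sum(core)
  expect_gt(covered, 0.995)
})

test_that("restoreScale inverts standardization exactly", {
  b <- fixtureBone()$mesh
  up <- scaleMesh(b, 2)
  back <- restoreScale(up, 2)
  expect_lt(max(abs(vertices(back) - vertices(b))), 1e-9)
  expect_relative(volume(restoreScale(b, 0.5)), volume(b) * 8, 1e-9)
  expect_error(restoreScale(b, 0), "positive")
})

test_that("standardize-complete-restore round-trips an intact bone", {
  b <- fixtureBone()$mesh
  set <- standardizeSubject(b, scaleMesh(b, 0.5), scaleMesh(b, 0.4))
  ov <- overlapInBodyFrames(set@metatarsal, set@metatarsal)
  suppressMessages(patch <- detectDefect(ov$damaged, ov$donor))
  cm <- completeMesh(ov$damaged, ov$donor, patch, pitch = 0.35)
  restored <- restoreScale(cm$completed, set@scale)
  expect_relative(volume(restored), volume(b), 0.02)
})
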