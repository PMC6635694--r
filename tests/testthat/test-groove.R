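# Cross-sections, groove arcs, circle fits, CD scans, parallelism.

test_that("sections reproduce analytic areas", {
  cyl <- meshCylinder(4, 20, 96)
  s <- sectionAt(cyl, axis = c(1, 0, 0), angle = 0, pivot = c(0, 0, 0),
                 baseNormal = c(0, 0, 1))
  expect_equal(length(contours(s)), 1L)
  expect_relative(sectionArea(s), 16 * pi, 0.01)
  cube <- meshBox(1, 1, 1)
  s2 <- sectionAt(cube, axis = c(0, 0, 1), angle = 0)
  expect_equal(sectionArea(s2), 1, tolerance = 1e-9)
  expect_error(sectionAt(cube, axis = c(0, 0, 1), angle = 0, offset = 5),
               "empty section")
})

test_that("the base level maximizes the section area", {
  # elliptical cross-section: the maximal plane contains the major axis
  ell <- meshCylinder(1, 30, 96)
  ell@vertices <- ell@vertices %*% diag(c(4, 2, 1)) # radii 4 x 2, axis z
  bl <- suppressWarnings(findBaseLevel(ell, axis = c(0, 0, 1), step = 2,
                                       baseNormal = c(0, 1, 0)))
  # normal starts along y; area is maximal when the plane contains x
  expect_true(min(abs(bl$angle - c(0, 180))) <= 2)
  expect_relative(bl$area, 2 * 4 * 30, 0.02)
  # rectangular cross-section: the diagonal chord wins
  bl2 <- suppressWarnings(findBaseLevel(meshBox(10, 4, 2),
                                        axis = c(1, 0, 0), step = 1))
  diag_angle <- atan2(2, 4) * 180 / pi
  expect_lt(min(abs(bl2$angle - c(diag_angle, 180 - diag_angle))), 1.5)
  expect_relative(bl2$area, 10 * sqrt(4^2 + 2^2), 0.02)
  expect_warning(findBaseLevel(meshIcosphere(1, 2), axis = c(0, 0, 1),
                               step = 30), "tie")
  expect_error(findBaseLevel(meshBox(1, 1, 1), axis = c(1, 0, 0),
                             step = 0), "positive")
})

test_that("groove arcs are found at the generator's positions", {
  sec <- fixtureHeadSection()
  arcs <- detectGrooveArcs(sec)
  # groove axes sit plantar at (u, v) = (+/- d sin(alpha), -d cos(alpha)),
  # alpha = 35 deg: the fitted circle centres recover them
  d <- 10 + 0.2 * 4
  cm <- fitCircle(arcs$medial$points)$center
  cl <- fitCircle(arcs$lateral$points)$center
  expect_lt(max(abs(cm - d * c(-sin(35 * pi / 180), -cos(35 * pi / 180)))),
            0.5)
  expect_lt(max(abs(cl - d * c(sin(35 * pi / 180), -cos(35 * pi / 180)))),
            0.5)
  expect_lt(arcs$medial$centroid2d[2], 0) # plantar
  expect_gte(nrow(arcs$medial$points), 5L)
})

test_that("a convex contour raises groove-not-found", {
  cyl <- meshCylinder(4, 20, 64)
  s <- sectionAt(cyl, axis = c(1, 0, 0), angle = 0, baseNormal = c(0, 0, 1))
  expect_error(detectGrooveArcs(s), "groove not found")
})

test_that("mirroring the mesh swaps the medial and lateral labels", {
  p <- boneParams(meshResolution = 2, grooveRadiusMedial = 3,
                  grooveRadiusLateral = 5)
  b <- makeBone(p)$mesh
  sec <- sectionAt(b, axis = c(0, 0, 1), angle = 0, pivot = c(6, 0, 0),
                   baseNormal = c(1, 0, 0))
  arcs <- detectGrooveArcs(sec)
  rm <- fitCircle(arcs$medial$points)$radius
  rl <- fitCircle(arcs$lateral$points)$radius
  expect_lt(abs(rm - 3), 0.3)
  expect_lt(abs(rl - 5), 0.5)
  # mirror across the x-z plane (y -> -y), rewinding faces
  V <- vertices(b) %*% diag(c(1, -1, 1))
  mir <- boneMesh(V, faces(b)[, c(1, 3, 2)], repair = FALSE)
  sec2 <- sectionAt(mir, axis = c(0, 0, 1), angle = 0, pivot = c(6, 0, 0),
                    baseNormal = c(1, 0, 0))
  arcs2 <- detectGrooveArcs(sec2)
  expect_lt(abs(fitCircle(arcs2$medial$points)$radius - 5), 0.5)
  expect_lt(abs(fitCircle(arcs2$lateral$points)$radius - 3), 0.3)
  # the flipSides override restores the original labelling
  arcs3 <- detectGrooveArcs(sec2, flipSides = TRUE)
  expect_lt(abs(fitCircle(arcs3$medial$points)$radius - 3), 0.3)
})

test_that("circle fits are exact on exact data and robust to noise", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  f <- fitCircle(cbind(2 + 5 * cos(th), -1 + 5 * sin(th)))
  expect_equal(f$radius, 5, tolerance = 1e-9)
  expect_equal(f$center, c(2, -1), tolerance = 1e-9)
  expect_lt(f$rmsResidual, 1e-9)
  # three points: the circumscribed circle
  f3 <- fitCircle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(f3$radius, 1, tolerance = 1e-12)
  expect_equal(f3$center, c(0, 0), tolerance = 1e-12)
  expect_error(fitCircle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fitCircle(rbind(c(0, 0), c(1, 1))), "3 points")
  # noisy quarter arc, r = 10, sigma = 0.05 mm: within 2% on every seed
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    a <- seq(0, pi / 2, length.out = 100)
    pts <- cbind(10 * cos(a), 10 * sin(a)) + matrix(rnorm(200, 0, 0.05),
                                                   ncol = 2)
    abs(fitCircle(pts)$radius / 10 - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("the CD scan recovers a groove diameter and skew angle", {
  b <- fixtureBone()$mesh # grooves r = 4, skew 0
  fit <- scanGrooveCD(b, "medial", angleRange = 4)
  expect_relative(curvatureDiameter(fit), 8, 0.03)
  expect_lt(abs(rotationAngle(fit)), 0.5)
  # minimal CD is minimal over the whole trace (definitional)
  expect_true(all(fit@trace$cd >= curvatureDiameter(fit) - 1e-9,
                  na.rm = TRUE))
  expect_error(scanGrooveCD(b, "medial", step = 0), "positive")
  expect_error(scanGrooveCD(b, "medial", angleRange = -1), "positive")
})

test_that("parallelism verdicts follow the angle-difference rule", {
  gm <- function(a) grooveFit("medial", a, 10)
  gl <- function(a) grooveFit("lateral", a, 12)
  expect_equal(verdict(parallelismTest(gm(-2), gl(-2))), "parallel")
  expect_equal(verdict(parallelismTest(gm(-1), gl(-3))), "dis_parallel")
  # exactly at tolerance counts as parallel
  expect_equal(verdict(parallelismTest(gm(-1), gl(-1.5), tolerance = 0.5)),
               "parallel")
  expect_equal(angleDifference(parallelismTest(gm(-1), gl(-3))), 2)
  expect_error(parallelismTest(gl(-1), gm(-1)), "medial and lateral")
  # mismatched scan settings are refused
  s1 <- grooveFit("medial", 0, 10, settings = list(scan = "min_cd",
    step = 0.5, angleRange = 10, axis = c(0, 0, 1),
    baseNormal = c(1, 0, 0), baseAngle = 0))
  s2 <- grooveFit("lateral", 0, 10, settings = list(scan = "min_cd",
    step = 1, angleRange = 10, axis = c(0, 0, 1),
    baseNormal = c(1, 0, 0), baseAngle = 0))
  expect_error(parallelismTest(s1, s2), "mismatched")
})

test_that("scan results survive a rigid pre-rotation of the mesh", {
  b <- toBodyFrame(fixtureBone()$mesh)
  fit0m <- scanGrooveCD(b, "medial", angleRange = 3)
  fit0l <- scanGrooveCD(b, "lateral", angleRange = 3)
  rot <- translateMesh(rotateMesh(b, axis = c(1, -2, 0.7), angle = 53),
                       c(4, 9, -6))
  aligned <- toBodyFrame(rot)
  fits <- lapply(c("medial", "lateral"), function(sd)
    scanGrooveCD(aligned, side = sd, angleRange = 3))
  cds0 <- sort(c(curvatureDiameter(fit0m), curvatureDiameter(fit0l)))
  cds1 <- sort(vapply(fits, curvatureDiameter, numeric(1)))
  expect_relative(cds1, cds0, 0.02)
  # angle difference (parallelism input) is rotation invariant; each
  # angle is localized to one half-step, so allow two
  d0 <- abs(rotationAngle(fit0m) - rotationAngle(fit0l))
  d1 <- abs(rotationAngle(fits[[1]]) - rotationAngle(fits[[2]]))
  expect_lt(abs(d1 - d0), 1.0)
})
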