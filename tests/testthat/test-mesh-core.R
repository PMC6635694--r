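# Mass properties, primitives and mesh validation.

test_that("unit cube has closed-form mass properties", {
  cube <- meshBox(1, 1, 1, center = c(0.5, 0.5, 0.5))
  expect_equal(nrow(vertices(cube)), 8L)
  expect_equal(nrow(faces(cube)), 12L)
  expect_true(isWatertight(cube))
  mp <- massProperties(cube)
  expect_equal(volume(mp), 1, tolerance = 1e-12)
  expect_equal(surfaceArea(mp), 6, tolerance = 1e-12)
  expect_equal(centerOfMass(mp), c(0.5, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(inertiaTensor(mp)), diag(1 / 6, 3), tolerance = 1e-12)
})

test_that("box inertia matches the analytic principal moments", {
  mp <- massProperties(meshBox(10, 4, 2))
  v <- volume(mp)
  expect_equal(v, 80, tolerance = 1e-12)
  expect_equal(principalMoments(mp) / v,
               sort(c(4^2 + 2^2, 10^2 + 2^2, 10^2 + 4^2) / 12),
               tolerance = 1e-12)
})

test_that("icosphere and cylinder volumes approach analytic limits", {
  ico <- meshIcosphere(1, 4)
  expect_true(isWatertight(ico))
  expect_relative(volume(ico), 4 * pi / 3, 0.005)
  cyl <- meshCylinder(4, 20, 96)
  expect_true(isWatertight(cyl))
  expect_relative(volume(cyl), pi * 16 * 20, 0.01)
  expect_error(meshBox(-1, 1, 1), "positive")
  expect_error(meshCylinder(0, 5), "positive")
})

test_that("invalid meshes are rejected and degenerate faces dropped", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(boneMesh(V, rbind(c(1, 2, 4))), "missing vertex")
  expect_error(boneMesh(V[0, ], matrix(0L, 0, 3)), "empty")
  # a degenerate (repeated-index) face is dropped with a message
  cube <- meshBox(1, 1, 1)
  expect_message(
    m <- boneMesh(vertices(cube), rbind(faces(cube), c(1, 1, 2))),
    "degenerate")
  expect_equal(nrow(faces(m)), 12L)
})

test_that("volume/COM are invariant to reordering, rotation, translation", {
  b <- meshBox(3, 2, 1)
  mp0 <- massProperties(b)
  # vertex re-ordering
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  inv <- order(perm)
  m2 <- boneMesh(vertices(b)[perm, ],
                 matrix(inv[faces(b)], ncol = 3), repair = FALSE)
  mp2 <- massProperties(m2)
  expect_equal(volume(mp2), volume(mp0), tolerance = 1e-9)
  expect_equal(centerOfMass(mp2), centerOfMass(mp0), tolerance = 1e-9)
  # rigid rotation
  R <- rotationAboutAxisForTest(c(1, 2, 3), 33)
  m3 <- rotateMesh(b, R)
  expect_equal(volume(m3), volume(mp0), tolerance = 1e-9)
  # translation equivariance of the COM
  m4 <- translateMesh(b, c(5, -2, 7))
  expect_equal(centerOfMass(massProperties(m4)),
               centerOfMass(mp0) + c(5, -2, 7), tolerance = 1e-9)
})


test_that("uniform scaling scales area, volume and inertia as s^2, s^3, s^5", {
  b <- fixtureBone()$mesh
  mp0 <- massProperties(b)
  s <- 1.7
  mp1 <- massProperties(scaleMesh(b, s))
  expect_relative(surfaceArea(mp1), surfaceArea(mp0) * s^2, 1e-9)
  expect_relative(volume(mp1), volume(mp0) * s^3, 1e-9)
  expect_relative(principalMoments(mp1), principalMoments(mp0) * s^5, 1e-9)
})

test_that("surface-integral mass properties agree with the voxel oracle", {
  b <- fixtureBone()
  mp <- massProperties(b$mesh)
  vo <- voxelMassProperties(mesh = b$mesh, pitch = 0.25)
  expect_relative(vo$volume, volume(mp), 0.01)
  expect_lt(max(abs(vo$com - centerOfMass(mp))), 0.05)
  expect_lt(norm(vo$inertia - inertiaTensor(mp), "F") /
              norm(inertiaTensor(mp), "F"), 0.01)
  # the generator's own ground truth is consistent too
  expect_relative(b$truth@volume, volume(mp), 0.01)
})

test_that("open meshes are detected and refused by massProperties", {
  cube <- meshBox(1, 1, 1)
  open <- boneMesh(vertices(cube), faces(cube)[-1, ], repair = FALSE)
  expect_false(isWatertight(open))
  expect_equal(boundaryEdgeCount(open), 3L)
  expect_error(massProperties(open), "watertight")
})
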