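# STL / PLY / OBJ readers and writers.

test_that("the same geometry round-trips through every format", {
  m <- meshCylinder(3, 10, 32)
  for (fmt in c("stl", "stl_binary", "ply", "obj")) {
    ext <- if (fmt == "stl_binary") "stl" else fmt
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMesh(m, path, format = fmt)
    m2 <- readMesh(path)
    expect_equal(nrow(faces(m2)), nrow(faces(m)), info = fmt)
    expect_equal(nrow(vertices(m2)), nrow(vertices(m)), info = fmt)
    expect_equal(volume(m2), volume(m), tolerance = 1e-5, info = fmt)
  }
})

test_that("an STL cube loads as 8 vertices / 12 faces, watertight", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeMesh(meshBox(1, 1, 1), path)
  m <- readMesh(path)
  expect_equal(nrow(vertices(m)), 8L) # duplicates merged at load
  expect_equal(nrow(faces(m)), 12L)
  expect_true(isWatertight(m))
})

test_that("corrupt or inconsistent files raise parse/validation errors", {
  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "garbage", "endsolid x"), bad)
  expect_error(readMesh(bad), "STL")
  expect_error(readMesh("no/such/file.stl"), "not found")
  # OBJ face referencing a missing vertex
  badobj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), badobj)
  expect_error(readMesh(badobj), "missing vertex")
  expect_error(readMesh(withr::local_tempfile(fileext = ".xyz")),
               "not found|format")
})

test_that("polygonal OBJ/PLY faces are fan-triangulated", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
               "f 1 4 3 2", "f 5 6 7 8", "f 1 2 6 5",
               "f 2 3 7 6", "f 3 4 8 7", "f 4 1 5 8"), p)
  m <- readMesh(p)
  expect_equal(nrow(faces(m)), 12L)
  expect_true(isWatertight(m))
  expect_equal(volume(m), 1, tolerance = 1e-9)
})
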