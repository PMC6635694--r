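# Shared fixtures, built once per test run. Bone generation is the
# expensive step, so the default synthetic bone (and a damaged copy)
# are cached here at the resolution used throughout the unit tests.

fixtureEnv <- new.env(parent = emptyenv())

# default synthetic metatarsal at test resolution (pitch 0.5 mm)
fixtureBone <- function() {
  if (is.null(fixtureEnv$bone))
    fixtureEnv$bone <- makeBone(boneParams(meshResolution = 2))
  fixtureEnv$bone
}

# 20%-clipped copy of the fixture bone (damage grid 0.25 mm)
fixtureDamaged <- function() {
  if (is.null(fixtureEnv$damaged))
    fixtureEnv$damaged <- damageBone(fixtureBone()$mesh, "plane_clip",
                                     fraction = 0.2, seed = 7,
                                     pitch = 0.25)
  fixtureEnv$damaged
}

# coronal head section of the fixture bone, cutting both grooves
fixtureHeadSection <- function() {
  if (is.null(fixtureEnv$section)) {
    m <- fixtureBone()$mesh
    fixtureEnv$section <- sectionAt(m, axis = c(0, 0, 1), angle = 0,
                                    pivot = c(6, 0, 0),
                                    baseNormal = c(1, 0, 0))
  }
  fixtureEnv$section
}

expect_relative <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}

# Rodrigues rotation, independent of package internals
rotationAboutAxisForTest <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# seed an expression without disturbing the session RNG stream
withSeedForTest <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
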