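# Parametric generator of bone-like test solids with ground-truth
# morphometrics: a superellipsoid shaft capped by a spherical head into
# which two cylindrical sesamoid grooves are carved, plus a damage
# operator. All solids are built as implicit fields on a voxel grid and
# isosurfaced, so every output is watertight by construction and the
# generating grid doubles as the ground-truth oracle.

#' Parameters for the synthetic bone generator
#'
#' Defaults describe a first-metatarsal-like solid: a 60 mm shaft of
#' elliptical cross-section (9 x 7 mm semi-radii), a 10 mm spherical
#' head, and two 4 mm plantar grooves running along the long axis with
#' configurable skew about the vertical axis. The voxel pitch of the
#' generator is `headRadius / (10 * meshResolution)`.
#'
#' @param shaftLength,shaftRadii,headRadius shaft length, shaft
#'   semi-radii (width, height) and head radius, mm.
#' @param grooveRadiusMedial,grooveRadiusLateral groove radii, mm.
#' @param grooveSkewMedial,grooveSkewLateral groove-axis skew about the
#'   vertical axis, degrees.
#' @param grooveDepthFrac carve depth as a fraction of groove radius.
#' @param groovePolarAngle angular position of the groove axes from the
#'   plantar (-z) direction, degrees.
#' @param meshResolution subdivision level (>= 2).
#' @param bumpAmplitude relative amplitude of seeded low-frequency
#'   surface bumps.
#' @param seed integer seed (bump field).
#' @return a validated [BoneParams-class].
#' @export
boneParams <- function(shaftLength = 60, shaftRadii = c(9, 7),
                       headRadius = 10,
                       grooveRadiusMedial = 4, grooveRadiusLateral = 4,
                       grooveSkewMedial = 0, grooveSkewLateral = 0,
                       grooveDepthFrac = 0.8, groovePolarAngle = 35,
                       meshResolution = 4, bumpAmplitude = 0,
                       seed = 1) {
  new("BoneParams", shaftLength = shaftLength, shaftRadii = shaftRadii,
      headRadius = headRadius,
      grooveRadiusMedial = grooveRadiusMedial,
      grooveRadiusLateral = grooveRadiusLateral,
      grooveSkewMedial = grooveSkewMedial,
      grooveSkewLateral = grooveSkewLateral,
      grooveDepthFrac = grooveDepthFrac,
      groovePolarAngle = groovePolarAngle,
      meshResolution = meshResolution,
      bumpAmplitude = bumpAmplitude, seed = seed)
}

# Implicit field of the bone (negative inside). Not a metric SDF, but
# its zero level is exact and its sign is what the oracle grid counts.
boneField <- function(p, X, Y, Z) {
  hr <- p@headRadius
  L <- p@shaftLength
  ry <- p@shaftRadii[1]
  rz <- p@shaftRadii[2]
  hx <- 0.6 * hr # head centre, shaft spans [-L, 0]
  # superellipsoid shaft: quartic along x, elliptic in cross-section
  xc <- (X + L / 2 - hx / 2) / ((L + hx) / 2)
  shaft <- (xc^4 + (Y / ry)^2 + (Z / rz)^2 - 1)
  head <- sqrt((X - hx)^2 + Y^2 + Z^2) - hr
  f <- pmin(shaft * min(ry, rz), head) # scale shaft residual to ~mm
  if (p@bumpAmplitude > 0) {
    amp <- p@bumpAmplitude * min(ry, rz)
    k <- withSeed(p@seed, matrix(runif(9, 0.05, 0.22), 3, 3))
    ph <- withSeed(p@seed + 1, matrix(runif(9, 0, 2 * pi), 3, 3))
    bump <- 0
    for (m in 1:3)
      bump <- bump + sin(k[m, 1] * X + ph[m, 1]) *
        sin(k[m, 2] * Y + ph[m, 2]) * sin(k[m, 3] * Z + ph[m, 3])
    f <- f - amp * bump / 3
  }
  # carve the grooves: subtract two cylinders near the plantar head
  for (side in c(-1, 1)) {
    r <- if (side < 0) p@grooveRadiusMedial else p@grooveRadiusLateral
    skew <- if (side < 0) p@grooveSkewMedial else p@grooveSkewLateral
    if (r <= 0) next
    alpha <- p@groovePolarAngle * pi / 180
    d <- hr + (1 - p@grooveDepthFrac) * r
    c0 <- c(hx, side * d * sin(alpha), -d * cos(alpha))
    a <- as.vector(rotationAboutAxis(c(0, 0, 1), skew) %*% c(1, 0, 0))
    px <- X - c0[1]; py <- Y - c0[2]; pz <- Z - c0[3]
    t <- px * a[1] + py * a[2] + pz * a[3]
    dx <- px - t * a[1]; dy <- py - t * a[2]; dz <- pz - t * a[3]
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    f <- pmax(f, r - dist)
  }
  f
}

#' Generate a synthetic bone with known ground truth
#'
#' Evaluates the implicit bone solid on a voxel grid at pitch
#' `headRadius / (10 * meshResolution)` and isosurfaces it to a
#' watertight mesh. The ground-truth volume is the voxel count of the
#' same grid (oracle), the surface area is the output mesh's, groove
#' CDs are 2 x radius and groove angles the configured skews. Grooves
#' that would merge into each other raise an error.
#'
#' @param params a [BoneParams-class] (default [boneParams()]).
#' @return list with `mesh` ([BoneMesh-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' \donttest{
#' b <- makeBone(boneParams(meshResolution = 2))
#' isWatertight(b$mesh)
#' }
#' @export
makeBone <- function(params = boneParams()) {
  validObject(params)
  p <- params
  pitch <- p@headRadius / (10 * p@meshResolution)
  hr <- p@headRadius
  L <- p@shaftLength
  m <- 3 * pitch + p@bumpAmplitude * min(p@shaftRadii)
  lo <- c(-L - m, -max(p@shaftRadii, hr) - m, -max(p@shaftRadii, hr) - m)
  hi <- c(0.6 * hr + hr + m, max(p@shaftRadii, hr) + m,
          max(p@shaftRadii, hr) + m)
  dims <- as.integer(ceiling((hi - lo) / pitch))
  xs <- lo[1] + (seq_len(dims[1]) - 0.5) * pitch
  ys <- lo[2] + (seq_len(dims[2]) - 0.5) * pitch
  zs <- lo[3] + (seq_len(dims[3]) - 0.5) * pitch
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  f <- boneField(p, X, Y, Z)
  checkGroovesDisjoint(p)
  mesh <- meshFromField(f, lo, pitch, iso = 0, name = "synthetic_bone")
  vol <- sum(f < 0) * pitch^3
  truth <- new("GroundTruth", volume = vol,
               surfaceArea = triangleAreaTotal(mesh),
               grooveCD = c(medial = 2 * p@grooveRadiusMedial,
                            lateral = 2 * p@grooveRadiusLateral),
               grooveAngles = c(medial = p@grooveSkewMedial,
                                lateral = p@grooveSkewLateral),
               damageFraction = 0)
  list(mesh = mesh, truth = truth)
}

# The two groove cylinders must not intersect each other where they
# meet the head, or the carved furrows merge and sides are ambiguous.
checkGroovesDisjoint <- function(p) {
  hr <- p@headRadius
  alpha <- p@groovePolarAngle * pi / 180
  dm <- hr + (1 - p@grooveDepthFrac) * p@grooveRadiusMedial
  dl <- hr + (1 - p@grooveDepthFrac) * p@grooveRadiusLateral
  c1 <- c(-dm * sin(alpha), -dm * cos(alpha))
  c2 <- c(dl * sin(alpha), -dl * cos(alpha))
  gap <- vnorm(c1 - c2) - (p@grooveRadiusMedial + p@grooveRadiusLateral)
  if (gap <= 0)
    stop("grooves overlap each other (gap ", signif(gap, 3),
         " mm); reduce radii or increase groovePolarAngle")
  invisible(TRUE)
}

#' Damage a bone mesh by a plane clip or a spherical bite
#'
#' Removes approximately `fraction` of the solid volume, emulating
#' fossil damage. The cut is found by bisection on the voxel occupancy
#' (plane offset or sphere radius) and the damaged solid is re-closed
#' along the cut, so the result is watertight but misses the anatomy.
#' `plane_clip` removes a cap in a seeded random direction biased
#' toward the head (+x); `sphere_bite` removes the intersection with a
#' sphere centred on a seeded random surface point.
#'
#' @param mesh a watertight [BoneMesh-class].
#' @param mode "plane_clip" or "sphere_bite".
#' @param fraction target removed-volume fraction, in (0, 0.5).
#' @param seed integer seed for the cut geometry.
#' @param pitch voxel pitch (mm) of the damage grid.
#' @return list with `mesh` (damaged [BoneMesh-class]),
#'   `removedFraction` (achieved value) and `cut` (the cut geometry:
#'   plane direction/offset or sphere centre/radius).
#' @export
damageBone <- function(mesh, mode = c("plane_clip", "sphere_bite"),
                       fraction = 0.2, seed = 1, pitch = NULL) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)")
  if (is.null(pitch)) {
    ext <- apply(mesh@vertices, 2, function(x) diff(range(x)))
    pitch <- max(ext) / 300 # ~0.25 mm for a 75 mm bone, CT-like
  }
  grid <- voxelizeMesh(mesh, pitch)
  occ <- grid$occ
  n0 <- sum(occ)
  if (n0 == 0) stop("voxelization failed; try a finer pitch")
  idx <- which(occ, arr.ind = TRUE)
  ctr <- sweep((idx - 0.5) * grid$pitch, 2, grid$origin, "+")
  cut <- NULL
  if (mode == "plane_clip") {
    dir <- withSeed(seed, {
      v <- rnorm(3)
      v[1] <- abs(v[1]) + 0.5 # bias toward the head (+x)
      unitv(v)
    })
    proj <- as.vector(ctr %*% dir)
    # plane offset t: remove voxels with projection > t
    t <- stats::quantile(proj, 1 - fraction, names = FALSE)
    removed <- proj > t
    cut <- list(mode = mode, direction = dir, offset = t)
  } else {
    surfpt <- withSeed(seed, {
      v <- unitv(rnorm(3))
      i <- which.max(as.vector(mesh@vertices %*% v))
      mesh@vertices[i, ]
    })
    dist <- sqrt(rowSums(sweep(ctr, 2, surfpt)^2))
    lo <- 0; hi <- 2 * max(dist)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      fr <- mean(dist < mid)
      if (fr < fraction) lo <- mid else hi <- mid
    }
    removed <- dist < (lo + hi) / 2
    cut <- list(mode = mode, center = surfpt, radius = (lo + hi) / 2)
  }
  keep <- occ
  keep[idx[removed, , drop = FALSE]] <- FALSE
  achieved <- 1 - sum(keep) / n0
  dam <- meshFromOccupancy(list(occ = keep, origin = grid$origin,
                                pitch = grid$pitch, dims = grid$dims),
                           name = paste0(mesh@name, "_damaged"))
  list(mesh = dam, removedFraction = achieved, cut = cut)
}

#' Generate a three-bone synthetic subject
#'
#' Builds a proportioned metatarsal / proximal phalanx / distal phalanx
#' set feeding the morphometry pipeline. The phalanges are plain
#' (grooveless) bones scaled down from the metatarsal; the distal
#' phalanx is additionally scaled so the proximal:distal volume ratio
#' matches `phalanxVolumeRatio`.
#'
#' @param scale uniform pre-standardization scale of the whole subject.
#' @param params metatarsal [BoneParams-class].
#' @param phalanxVolumeRatio target proximal/distal volume ratio
#'   (default 1.83, a proportionally stout distal phalanx).
#' @return list with `metatarsal`, `proximal`, `distal` meshes and
#'   `truth` (the metatarsal's [GroundTruth-class]).
#' @export
makeSubject <- function(scale = 1, params = boneParams(),
                        phalanxVolumeRatio = 1.83) {
  if (scale <= 0) stop("scale must be positive")
  met <- makeBone(params)
  proxPar <- boneParams(shaftLength = 0.45 * params@shaftLength,
                        shaftRadii = 0.9 * params@shaftRadii,
                        headRadius = 0.8 * params@headRadius,
                        grooveRadiusMedial = 0, grooveRadiusLateral = 0,
                        meshResolution = params@meshResolution,
                        seed = params@seed + 1)
  pro <- makeBone(proxPar)
  distPar <- boneParams(shaftLength = 0.3 * params@shaftLength,
                        shaftRadii = 0.85 * params@shaftRadii,
                        headRadius = 0.75 * params@headRadius,
                        grooveRadiusMedial = 0, grooveRadiusLateral = 0,
                        meshResolution = params@meshResolution,
                        seed = params@seed + 2)
  dis <- makeBone(distPar)
  s <- (volume(pro$mesh) / (phalanxVolumeRatio * volume(dis$mesh)))^(1 / 3)
  dmesh <- scaleMesh(dis$mesh, s)
  list(metatarsal = scaleMesh(met$mesh, scale),
       proximal = scaleMesh(pro$mesh, scale),
       distal = scaleMesh(dmesh, scale),
       truth = met$truth)
}
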