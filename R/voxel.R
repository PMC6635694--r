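# Voxel-domain machinery: solid voxelization, signed distance fields,
# isosurface re-meshing, voxel mass-property oracle and voxel IoU.
# Grids are cell-centred; `origin` is the corner of the first cell so
# cell (i,j,k) has centre origin + (i - 0.5) * pitch (1-based).

#' Voxelize the solid enclosed by a mesh
#'
#' Rasterizes a watertight mesh into a boolean occupancy grid by x-ray
#' parity counting: a cell is inside when its centre lies between an
#' odd/even pair of surface crossings.
#'
#' @param mesh a watertight [BoneMesh-class].
#' @param pitch voxel edge length (mm).
#' @param margin grid padding beyond the bounding box (mm).
#' @param bbox optional 2 x 3 matrix (min row, max row) forcing the
#'   grid extent, e.g. to share a grid between two meshes.
#' @return a list with `occ` (logical 3D array), `origin`, `pitch`,
#'   `dims`.
#' @export
voxelizeMesh <- function(mesh, pitch, margin = 2 * pitch, bbox = NULL) {
  if (pitch <= 0) stop("pitch must be positive")
  V <- mesh@vertices
  if (is.null(bbox)) {
    bbox <- rbind(apply(V, 2, min) - margin, apply(V, 2, max) + margin)
  }
  # irrational sub-pitch grid offset: keeps parity rays and cell centres
  # off the lattice planes of grid-generated (isosurfaced) meshes
  origin <- bbox[1, ] - pitch * c(0.21373130, 0.37029118, 0.43212112)
  dims <- pmax(as.integer(ceiling((bbox[2, ] - origin) / pitch)), 1L)
  occ <- cpp_voxelize(V, mesh@faces, as.numeric(origin), pitch,
                      as.integer(dims))
  dim(occ) <- dims
  list(occ = occ, origin = as.numeric(origin), pitch = pitch, dims = dims)
}

# Signed distance field (mm) from an occupancy grid; negative inside.
gridSDF <- function(grid) {
  sdf <- cpp_chamfer_sdf(as.logical(grid$occ), as.integer(grid$dims)) *
    grid$pitch
  dim(sdf) <- grid$dims
  sdf
}

#' Extract a watertight mesh from a scalar field (marching tetrahedra)
#'
#' Triangulates the `iso` level set of a cell-centred scalar field.
#' Triangles are consistently oriented with normals pointing toward
#' increasing field values, so for signed-distance-like fields
#' (negative inside) the result encloses the negative region.
#'
#' @param field 3D numeric array of field values at cell centres.
#' @param origin grid corner (mm).
#' @param pitch cell size (mm).
#' @param iso level to extract (default 0).
#' @param name label for the output mesh.
#' @return a [BoneMesh-class].
#' @export
meshFromField <- function(field, origin, pitch, iso = 0, name = "isosurface") {
  dims <- dim(field)
  f <- as.numeric(field)
  # avoid exact-on-level grid values (degenerate tetrahedra)
  rng <- max(abs(range(f - iso)))
  f[f == iso] <- iso + 1e-9 * max(rng, 1)
  res <- cpp_marching_tetra(f, as.integer(dims), as.numeric(origin),
                            pitch, iso)
  if (nrow(res$vertices) == 0)
    stop("empty isosurface: the level set does not intersect the grid")
  boneMesh(res$vertices, res$faces, name = name, repair = FALSE)
}

# Re-mesh an occupancy grid through its signed distance field.
meshFromOccupancy <- function(grid, name = "remeshed") {
  meshFromField(gridSDF(grid), grid$origin, grid$pitch, iso = 0, name = name)
}

#' Brute-force voxel oracle for mass properties
#'
#' Computes volume, centre of mass and inertia tensor by summing voxel
#' contributions of an occupancy grid (each voxel a cube of side
#' `pitch`, including its own small-cube inertia). Used as an
#' independent cross-check of the surface-integral implementation in
#' [massProperties()].
#'
#' @param grid output of [voxelizeMesh()], or a mesh plus `pitch`.
#' @param mesh optional mesh; when given, it is voxelized at `pitch`.
#' @param pitch voxel size when `mesh` is given (mm).
#' @return list with `volume`, `com`, `inertia`.
#' @export
voxelMassProperties <- function(grid = NULL, mesh = NULL, pitch = 0.25) {
  if (is.null(grid)) grid <- voxelizeMesh(mesh, pitch)
  occ <- grid$occ
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty occupancy grid")
  p <- grid$pitch
  ctr <- sweep((idx - 0.5) * p, 2, grid$origin, "+")
  vol <- nrow(idx) * p^3
  com <- colMeans(ctr)
  d <- sweep(ctr, 2, com)
  S <- crossprod(d) * p^3 # second moments of voxel centres
  I <- diag(sum(diag(S)), 3) - S
  # own inertia of each voxel cube: (1/6) m p^2 per axis
  I <- I + diag(nrow(idx) * p^3 * p^2 / 6, 3)
  list(volume = vol, com = com, inertia = I)
}

#' Intersection-over-union of two solids on a shared voxel grid
#'
#' @param meshA,meshB watertight meshes.
#' @param pitch voxel size (mm).
#' @return IoU in [0, 1].
#' @export
voxelIoU <- function(meshA, meshB, pitch = 0.5) {
  lo <- pmin(apply(meshA@vertices, 2, min), apply(meshB@vertices, 2, min))
  hi <- pmax(apply(meshA@vertices, 2, max), apply(meshB@vertices, 2, max))
  bbox <- rbind(lo - 2 * pitch, hi + 2 * pitch)
  ga <- voxelizeMesh(meshA, pitch, bbox = bbox)
  gb <- voxelizeMesh(meshB, pitch, bbox = bbox)
  inter <- sum(ga$occ & gb$occ)
  uni <- sum(ga$occ | gb$occ)
  if (uni == 0) return(0)
  inter / uni
}
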