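#' Construct a BoneMesh, validating and repairing orientation
#'
#' Builds a [BoneMesh-class] from raw vertex and face arrays. Load-time
#' repair merges exactly duplicated vertices, drops degenerate
#' (zero-area) faces with a message, makes face winding consistent
#' across shared edges and flips the whole surface if needed so the
#' signed volume is positive (outward normals).
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param name label for the bone.
#' @param repair logical; apply the repair pipeline (default TRUE).
#' @return a validated [BoneMesh-class].
#' @examples
#' cube <- meshBox(1, 1, 1)
#' isWatertight(cube)
#' @export
boneMesh <- function(vertices, faces, name = "", repair = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0 || nrow(faces) == 0)
    stop("empty mesh: no vertices or faces")
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (any(is.na(vertices)) || any(is.na(faces)))
    stop("mesh contains NA values")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face references a missing vertex")
  if (repair) {
    m <- repairMesh(vertices, faces)
    vertices <- m$vertices
    faces <- m$faces
  }
  new("BoneMesh", vertices = vertices, faces = faces, name = name)
}

# Merge duplicate vertices, drop degenerate faces, fix winding.
repairMesh <- function(V, F) {
  key <- paste(V[, 1], V[, 2], V[, 3], sep = "/")
  first <- match(key, key)
  if (any(first != seq_len(nrow(V)))) {
    keep <- sort(unique(first))
    remap <- integer(nrow(V))
    remap[keep] <- seq_along(keep)
    F <- matrix(remap[first[F]], ncol = 3)
    V <- V[keep, , drop = FALSE]
  }
  # degenerate faces: repeated indices or (near-)zero area
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  # only exactly-degenerate faces (repeated vertices, zero area) are
  # dropped: tiny-but-real sliver triangles from isosurfacing are part
  # of the closed surface and removing them would open holes
  bad <- (F[, 1] == F[, 2]) | (F[, 2] == F[, 3]) | (F[, 1] == F[, 3]) |
    (area2 == 0)
  if (any(bad)) {
    message(sum(bad), " degenerate face(s) dropped at load")
    F <- F[!bad, , drop = FALSE]
  }
  if (nrow(F) == 0) stop("mesh has no non-degenerate faces")
  F <- orientFaces(V, F)
  storage.mode(F) <- "integer"
  list(vertices = V, faces = F)
}

# Make winding consistent (BFS over shared edges) and outward
# (positive signed volume). Only runs BFS when a directed edge is
# duplicated, i.e. winding is inconsistent.
orientFaces <- function(V, F) {
  dirkey <- function(F) c(F[, 1], F[, 2], F[, 3]) * 2^26 +
    c(F[, 2], F[, 3], F[, 1])
  if (anyDuplicated(dirkey(F))) {
    m <- nrow(F)
    ek <- function(i, j) paste(pmin(i, j), pmax(i, j))
    edges <- c(ek(F[, 1], F[, 2]), ek(F[, 2], F[, 3]), ek(F[, 3], F[, 1]))
    eid <- match(edges, unique(edges))
    face_of <- rep(seq_len(m), 3)
    adj <- split(face_of, eid) # faces sharing each edge
    flipped <- rep(NA, m)
    for (seed in seq_len(m)) {
      if (!is.na(flipped[seed])) next
      flipped[seed] <- FALSE
      queue <- seed
      while (length(queue)) {
        f <- queue[[1]]; queue <- queue[-1]
        Ff <- if (flipped[f]) F[f, c(1, 3, 2)] else F[f, ]
        fdir <- rbind(Ff[1:2], Ff[2:3], Ff[c(3, 1)])
        for (e in ((f - 1) %% m) + c(0, m, 2 * m) + 1) {
          for (g in adj[[eid[e]]]) {
            if (g == f || !is.na(flipped[g])) next
            Fg <- F[g, ]
            gdir <- rbind(Fg[1:2], Fg[2:3], Fg[c(3, 1)])
            # shared edge must be traversed in opposite directions
            same <- any(apply(fdir, 1, function(d)
              any(gdir[, 1] == d[1] & gdir[, 2] == d[2])))
            flipped[g] <- xor(same, flipped[f])
            queue <- c(queue, g)
          }
        }
      }
    }
    flip <- which(flipped)
    if (length(flip)) F[flip, ] <- F[flip, c(1, 3, 2), drop = FALSE]
  }
  if (signedVolume(V, F) < 0) F <- F[, c(1, 3, 2), drop = FALSE]
  F
}

signedVolume <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

triangleAreaTotal <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# Multiplicity of each undirected edge, via packed numeric keys
# (valid for meshes below 2^26 vertices).
undirectedEdgeCounts <- function(F) {
  i <- c(F[, 1], F[, 2], F[, 3])
  j <- c(F[, 2], F[, 3], F[, 1])
  key <- sort(pmin(i, j) * 2^26 + pmax(i, j))
  n <- length(key)
  new_grp <- c(TRUE, key[-1] != key[-n])
  list(keys = key[new_grp], counts = diff(c(which(new_grp), n + 1)))
}

#' Watertightness and boundary edges
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two faces. `boundaryEdgeCount` counts edges belonging to exactly one
#' face (open boundary).
#'
#' @param mesh a [BoneMesh-class].
#' @return `isWatertight`: logical. `boundaryEdgeCount`: integer.
#' @export
isWatertight <- function(mesh) {
  all(undirectedEdgeCounts(mesh@faces)$counts == 2)
}

#' @rdname isWatertight
#' @export
boundaryEdgeCount <- function(mesh) {
  sum(undirectedEdgeCounts(mesh@faces)$counts == 1)
}

# Boundary loop count and total length, for defect reporting.
boundaryLoopStats <- function(mesh) {
  ec <- undirectedEdgeCounts(mesh@faces)
  open <- ec$keys[ec$counts == 1]
  if (!length(open)) return(list(loops = 0L, length = 0))
  e <- cbind(open %/% 2^26, open %% 2^26)
  V <- mesh@vertices
  len <- sum(sqrt(rowSums((V[e[, 1], , drop = FALSE] -
                           V[e[, 2], , drop = FALSE])^2)))
  # count connected components of the boundary edge graph
  verts <- unique(as.vector(e))
  comp <- seq_along(verts)
  names(comp) <- verts
  find <- function(x) {
    while (comp[[as.character(x)]] != x) x <- comp[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(e))) {
    ra <- find(e[r, 1]); rb <- find(e[r, 2])
    if (ra != rb) comp[[as.character(max(ra, rb))]] <- min(ra, rb)
  }
  roots <- unique(vapply(verts, find, numeric(1)))
  list(loops = length(roots), length = len)
}

#' Mass properties of the enclosed uniform-density solid
#'
#' Volume, surface area, centre of mass and the inertia tensor about
#' the COM, computed exactly from the surface by signed-tetrahedron
#' summation (divergence theorem), with density fixed at 1. The mesh
#' must be watertight and consistently oriented.
#'
#' @param mesh a watertight [BoneMesh-class].
#' @return a [MassProperties-class].
#' @examples
#' mp <- massProperties(meshBox(10, 4, 2))
#' volume(mp)          # 80
#' principalMoments(mp) / volume(mp)  # (b^2+c^2)/12 etc.
#' @export
massProperties <- function(mesh) {
  stopifnot(is(mesh, "BoneMesh"))
  if (!isWatertight(mesh))
    stop("mesh is not watertight: ", boundaryEdgeCount(mesh),
         " open boundary edge(s); mass properties need an enclosed solid")
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  detv <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- sum(detv) / 6
  if (vol <= 0) stop("non-positive enclosed volume; orientation repair failed")
  # first moments: integral of x over each origin-tetrahedron
  centroid4 <- (a + b + cc) / 4 # fourth vertex is the origin
  com <- colSums(centroid4 * detv / 6) / vol
  # second moments over origin-tetrahedra:
  # int x_p x_q dV = V_t/20 * (sum_i v_ip v_iq + (sum_i v_ip)(sum_i v_iq))
  S <- matrix(0, 3, 3)
  sv <- a + b + cc # origin contributes zero
  for (p in 1:3) for (q in p:3) {
    term <- a[, p] * a[, q] + b[, p] * b[, q] + cc[, p] * cc[, q] +
      sv[, p] * sv[, q]
    S[p, q] <- S[q, p] <- sum(detv / 6 / 20 * term)
  }
  Scom <- S - vol * outer(com, com)
  inertia <- diag(sum(diag(Scom)), 3) - Scom
  new("MassProperties", volume = vol, surfaceArea = triangleAreaTotal(mesh),
      com = com, inertia = inertia)
}

#' Serialize mass properties to JSON with explicit units
#'
#' @param mp a [MassProperties-class].
#' @param path optional file; when NULL the JSON string is returned.
#' @export
massPropertiesJSON <- function(mp, path = NULL) {
  x <- list(volume_mm3 = mp@volume, surface_area_mm2 = mp@surfaceArea,
            com_mm = mp@com, inertia_mm5 = mp@inertia,
            principal_moments_mm5 = principalMoments(mp))
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Primitive test meshes: box, icosphere, cylinder
#'
#' Watertight primitives used as fixtures and building blocks. The box
#' spans `c(-a,-b,-c)/2 .. c(a,b,c)/2 + center`; the icosphere is a
#' subdivided icosahedron projected to radius `r`; the cylinder has its
#' axis along z and capped ends.
#'
#' @param a,b,c box edge lengths (mm).
#' @param center centre of the primitive.
#' @param r radius (mm).
#' @param subdivisions icosphere subdivision level (>= 0).
#' @param h cylinder height (mm).
#' @param sections number of angular segments of the cylinder.
#' @return a [BoneMesh-class].
#' @export
meshBox <- function(a, b, c, center = c(0, 0, 0)) {
  if (a <= 0 || b <= 0 || c <= 0) stop("box dimensions must be positive")
  s <- c(a, b, c) / 2
  V <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  V <- sweep(V %*% diag(s), 2, center, "+")
  # 12 outward triangles of the unit cube with the expand.grid ordering
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = -1
    c(5, 6, 7), c(6, 8, 7),  # z = +1
    c(1, 2, 5), c(2, 6, 5),  # y = -1
    c(3, 7, 4), c(4, 7, 8),  # y = +1
    c(1, 5, 3), c(3, 5, 7),  # x = -1
    c(2, 4, 6), c(4, 8, 6))  # x = +1
  boneMesh(V, F, name = "box", repair = FALSE) # already consistent
}

#' @rdname meshBox
#' @export
meshIcosphere <- function(r = 1, subdivisions = 3, center = c(0, 0, 0)) {
  if (r <= 0) stop("radius must be positive")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdivisions)) {
    nv <- nrow(V)
    ek <- function(i, j) paste(pmin(i, j), pmax(i, j))
    edges <- unique(c(ek(F[, 1], F[, 2]), ek(F[, 2], F[, 3]),
                      ek(F[, 1], F[, 3])))
    mididx <- function(i, j) nv + match(ek(i, j), edges)
    pairs <- do.call(rbind, strsplit(edges, " "))
    i <- as.integer(pairs[, 1]); j <- as.integer(pairs[, 2])
    mids <- (V[i, , drop = FALSE] + V[j, , drop = FALSE]) / 2
    V <- rbind(V, mids)
    m12 <- mididx(F[, 1], F[, 2])
    m23 <- mididx(F[, 2], F[, 3])
    m13 <- mididx(F[, 1], F[, 3])
    F <- rbind(cbind(F[, 1], m12, m13), cbind(F[, 2], m23, m12),
               cbind(F[, 3], m13, m23), cbind(m12, m23, m13))
  }
  V <- V / sqrt(rowSums(V^2)) * r
  V <- sweep(V, 2, center, "+")
  boneMesh(V, F, name = "icosphere", repair = FALSE)
}

#' @rdname meshBox
#' @export
meshCylinder <- function(r = 1, h = 1, sections = 48, center = c(0, 0, 0)) {
  if (r <= 0 || h <= 0) stop("cylinder dimensions must be positive")
  th <- seq(0, 2 * pi, length.out = sections + 1)[-(sections + 1)]
  ring <- cbind(r * cos(th), r * sin(th))
  V <- rbind(cbind(ring, -h / 2), cbind(ring, h / 2),
             c(0, 0, -h / 2), c(0, 0, h / 2))
  n <- sections
  lo <- seq_len(n); hi <- lo + n
  nxt <- c(2:n, 1)
  side <- rbind(cbind(lo, nxt, hi), cbind(nxt, nxt + n, hi))
  capb <- cbind(2 * n + 1, nxt, lo)
  capt <- cbind(2 * n + 2, hi, nxt + n)
  V <- sweep(V, 2, center, "+")
  boneMesh(V, rbind(side, capb, capt), name = "cylinder", repair = FALSE)
}

#' Rigid and scaling transforms of a mesh
#'
#' `translateMesh`, `rotateMesh` (about the origin) and `scaleMesh`
#' (uniform, about the origin) return transformed copies.
#'
#' @param mesh a [BoneMesh-class].
#' @param offset length-3 translation (mm).
#' @param R 3 x 3 rotation matrix, or `axis`+`angle` (degrees).
#' @param axis,angle alternative rotation specification.
#' @param s uniform scale factor (> 0).
#' @export
translateMesh <- function(mesh, offset) {
  mesh@vertices <- sweep(mesh@vertices, 2, offset, "+")
  mesh
}

#' @rdname translateMesh
#' @export
rotateMesh <- function(mesh, R = NULL, axis = NULL, angle = NULL) {
  if (is.null(R)) R <- rotationAboutAxis(axis, angle)
  if (abs(det(R) - 1) > 1e-6) stop("R must be a proper rotation")
  mesh@vertices <- mesh@vertices %*% t(R)
  mesh
}

#' @rdname translateMesh
#' @export
scaleMesh <- function(mesh, s) {
  if (s <= 0) stop("scale must be positive")
  mesh@vertices <- mesh@vertices * s
  mesh
}
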