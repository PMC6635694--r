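#' Principal-axes-of-inertia body coordinate frame of a bone
#'
#' Builds the bone's intrinsic "body coordinate system": origin at the
#' centre of mass, axes along the principal axes of inertia of the
#' enclosed uniform solid. Axes are ordered by ascending principal
#' moment, so the first axis is the elongation (long) axis. Signs are
#' fixed by a mesh-intrinsic convention: each of the first two axes is
#' oriented so the third central moment (skewness) of the vertex
#' coordinates along it is non-negative (on a tie, so that the vertex
#' with the largest absolute coordinate is positive); the third axis
#' completes a right-handed triplet.
#'
#' Near-degenerate principal moments (relative eigenvalue gap below
#' `degeneracyTol`) trigger a deterministic fallback to the global
#' x/y/z axes with a warning, since the principal directions are then
#' numerically meaningless.
#'
#' @param mesh a watertight [BoneMesh-class].
#' @param degeneracyTol relative eigenvalue gap below which the frame
#'   is treated as degenerate.
#' @return a [BodyFrame-class].
#' @examples
#' f <- principalFrame(meshBox(10, 4, 2))
#' frameAxes(f)[1, ]  # the 10 mm edge direction (up to sign)
#' @export
principalFrame <- function(mesh, degeneracyTol = 1e-6) {
  mp <- massProperties(mesh)
  eg <- eigen(mp@inertia, symmetric = TRUE)
  ord <- order(eg$values) # ascending moment: long axis first
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  gaps <- diff(vals) / max(abs(vals))
  degenerate <- any(gaps < degeneracyTol)
  if (degenerate) {
    warning("near-degenerate principal moments; falling back to global axes")
    axes <- diag(3)
  } else {
    axes <- matrix(0, 3, 3)
    ctr <- sweep(mesh@vertices, 2, mp@com)
    for (i in 1:2) {
      a <- vecs[, i]
      t <- as.vector(ctr %*% a)
      s <- mean(t^3)
      if (abs(s) < 1e-9 * max(abs(t))^3) {
        # skewness tie: make the farthest vertex positive
        if (t[which.max(abs(t))] < 0) a <- -a
      } else if (s < 0) a <- -a
      axes[i, ] <- a
    }
    axes[3, ] <- cross3(axes[1, ], axes[2, ])
  }
  new("BodyFrame", origin = mp@com, axes = axes, handedness = 1,
      moments = vals, degenerate = degenerate)
}

#' Transform a mesh into its body coordinate frame
#'
#' Maps the mesh so its centre of mass sits at the origin and its
#' long/second/third principal axes align with global x/y/z. The
#' operation is idempotent up to the sign convention.
#'
#' @param mesh a watertight [BoneMesh-class].
#' @param frame optional precomputed [BodyFrame-class].
#' @return the aligned [BoneMesh-class].
#' @export
toBodyFrame <- function(mesh, frame = NULL) {
  if (is.null(frame)) frame <- principalFrame(mesh)
  R <- frame@axes
  mesh@vertices <- sweep(mesh@vertices, 2, frame@origin) %*% t(R)
  mesh
}

#' Homogeneous 4 x 4 transform of a body frame
#'
#' The matrix mapping global coordinates into the frame's body
#' coordinates (rotation rows = axes, then translation of the COM to
#' the origin).
#'
#' @param frame a [BodyFrame-class].
#' @return 4 x 4 numeric matrix.
#' @export
bodyTransform <- function(frame) {
  M <- diag(4)
  M[1:3, 1:3] <- frame@axes
  M[1:3, 4] <- -frame@axes %*% frame@origin
  M
}

#' Body-frame extents: standardized length, width and height
#'
#' Axis-aligned bounding-box extents of a mesh already expressed in its
#' body frame, reported along the long/second/third axes in that order.
#'
#' @param mesh a [BoneMesh-class] in its body frame.
#' @return named numeric: length, width, height (mm).
#' @export
boneExtents <- function(mesh) {
  r <- apply(mesh@vertices, 2, range)
  ext <- r[2, ] - r[1, ]
  names(ext) <- c("length", "width", "height")
  ext
}

#' Standardize a subject's bone set to metatarsal length 100
#'
#' Aligns the three bones of a subject (first metatarsal, proximal
#' phalanx, distal phalanx) into their individual body frames, then
#' applies one uniform scale `s = 100 / metatarsal length` to all
#' three, so the metatarsal's body-frame length is exactly 100. Linear
#' measures scale by s, areas by s^2, volumes by s^3, leaving all
#' dimensionless shape ratios unchanged.
#'
#' @param metatarsal,proximal,distal watertight [BoneMesh-class]
#'   objects.
#' @return a [StandardizedSet-class].
#' @export
standardizeSubject <- function(metatarsal, proximal, distal) {
  met <- toBodyFrame(metatarsal)
  pro <- toBodyFrame(proximal)
  dis <- toBodyFrame(distal)
  lens <- c(metatarsal = unname(boneExtents(met)["length"]),
            proximal = unname(boneExtents(pro)["length"]),
            distal = unname(boneExtents(dis)["length"]))
  if (!is.finite(lens[1]) || lens[1] <= 0)
    stop("metatarsal length must be positive")
  s <- 100 / lens[[1]]
  new("StandardizedSet",
      metatarsal = scaleMesh(met, s), proximal = scaleMesh(pro, s),
      distal = scaleMesh(dis, s), scale = s, originalLengths = lens)
}
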