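# Rotational cross-section analysis of the first metatarsal head:
# plane sections, the largest-section base level, concave groove arcs,
# least-squares curvature circles and the parallelism test.

# Intersect a mesh with the plane through `point` with unit normal
# `normal`. Segments are chained exactly via the mesh edges they cross,
# so closed surfaces yield closed loops. Returns loops of 3D points.
meshPlaneLoops <- function(V, F, point, normal) {
  d <- as.vector(sweep(V, 2, point) %*% normal)
  d[d == 0] <- 1e-12
  s <- d > 0
  cross_f <- which(s[F[, 1]] != s[F[, 2]] | s[F[, 2]] != s[F[, 3]])
  if (!length(cross_f)) return(list())
  Fc <- F[cross_f, , drop = FALSE]
  # per crossing face, its two crossing edges (as sorted vertex pairs)
  edgesOf <- function(fc) {
    sa <- s[fc[1]]; sb <- s[fc[2]]; sc <- s[fc[3]]
    # the lone vertex is on one side; crossing edges connect it to the others
    lone <- if (sa != sb && sa != sc) 1 else if (sb != sa && sb != sc) 2 else 3
    oth <- setdiff(1:3, lone)
    rbind(sort(fc[c(lone, oth[1])]), sort(fc[c(lone, oth[2])]))
  }
  ep <- lapply(seq_len(nrow(Fc)), function(i) edgesOf(Fc[i, ]))
  e1 <- t(vapply(ep, function(x) x[1, ], numeric(2)))
  e2 <- t(vapply(ep, function(x) x[2, ], numeric(2)))
  allE <- rbind(e1, e2)
  key <- paste(allE[, 1], allE[, 2])
  ukey <- unique(key)
  eid <- matrix(match(key, ukey), ncol = 2) # nface x 2 edge ids
  # intersection point per unique edge
  pairs <- allE[match(ukey, key), , drop = FALSE]
  di <- d[pairs[, 1]]; dj <- d[pairs[, 2]]
  t <- di / (di - dj)
  P <- V[pairs[, 1], , drop = FALSE] +
    (V[pairs[, 2], , drop = FALSE] - V[pairs[, 1], , drop = FALSE]) * t
  # walk loops: each edge id appears in exactly 2 faces on a closed surface
  nf <- nrow(eid)
  edge2face <- split(rep(seq_len(nf), 2), c(eid[, 1], eid[, 2]))
  visited <- logical(nf)
  loops <- list()
  for (f0 in seq_len(nf)) {
    if (visited[f0]) next
    loop <- integer()
    f <- f0
    enter <- eid[f, 1]
    repeat {
      visited[f] <- TRUE
      loop <- c(loop, enter)
      leave <- if (eid[f, 1] == enter) eid[f, 2] else eid[f, 1]
      nxt <- setdiff(edge2face[[leave]], f)
      if (!length(nxt) || visited[nxt[1]]) {
        loop <- c(loop, leave)
        break
      }
      f <- nxt[1]
      enter <- leave
    }
    # drop the duplicated closing edge if the loop closed on itself
    if (length(loop) > 1 && loop[length(loop)] == loop[1])
      loop <- loop[-length(loop)]
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- P[loop, , drop = FALSE]
  }
  loops
}

polygonArea2D <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Planar cross-section of a mesh about a rotation axis
#'
#' Cuts the mesh with a plane containing the rotation `axis`, rotated
#' by `angle` degrees about it from the base orientation
#' (`baseNormal`), optionally offset along the resulting normal. The
#' 3D intersection contours are expressed in 2D in-plane coordinates
#' with basis u = axis x normal (roughly the second body axis at angle
#' 0 when scanning about the vertical axis) and v = axis.
#'
#' @param mesh a [BoneMesh-class], normally in its body frame.
#' @param axis rotation axis (length-3, body frame).
#' @param angle signed rotation of the section plane about `axis`,
#'   degrees; negative is clockwise seen from the +axis direction.
#' @param offset plane offset along its normal (mm).
#' @param pivot point the plane passes through (default the origin).
#' @param baseNormal plane normal at angle 0; defaults to a
#'   deterministic direction orthogonal to `axis` (global x if
#'   possible).
#' @return a [CrossSection-class].
#' @export
sectionAt <- function(mesh, axis, angle = 0, offset = 0,
                      pivot = c(0, 0, 0), baseNormal = NULL) {
  axis <- unitv(axis)
  if (is.null(baseNormal)) {
    bn <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
    if (vnorm(bn) < 1e-6) bn <- cross3(axis, c(0, 1, 0))
    baseNormal <- unitv(bn)
  } else {
    baseNormal <- unitv(baseNormal - sum(baseNormal * axis) * axis)
  }
  n <- as.vector(rotationAboutAxis(axis, angle) %*% baseNormal)
  pt <- pivot + offset * n
  loops <- meshPlaneLoops(mesh@vertices, mesh@faces, pt, n)
  if (!length(loops))
    stop("empty section: the plane does not intersect the mesh")
  u <- cross3(axis, n)
  contours <- lapply(loops, function(L) {
    rel <- sweep(L, 2, pt)
    cbind(rel %*% u, rel %*% axis)
  })
  area <- sum(vapply(contours, function(cc) polygonArea2D(cc), numeric(1)))
  # outer loops are CCW given consistent outward mesh orientation;
  # report the magnitude (holes carry opposite sign)
  new("CrossSection", planePoint = pt, planeNormal = n,
      axisU = u, axisV = axis, contours = contours, area = abs(area))
}

#' Find the base level: the rotation angle of maximal section area
#'
#' Scans the family of planes containing `axis` over [0, 180) degrees
#' in `step` increments (the family is periodic with period 180) and
#' returns the angle whose cross-section through `pivot` has maximal
#' area. Ties return the smallest angle with a warning.
#'
#' @param mesh a [BoneMesh-class] in its body frame.
#' @param axis the rotation (long) axis.
#' @param step angular step, degrees (default 0.5).
#' @param pivot point contained in every plane (default origin = COM).
#' @param baseNormal normal at angle 0 (see [sectionAt()]).
#' @return list with `angle` (degrees), `area` (mm^2) and the full
#'   `trace` data.frame.
#' @export
findBaseLevel <- function(mesh, axis = c(1, 0, 0), step = 0.5,
                          pivot = c(0, 0, 0), baseNormal = NULL) {
  if (step <= 0) stop("step must be positive")
  angles <- seq(0, 180 - step / 2, by = step)
  areas <- vapply(angles, function(a) {
    sec <- try(sectionAt(mesh, axis, a, pivot = pivot,
                         baseNormal = baseNormal), silent = TRUE)
    if (inherits(sec, "try-error")) 0 else sec@area
  }, numeric(1))
  if (all(areas == 0)) stop("no plane of the family intersects the mesh")
  best <- which(areas >= max(areas) - 1e-12 * max(areas))
  if (length(best) > 1)
    warning("base-level tie across ", length(best),
            " angles; returning the smallest")
  list(angle = angles[best[1]], area = areas[best[1]],
       trace = data.frame(angle = angles, area = areas))
}

# Resample a closed polygon to n points equally spaced in arc length.
resampleClosed <- function(xy, n = 400) {
  P <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(P)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(P)] <- nrow(P) - 1
  w <- (s - cum[i]) / pmax(seg[i], 1e-300)
  P[i, , drop = FALSE] + (P[i + 1, , drop = FALSE] - P[i, , drop = FALSE]) * w
}

# Circular moving average for turning angles.
circularSmooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  k <- (w - 1) %/% 2
  xx <- c(x[(n - k + 1):n], x, x[1:k])
  as.vector(stats::filter(xx, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
}

#' Detect the medial and lateral groove arcs in a head cross-section
#'
#' Segments the section's outer contour by the sign of its discrete
#' curvature (turning angle) and extracts concave-inward runs: the
#' sesamoid grooves appear as the two longest concave arcs on the
#' plantar side of the head. Arcs are labelled medial/lateral by the
#' sign of their centroid's first in-plane coordinate (the second body
#' axis direction); `flipSides` swaps the labels, since an inertial
#' frame cannot know anatomical sidedness.
#'
#' @param section a [CrossSection-class] through the head.
#' @param nResample contour resampling density.
#' @param smoothWindow moving-average window (points) for the turning
#'   angle.
#' @param minTurn minimum total concave turning (degrees) for a run to
#'   count as a groove arc.
#' @param plantarSide which sign of the v (vertical) coordinate is
#'   plantar: "auto" (default; the side of the strongest concave arc,
#'   since both grooves lie on the same, plantar, side of the head),
#'   "negative", "positive", or "any" (no side filter).
#' @param flipSides swap the medial/lateral labels.
#' @return list with elements `medial` and `lateral`, each a list of
#'   `points` (k x 2 arc coordinates), `centroid2d`, `centroid3d`,
#'   `arcLength`.
#' @export
detectGrooveArcs <- function(section, nResample = 400, smoothWindow = 7,
                             minTurn = 8,
                             plantarSide = c("auto", "negative",
                                             "positive", "any"),
                             flipSides = FALSE) {
  plantarSide <- match.arg(plantarSide)
  cc <- section@contours
  areas <- vapply(cc, function(x) abs(polygonArea2D(x)), numeric(1))
  outer <- cc[[which.max(areas)]]
  if (polygonArea2D(outer) < 0) outer <- outer[nrow(outer):1, , drop = FALSE]
  P <- resampleClosed(outer, nResample)
  n <- nrow(P)
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  e1 <- P - P[prv, , drop = FALSE]
  e2 <- P[nxt, , drop = FALSE] - P
  turn <- atan2(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1],
                rowSums(e1 * e2)) * 180 / pi
  turn <- circularSmooth(turn, smoothWindow)
  concave <- turn < 0
  if (!any(concave)) stop("groove not found: contour has no concave arcs")
  # maximal circular runs of concavity
  r <- rle(concave)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (concave[1] && concave[n] && nrow(runs) > 1) { # wrap-around run
    runs$start[1] <- runs$start[nrow(runs)] - n
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  ctr <- colMeans(P)
  info <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- ((runs$start[i]:runs$end[i]) - 1) %% n + 1
    pts <- P[idx, , drop = FALSE]
    list(points = pts,
         totalTurn = -sum(turn[idx]),
         arcLength = sum(sqrt(rowSums(diff(pts)^2))),
         centroid2d = colMeans(pts))
  })
  keep <- vapply(info, function(x)
    x$totalTurn >= minTurn && nrow(x$points) >= 5, logical(1))
  if (plantarSide != "any" && any(keep)) {
    sgn <- switch(plantarSide,
      negative = -1, positive = 1,
      auto = {
        lens <- vapply(info, `[[`, numeric(1), "arcLength")
        lens[!keep] <- -Inf
        sign(info[[which.max(lens)]]$centroid2d[2] - ctr[2])
      })
    keep <- keep & vapply(info, function(x)
      sgn * (x$centroid2d[2] - ctr[2]) > 0, logical(1))
  }
  info <- info[keep]
  if (length(info) < 2)
    stop("groove not found: fewer than 2 concave arcs on the plantar side")
  ord <- order(vapply(info, `[[`, numeric(1), "arcLength"), decreasing = TRUE)
  two <- info[ord[1:2]]
  uord <- order(vapply(two, function(x) x$centroid2d[1], numeric(1)))
  medial <- two[[uord[1]]] # smaller u coordinate
  lateral <- two[[uord[2]]]
  if (flipSides) {
    tmp <- medial; medial <- lateral; lateral <- tmp
  }
  to3d <- function(x) {
    section@planePoint + x$centroid2d[1] * section@axisU +
      x$centroid2d[2] * section@axisV
  }
  medial$centroid3d <- to3d(medial)
  lateral$centroid3d <- to3d(lateral)
  list(medial = medial, lateral = lateral)
}

#' Algebraic least-squares circle fit (curvature circle)
#'
#' Fits a circle to 2D points by the linearized least-squares method
#' minimizing sum((|p - c|^2 - r^2)^2). The curvature diameter is twice
#' the fitted radius.
#'
#' @param points k x 2 matrix, k >= 3, not collinear.
#' @return list with `center` (length 2), `radius`, `rmsResidual` (rms
#'   of radial distances minus the radius, mm).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' fitCircle(cbind(5 * cos(th), 5 * sin(th)))$radius  # 5
#' @export
fitCircle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) stop("points are collinear; no unique circle")
  sol <- qr.coef(qrA, b)
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  if (r2 <= 0) stop("degenerate circle fit")
  radius <- sqrt(r2)
  res <- sqrt((x - center[1])^2 + (y - center[2])^2) - radius
  list(center = unname(center), radius = unname(radius),
       rmsResidual = sqrt(mean(res^2)))
}

#' Scan rotated sections for a groove's curvature diameter
#'
#' Rotates the section plane about `axis` (by default the vertical,
#' third body axis) in `step`-degree increments over `baseAngle` +/-
#' `angleRange`, pivoting at the groove-arc centroid so the plane keeps
#' cutting the groove. At each angle the groove arc on the requested
#' side is extracted and a curvature circle fitted; the fit at minimal
#' (default) or maximal CD is returned. The reported rotation angle is
#' refined by parabolic interpolation of CD over the three angles
#' around the grid optimum (sub-step localization of the extremum).
#'
#' @param mesh a [BoneMesh-class] in its body frame.
#' @param side "medial" or "lateral".
#' @param scan "min_cd" (default; the groove's true diameter, since
#'   oblique slices of a cylinder fit larger circles) or "max_cd".
#' @param angleRange half-range of the scan, degrees.
#' @param step angular step, degrees (default 0.5).
#' @param axis rotation axis; default the vertical body axis z.
#' @param baseNormal plane normal at angle 0; default the long axis x.
#' @param baseAngle centre of the scanned interval, degrees.
#' @param pivot optional fixed pivot; by default the side's groove-arc
#'   centroid located by [locateGrooves()].
#' @param flipSides,minTurn passed to [detectGrooveArcs()].
#' @return a [GrooveFit-class] with the per-angle trace.
#' @export
scanGrooveCD <- function(mesh, side = c("medial", "lateral"),
                         scan = c("min_cd", "max_cd"),
                         angleRange = 10, step = 0.5,
                         axis = c(0, 0, 1), baseNormal = c(1, 0, 0),
                         baseAngle = 0, pivot = NULL,
                         flipSides = FALSE, minTurn = 8) {
  side <- match.arg(side)
  scan <- match.arg(scan)
  if (step <= 0) stop("step must be positive")
  if (angleRange <= 0) stop("angleRange must be positive")
  if (is.null(pivot)) {
    loc <- locateGrooves(mesh, longAxis = baseNormal, axis = axis,
                         flipSides = flipSides, minTurn = minTurn)
    pivot <- loc[[side]]$centroid3d
  }
  angles <- seq(baseAngle - angleRange, baseAngle + angleRange, by = step)
  rows <- lapply(angles, function(a) {
    fit <- try(suppressWarnings({
      sec <- sectionAt(mesh, axis, a, pivot = pivot,
                       baseNormal = baseNormal)
      arcs <- detectGrooveArcs(sec, flipSides = flipSides,
                               minTurn = minTurn)
      arc <- arcs[[side]]
      cf <- fitCircle(arc$points)
      list(cd = 2 * cf$radius, rms = cf$rmsResidual,
           npts = nrow(arc$points), center = cf$center)
    }), silent = TRUE)
    if (inherits(fit, "try-error"))
      list(cd = NA_real_, rms = NA_real_, npts = 0L, center = c(NA, NA))
    else fit
  })
  trace <- data.frame(angle = angles,
                      cd = vapply(rows, `[[`, numeric(1), "cd"),
                      rms = vapply(rows, `[[`, numeric(1), "rms"),
                      npts = vapply(rows, function(r) as.integer(r$npts),
                                    integer(1)))
  ok <- which(!is.na(trace$cd))
  if (!length(ok))
    stop("groove lost at all scanned angles on the ", side, " side")
  i <- if (scan == "min_cd") ok[which.min(trace$cd[ok])]
       else ok[which.max(trace$cd[ok])]
  angle <- trace$angle[i]
  # sub-step refinement: CD(angle) is locally quadratic around the
  # extremum but very flat (for a groove of radius r the curvature is
  # ~2r per rad^2), so a least-squares parabola over a +/-refineWindow
  # neighbourhood is used to average out per-section fitting noise
  refineWindow <- max(2.5, 2 * step)
  win <- ok[abs(trace$angle[ok] - angle) <= refineWindow + 1e-9]
  if (length(win) >= 5) {
    th <- trace$angle[win] - angle
    co <- stats::lm.fit(cbind(1, th, th^2), trace$cd[win])$coefficients
    a2 <- co[3]
    ok_curv <- if (scan == "min_cd") a2 > 0 else a2 < 0
    if (ok_curv) {
      vertex <- -co[2] / (2 * a2)
      if (abs(vertex) <= refineWindow) angle <- angle + vertex
    }
  }
  new("GrooveFit", side = side, rotationAngle = angle,
      circleCenter = as.numeric(rows[[i]]$center),
      curvatureDiameter = trace$cd[i], rmsResidual = trace$rms[i],
      arcPoints = as.integer(trace$npts[i]), trace = trace,
      settings = list(scan = scan, step = step, angleRange = angleRange,
                      axis = axis, baseNormal = baseNormal,
                      baseAngle = baseAngle, pivot = pivot,
                      flipSides = flipSides))
}

#' Locate the sesamoid grooves on the head of a metatarsal mesh
#'
#' Sweeps section planes normal to the long axis across the distal
#' (head) part of the bone and returns, for the offset where groove
#' arcs are best developed (maximal combined arc length), the medial
#' and lateral arc descriptors including their 3D centroids. These
#' centroids are the natural pivots for [scanGrooveCD()].
#'
#' @param mesh a [BoneMesh-class] in its body frame, head toward +x.
#' @param longAxis the long axis (default x).
#' @param axis the vertical axis (default z) used to orient sections.
#' @param searchSpan fractions of the +x half-extent to sweep.
#' @param nOffsets number of sweep positions.
#' @param flipSides,minTurn passed to [detectGrooveArcs()].
#' @return as [detectGrooveArcs()], for the best sweep position.
#' @export
locateGrooves <- function(mesh, longAxis = c(1, 0, 0), axis = c(0, 0, 1),
                          searchSpan = c(0.4, 0.95), nOffsets = 18,
                          flipSides = FALSE, minTurn = 8) {
  longAxis <- unitv(longAxis)
  xcoord <- as.vector(mesh@vertices %*% longAxis)
  # the head can sit at either end of the long axis (the inertial sign
  # convention does not know where the head is): sweep both ends
  fr <- seq(searchSpan[1], searchSpan[2], length.out = nOffsets)
  offs <- c(fr * max(xcoord), fr * min(xcoord))
  best <- NULL
  bestLen <- -Inf
  for (o in offs) {
    arcs <- try(suppressWarnings({
      sec <- sectionAt(mesh, axis = axis, angle = 0,
                       pivot = longAxis * o, baseNormal = longAxis)
      detectGrooveArcs(sec, flipSides = flipSides, minTurn = minTurn)
    }), silent = TRUE)
    if (inherits(arcs, "try-error")) next
    len <- arcs$medial$arcLength + arcs$lateral$arcLength
    if (len > bestLen) {
      bestLen <- len
      best <- arcs
    }
  }
  if (is.null(best))
    stop("no groove-bearing section found along the long axis")
  best
}

#' Parallelism test of the medial and lateral grooves
#'
#' The grooves are parallel when both attain their minimal curvature
#' diameter in the same cross-section, i.e. when the two scan angles
#' agree within `tolerance` degrees; otherwise they are dis-parallel.
#' Both fits must come from the same scan settings.
#'
#' @param medial,lateral [GrooveFit-class] objects for the two sides.
#' @param tolerance angular tolerance, degrees (default 0.5, one scan
#'   step).
#' @return a [ParallelismResult-class].
#' @examples
#' # angles (-2, -2) -> parallel; (-1, -3) -> dis_parallel
#' @export
parallelismTest <- function(medial, lateral, tolerance = 0.5) {
  stopifnot(is(medial, "GrooveFit"), is(lateral, "GrooveFit"))
  if (medial@side != "medial" || lateral@side != "lateral")
    stop("arguments must be the medial and lateral fits, in that order")
  if (tolerance < 0) stop("tolerance must be >= 0")
  s1 <- medial@settings; s2 <- lateral@settings
  cmp <- c("scan", "step", "angleRange", "axis", "baseNormal", "baseAngle")
  if (length(s1) && length(s2))
    for (k in cmp)
      if (!isTRUE(all.equal(s1[[k]], s2[[k]])))
        stop("mismatched scan settings between sides: ", k)
  dd <- medial@rotationAngle - lateral@rotationAngle
  new("ParallelismResult", medialFit = medial, lateralFit = lateral,
      angleDifference = dd,
      verdict = if (abs(dd) <= tolerance) "parallel" else "dis_parallel",
      tolerance = tolerance)
}

#' Construct a GrooveFit from known values
#'
#' Convenience constructor used when rotation angles and CDs come from
#' an external scan (e.g. a reported results table) and only the parallelism
#' verdict is needed.
#'
#' @param side "medial" or "lateral".
#' @param rotationAngle signed angle, degrees.
#' @param curvatureDiameter CD, mm.
#' @param settings optional scan settings list.
#' @return a [GrooveFit-class].
#' @export
grooveFit <- function(side, rotationAngle, curvatureDiameter,
                      settings = list()) {
  new("GrooveFit", side = side, rotationAngle = rotationAngle,
      circleCenter = c(0, 0), curvatureDiameter = curvatureDiameter,
      rmsResidual = 0, arcPoints = 5L, settings = settings)
}
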