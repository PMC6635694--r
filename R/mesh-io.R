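#' Read a bone surface mesh from STL, PLY or OBJ
#'
#' Loads a triangular surface mesh. STL is auto-detected as binary or
#' ASCII; PLY must be ASCII ("format ascii 1.0"); OBJ reads `v`/`f`
#' records (polygonal faces are fan-triangulated). Coordinates are
#' taken to be millimetres. The mesh is passed through the load-time
#' repair of [boneMesh()].
#'
#' @param path file path.
#' @param format one of "auto", "stl", "ply", "obj"; "auto" uses the
#'   file extension.
#' @param name label; defaults to the file base name.
#' @return a [BoneMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                     name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  m <- switch(format,
    stl = readSTL(path),
    ply = readPLY(path),
    obj = readOBJ(path))
  boneMesh(m$vertices, m$faces, name = name)
}

readSTL <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt)
  if (is_ascii) {
    # binary STL may also start with "solid": cross-check the size
    sz <- file.info(path)$size
    con <- file(path, "rb")
    hdr <- readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri)
      is_ascii <- FALSE
  }
  if (is_ascii) readSTLascii(path) else readSTLbinary(path)
}

readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("corrupt ASCII STL: no vertex records")
  nums <- strsplit(trimws(vl), "\\s+")
  V <- t(vapply(nums, function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(is.na(V)) || nrow(V) %% 3 != 0)
    stop("corrupt ASCII STL: malformed vertex records")
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

readSTLbinary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri <= 0 || sz < 84 + 50 * ntri)
    stop("corrupt binary STL: bad triangle count")
  rec <- readBin(con, "raw", 50 * ntri)
  dim(rec) <- c(50, ntri)
  coords <- rec[1:48, , drop = FALSE] # normal (12) + 3 vertices (36)
  vals <- readBin(as.vector(coords), "numeric", n = 12L * ntri, size = 4,
                  endian = "little")
  vals <- matrix(vals, nrow = 12) # columns = triangles
  V <- matrix(as.vector(vals[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("corrupt OBJ: missing v or f records")
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(is.na(V))) stop("corrupt OBJ: malformed vertex")
  tris <- list()
  for (ln in fl) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, character(1), 1))
    if (any(is.na(idx))) stop("corrupt OBJ: malformed face")
    idx[idx < 0] <- nrow(V) + idx[idx < 0] + 1L
    if (length(idx) < 3) stop("corrupt OBJ: face with < 3 vertices")
    for (k in seq_len(length(idx) - 2))
      tris[[length(tris) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  list(vertices = V, faces = do.call(rbind, tris))
}

readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("corrupt PLY: missing magic")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("corrupt PLY: no end_header")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported")
  els <- grep("^element ", header)
  getcount <- function(what) {
    ln <- grep(paste0("^element ", what), header, value = TRUE)
    if (!length(ln)) stop("corrupt PLY: no ", what, " element")
    as.integer(strsplit(ln, "\\s+")[[1]][3])
  }
  nv <- getcount("vertex")
  nf <- getcount("face")
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vtok, function(x) as.numeric(x[1:3]), numeric(3)))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tris <- list()
  for (tok in ftok) {
    n <- as.integer(tok[1])
    idx <- as.integer(tok[1 + seq_len(n)]) + 1L # PLY is 0-based
    for (k in seq_len(n - 2))
      tris[[length(tris) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  list(vertices = V, faces = do.call(rbind, tris))
}

#' Write a mesh to STL (ASCII or binary), PLY (ASCII) or OBJ
#'
#' @param mesh a [BoneMesh-class].
#' @param path output file; the extension picks the format unless
#'   `format` is given.
#' @param format "auto", "stl", "stl_binary", "ply" or "obj".
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path,
                      format = c("auto", "stl", "stl_binary", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj"))
      stop("cannot infer output format for '", path, "'")
  }
  V <- mesh@vertices; F <- mesh@faces
  switch(format,
    stl = {
      a <- V[F[, 1], , drop = FALSE]
      b <- V[F[, 2], , drop = FALSE]
      cc <- V[F[, 3], , drop = FALSE]
      e1 <- b - a; e2 <- cc - a
      n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
      txt <- c(sprintf("solid %s", mesh@name),
               sprintf(paste0(" facet normal %.9g %.9g %.9g\n",
                              "  outer loop\n",
                              "   vertex %.12g %.12g %.12g\n",
                              "   vertex %.12g %.12g %.12g\n",
                              "   vertex %.12g %.12g %.12g\n",
                              "  endloop\n endfacet"),
                       n[, 1], n[, 2], n[, 3],
                       a[, 1], a[, 2], a[, 3],
                       b[, 1], b[, 2], b[, 3],
                       cc[, 1], cc[, 2], cc[, 3]),
               sprintf("endsolid %s", mesh@name))
      writeLines(txt, path)
    },
    stl_binary = {
      con <- file(path, "wb")
      on.exit(close(con))
      hdr <- charToRaw(sprintf("%-80s", "binary STL"))[1:80]
      writeBin(hdr, con)
      writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
      a <- V[F[, 1], , drop = FALSE]
      b <- V[F[, 2], , drop = FALSE]
      cc <- V[F[, 3], , drop = FALSE]
      for (i in seq_len(nrow(F))) {
        nrm <- cross3(b[i, ] - a[i, ], cc[i, ] - a[i, ])
        nn <- vnorm(nrm)
        if (nn > 0) nrm <- nrm / nn
        writeBin(as.numeric(c(nrm, a[i, ], b[i, ], cc[i, ])), con,
                 size = 4, endian = "little")
        writeBin(as.raw(c(0, 0)), con)
      }
    },
    ply = {
      hdr <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header")
      vtxt <- sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3])
      ftxt <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
      writeLines(c(hdr, vtxt, ftxt), path)
    },
    obj = {
      vtxt <- sprintf("v %.12g %.12g %.12g", V[, 1], V[, 2], V[, 3])
      ftxt <- sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])
      writeLines(c(vtxt, ftxt), path)
    })
  invisible(path)
}
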