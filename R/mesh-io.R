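#' Read a triangle mesh from OFF, OBJ, PLY or STL
#'
#' PLY is supported in ascii and binary-little-endian flavors, STL in ascii
#' and binary. STL soups are welded (duplicate vertices within
#' 1e-8 x bounding-box diagonal merged) so the undirected edge set is
#' well-defined. OFF/OBJ index-base quirks are absorbed here; internally all
#' indices are 1-based.
#'
#' @param path file path.
#' @param format one of `"auto"` (from the file extension), `"off"`, `"obj"`,
#'   `"ply"`, `"stl"`.
#' @return a [TriangleMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "off", "obj", "ply", "stl")) {
  format <- match.arg(format)
  if (!file.exists(path)) .iostop("cannot read mesh: no such file '%s'", path)
  if (file.size(path) == 0) .iostop("cannot read mesh: empty file '%s'", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("off", "obj", "ply", "stl"))
      .iostop("cannot infer mesh format from extension '%s'", ext)
    format <- ext
  }
  switch(format,
         off = .readOFF(path),
         obj = .readOBJ(path),
         ply = .readPLY(path),
         stl = .readSTL(path))
}

.numTokens <- function(line) {
  as.numeric(strsplit(trimws(line), "[[:space:]]+")[[1L]])
}

.readOFF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .iostop("empty OFF file '%s'", path)
  first <- trimws(lines[[1L]])
  if (toupper(first) == "OFF") {
    lines <- lines[-1L]
  } else if (grepl("^OFF", toupper(first))) {
    lines[[1L]] <- sub("^[Oo][Ff][Ff]", "", first)
    lines <- lines[nzchar(trimws(lines))]
  } else .iostop("'%s' is not an OFF file (missing OFF header)", path)
  counts <- .numTokens(lines[[1L]])
  nv <- counts[[1L]]; nf <- counts[[2L]]
  if (length(lines) < 1L + nv + nf) .iostop("truncated OFF file '%s'", path)
  vtx <- t(vapply(lines[1L + seq_len(nv)],
                  function(l) .numTokens(l)[1:3], numeric(3L)))
  flines <- lines[1L + nv + seq_len(nf)]
  fl <- lapply(flines, .numTokens)
  sizes <- vapply(fl, function(x) x[[1L]], numeric(1L))
  if (any(sizes != 3))
    .vstop("non-triangular face in OFF file at face %d (%d vertices)",
           which(sizes != 3)[1L], sizes[sizes != 3][1L])
  faces <- t(vapply(fl, function(x) x[2:4], numeric(3L))) + 1
  triangleMesh(vtx, faces)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines))
    .iostop("'%s' has no usable OBJ v/f records", path)
  vtx <- t(vapply(vlines, function(l) .numTokens(substring(l, 2L))[1:3],
                  numeric(3L)))
  faces <- lapply(flines, function(l) {
    toks <- strsplit(trimws(substring(l, 2L)), "[[:space:]]+")[[1L]]
    as.integer(sub("/.*$", "", toks))
  })
  sizes <- lengths(faces)
  if (any(sizes != 3L))
    .vstop("non-triangular face in OBJ file at face %d (%d vertices)",
           which(sizes != 3L)[1L], sizes[sizes != 3L][1L])
  faces <- do.call(rbind, faces)
  neg <- faces < 0L
  if (any(neg)) faces[neg] <- nrow(vtx) + 1L + faces[neg]
  triangleMesh(vtx, faces)
}

.plyTypeSize <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.plyReadScalar <- function(raw, off, type) {
  sz <- .plyTypeSize[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")
  readBin(raw[(off + 1L):(off + sz)], what = what, size = sz, n = 1L,
          endian = "little", signed = if (sz < 4L) signed else TRUE)
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) .iostop("truncated PLY header in '%s'", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!identical(trimws(header[[1L]]), "ply"))
    .iostop("'%s' is not a PLY file", path)
  fmtline <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(trimws(fmtline[[1L]]), "[[:space:]]+")[[1L]][[2L]]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    .iostop("unsupported PLY format '%s'", fmt)

  # parse elements & properties
  elements <- list()
  cur <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (toks[[1L]] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[[2L]], count = as.integer(toks[[3L]]),
                  props = list())
    } else if (toks[[1L]] == "property" && !is.null(cur)) {
      if (toks[[2L]] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[[5L]], type = "list",
               countType = toks[[3L]], itemType = toks[[4L]])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[[3L]], type = toks[[2L]])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    .iostop("PLY file '%s' lacks vertex/face elements", path)

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(rest) < nv + nf) .iostop("truncated PLY body in '%s'", path)
    vprops <- vapply(elements$vertex$props, function(p) p$name, "")
    xyz <- match(c("x", "y", "z"), vprops)
    if (anyNA(xyz)) .iostop("PLY vertex element lacks x/y/z in '%s'", path)
    vtx <- t(vapply(rest[seq_len(nv)],
                    function(l) .numTokens(l)[xyz], numeric(3L)))
    fl <- lapply(rest[nv + seq_len(nf)], .numTokens)
    sizes <- vapply(fl, function(x) x[[1L]], numeric(1L))
    if (any(sizes != 3))
      .vstop("non-triangular face in PLY file at face %d (%d vertices)",
             which(sizes != 3)[1L], sizes[sizes != 3][1L])
    faces <- t(vapply(fl, function(x) x[2:4], numeric(3L))) + 1
    return(triangleMesh(vtx, faces))
  }

  # binary little endian
  raw <- readBin(con, "raw", n = file.size(path))
  off <- 0L
  out <- list()
  for (el in elements) {
    props <- el$props
    fixed <- all(vapply(props, function(p) p$type != "list", TRUE))
    if (fixed) {
      sizes <- vapply(props, function(p) .plyTypeSize[[p$type]], 1L)
      stride <- sum(sizes)
      types <- vapply(props, function(p) p$type, "")
      vals <- matrix(NA_real_, el$count, length(props))
      if (length(unique(types)) == 1L && el$count > 0L) {
        tp <- types[[1L]]
        sz <- .plyTypeSize[[tp]]
        what <- if (tp %in% c("float", "float32", "double", "float64"))
          "double" else "integer"
        block <- readBin(raw[(off + 1L):(off + el$count * stride)],
                         what = what, size = sz, n = el$count * length(props),
                         endian = "little")
        vals <- matrix(block, el$count, length(props), byrow = TRUE)
        off <- off + el$count * stride
      } else {
        for (i in seq_len(el$count)) {
          o <- off
          for (j in seq_along(props)) {
            vals[i, j] <- .plyReadScalar(raw, o, props[[j]]$type)
            o <- o + sizes[[j]]
          }
          off <- off + stride
        }
      }
      colnames(vals) <- vapply(props, function(p) p$name, "")
      out[[el$name]] <- vals
    } else {
      # assume single list property (vertex_indices) possibly followed by
      # fixed scalars (e.g. face colors)
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- list()
        for (p in props) {
          if (p$type == "list") {
            cnt <- .plyReadScalar(raw, off, p$countType)
            off <- off + .plyTypeSize[[p$countType]]
            items <- numeric(cnt)
            for (k in seq_len(cnt)) {
              items[[k]] <- .plyReadScalar(raw, off, p$itemType)
              off <- off + .plyTypeSize[[p$itemType]]
            }
            vals[[p$name]] <- items
          } else {
            vals[[p$name]] <- .plyReadScalar(raw, off, p$type)
            off <- off + .plyTypeSize[[p$type]]
          }
        }
        rows[[i]] <- vals
      }
      out[[el$name]] <- rows
    }
  }
  vtx <- out$vertex[, c("x", "y", "z"), drop = FALSE]
  fl <- lapply(out$face, function(r) r[["vertex_indices"]] %||% r[[1L]])
  sizes <- lengths(fl)
  if (any(sizes != 3L))
    .vstop("non-triangular face in PLY file at face %d (%d vertices)",
           which(sizes != 3L)[1L], sizes[sizes != 3L][1L])
  faces <- do.call(rbind, fl) + 1
  triangleMesh(vtx, faces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.weldVertices <- function(coords, tol) {
  q <- round(coords / tol)
  key <- paste(q[, 1L], q[, 2L], q[, 3L])
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = coords[first, , drop = FALSE], map = map)
}

.readSTL <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80L, sz))
  isAscii <- FALSE
  if (sz >= 84L) {
    ntri <- readBin(con, "integer", size = 4L, n = 1L, endian = "little")
    if (length(ntri) == 1L && !is.na(ntri) && ntri > 0 &&
        isTRUE(84 + 50 * as.numeric(ntri) == sz)) {
      # 50-byte records: 12 float32 + uint16 attribute; strip the spacers
      rawAll <- readBin(con, "raw", n = 50L * ntri)
      idx <- rep(seq(0L, by = 50L, length.out = ntri), each = 48L) +
        rep(1:48, times = ntri)
      floats <- readBin(rawAll[idx], "double", size = 4L, n = 12L * ntri,
                        endian = "little")
      m <- matrix(floats, ncol = 12L, byrow = TRUE)
      coords <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                      m[, 10:12, drop = FALSE])
      ord <- as.vector(t(matrix(seq_len(3L * ntri), ntri, 3L)))
      coords <- coords[ord, , drop = FALSE]
      return(.stlSoupToMesh(coords))
    }
    isAscii <- TRUE
  } else isAscii <- TRUE
  if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^[[:space:]]*vertex[[:space:]]", txt, value = TRUE)
    if (!length(vlines)) .iostop("'%s' is not a readable STL file", path)
    coords <- t(vapply(vlines, function(l) {
      .numTokens(sub("^[[:space:]]*vertex", "", l))[1:3]
    }, numeric(3L)))
    if (nrow(coords) %% 3L != 0L) .iostop("truncated ascii STL '%s'", path)
    return(.stlSoupToMesh(coords))
  }
}

.stlSoupToMesh <- function(coords) {
  bb <- apply(coords, 2L, range)
  diag <- sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  tol <- max(1e-8 * diag, .Machine$double.xmin)
  w <- .weldVertices(coords, tol)
  faces <- matrix(w$map, ncol = 3L, byrow = TRUE)
  triangleMesh(w$vertices, faces)
}

#' Write a triangle mesh (OFF, OBJ or ascii PLY)
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path; the format is taken from the extension.
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh@vertices
  f <- mesh@faces
  if (ext == "off") {
    lines <- c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else if (ext == "ply") {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  } else .iostop("unsupported output mesh format '%s'", ext)
  writeLines(lines, path)
  invisible(path)
}

# fixed label -> RGB palette; label 0 (gingiva/rest) is grey
.labelPalette <- function(labels) {
  pal <- rbind(c(160, 160, 160),
               c(228, 26, 28), c(55, 126, 184), c(77, 175, 74),
               c(152, 78, 163), c(255, 127, 0), c(255, 255, 51),
               c(166, 86, 40), c(247, 129, 191), c(0, 139, 139),
               c(102, 0, 102), c(0, 102, 51), c(204, 102, 0),
               c(51, 51, 153), c(153, 0, 51), c(0, 153, 153))
  idx <- ifelse(labels == 0L, 1L, 2L + (labels - 1L) %% (nrow(pal) - 1L))
  pal[idx, , drop = FALSE]
}

#' Write a segmented mesh as colored PLY plus a JSON label map
#'
#' Writes an ascii PLY with per-face uchar RGB from a fixed label palette and
#' a sidecar JSON (`<path>.json`) mapping each label to its color and face
#' count. The PLY round-trips through [readMesh()] with identical vertex and
#' face arrays (color properties are ignored on read).
#'
#' @param mesh a [TriangleMesh-class].
#' @param faceLabels integer label per face (0 = rest, k >= 1 = tooth k).
#' @param path output PLY path.
#' @return the path, invisibly.
#' @export
writeSegmentedMesh <- function(mesh, faceLabels, path) {
  faceLabels <- as.integer(faceLabels)
  if (length(faceLabels) != nrow(mesh@faces))
    .vstop("faceLabels length %d does not match face count %d",
           length(faceLabels), nrow(mesh@faces))
  v <- mesh@vertices
  f <- mesh@faces
  rgb <- .labelPalette(faceLabels)
  lines <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices",
             "property uchar red", "property uchar green", "property uchar blue",
             "end_header",
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d %d %d %d",
                     f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L,
                     rgb[, 1], rgb[, 2], rgb[, 3]))
  writeLines(lines, path)
  labs <- sort(unique(faceLabels))
  meta <- lapply(labs, function(l) {
    col <- .labelPalette(l)[1L, ]
    list(label = l, color = sprintf("#%02X%02X%02X", col[1], col[2], col[3]),
         faces = sum(faceLabels == l))
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
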