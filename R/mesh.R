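## Triangle meshes: container + validation, generated primitives, PLY/STL IO.
## Vertices are always N x 3 in millimetres; faces are M x 3 one-based vertex
## indices in R (stored zero-based on disk).

MIN_FACE_AREA <- 1e-12   # mm^2; smaller faces are rejected at construction

#' Construct a triangle mesh
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of one-based vertex indices.
#' @param name optional mesh name.
#' @return An object of class `triangle_mesh`.
#' @details All face indices must lie in `[1, N]` and every face must have
#'   area >= 1e-12 mm^2; violations are errors (degenerate geometry breaks
#'   distance and rasterization queries downstream).
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("triangle_mesh: vertices must be N x 3", call. = FALSE)
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("triangle_mesh: faces must be M x 3", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop(errorCondition("triangle_mesh: face index out of range",
                          class = c("sl_error_mesh_invalid", "error", "condition")))
    a <- vertices[faces[, 1], , drop = FALSE]
    ab <- vertices[faces[, 2], , drop = FALSE] - a
    ac <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
    area2 <- sqrt(rowSums(cr^2)) / 2
    if (any(area2 < MIN_FACE_AREA))
      stop(errorCondition(sprintf("triangle_mesh: %d zero-area face(s)",
                                  sum(area2 < MIN_FACE_AREA)),
                          class = c("sl_error_mesh_invalid", "error", "condition")))
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Apply a rigid transform to a mesh
#' @param mesh a `triangle_mesh`.
#' @param transform a `rigid_transform`.
#' @export
mesh_transform <- function(mesh, transform) {
  stopifnot(is_triangle_mesh(mesh))
  triangle_mesh(rt_apply(transform, mesh$vertices), mesh$faces, mesh$name)
}

#' Is a mesh watertight?
#'
#' A mesh is treated as watertight (closed, manifold) when every undirected
#' edge is shared by exactly two faces.  Containment queries require this.
#'
#' @param mesh a `triangle_mesh`.
#' @return logical(1).
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## ---------------------------------------------------------------- primitives

## Remove duplicate vertices (exact match after rounding to `digits`), remap
## faces.  Used by primitive generators only; IO never welds.
mesh_weld <- function(vertices, faces, digits = 9) {
  key <- apply(round(vertices, digits), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])   # original row -> index in the deduped set
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3))
}

#' Generate an icosphere
#'
#' Subdivided icosahedron with all vertices on the sphere.  Subdivision 4
#' (5120 faces) is the default anatomy primitive: its maximal chord error
#' (sagitta) is what distance oracles use as tolerance, see
#' [icosphere_chord_tolerance()].
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 4-way subdivision passes.
#' @param center numeric(3) sphere centre, mm.
#' @param name mesh name.
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 4, center = c(0, 0, 0),
                           name = "icosphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    newv <- v; newf <- matrix(0L, nf * 4, 3)
    midcache <- new.env(hash = TRUE)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(m <- midcache[[key]])) return(m)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv <<- rbind(newv, p)
      midcache[[key]] <- nrow(newv)
      nrow(newv)
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- newv; f <- newf
  }
  triangle_mesh(sweep(v * radius, 2, center, "+"), f, name)
}

#' Chord-height (sagitta) tolerance of an icosphere
#'
#' Maximum distance between the true sphere surface and the inscribed
#' polyhedron, computed from the actual mesh: `radius - min distance of face
#' centroids to the centre`.
#'
#' @param mesh an icosphere `triangle_mesh`.
#' @param center,radius the generating sphere.
#' @export
icosphere_chord_tolerance <- function(mesh, center, radius) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cen <- sweep((a + b + c3) / 3, 2, center, "-")
  radius - min(sqrt(rowSums(cen^2)))
}

#' Generate a closed tube (capped cylinder)
#'
#' @param radius tube radius, mm.
#' @param length tube length along the axis, mm.
#' @param center numeric(3) tube centre, mm.
#' @param axis numeric(3) tube axis direction.
#' @param segments angular resolution.
#' @param name mesh name.
#' @export
mesh_tube <- function(radius = 1, length = 10, center = c(0, 0, 0),
                      axis = c(0, 0, 1), segments = 32, name = "tube") {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- outer(cos(th), u) + outer(sin(th), w)
  lo <- sweep(ring * radius, 2, center - axis * length / 2, "+")
  hi <- sweep(ring * radius, 2, center + axis * length / 2, "+")
  v <- rbind(lo, hi, center - axis * length / 2, center + axis * length / 2)
  nb <- segments + segments + 1L  # index of bottom centre
  nt <- nb + 1L
  f <- NULL
  for (i in seq_len(segments)) {
    j <- if (i == segments) 1L else i + 1L
    f <- rbind(f,
               c(i, j, segments + i), c(j, segments + j, segments + i),
               c(nb, j, i),                       # bottom cap (faces -axis)
               c(nt, segments + i, segments + j)) # top cap (faces +axis)
  }
  triangle_mesh(v, f, name)
}

#' Generate an axis-aligned box
#' @param size numeric(3) edge lengths, mm.
#' @param center numeric(3) box centre, mm.
#' @param name mesh name.
#' @export
mesh_box <- function(size = c(1, 1, 1), center = c(0, 0, 0), name = "box") {
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8), 2, center, "+")
  ## outward-facing CCW triangles for the 1..8 corner order above
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z-
             c(5, 6, 7), c(6, 8, 7),   # z+
             c(1, 2, 5), c(2, 6, 5),   # y-
             c(3, 7, 4), c(4, 7, 8),   # y+
             c(1, 5, 3), c(3, 5, 7),   # x-
             c(2, 4, 6), c(4, 8, 6))   # x+
  triangle_mesh(v, f, name)
}

#' Generate a capsule (cylinder with hemispherical caps)
#'
#' Used as the default instrument-shaft proxy when no shaft mesh is supplied.
#' The capsule spans the segment from `p0` to `p1` with the given radius.
#' The cylinder body is split into rings roughly `body_step` mm apart so the
#' rasterizer never sees extremely elongated triangles.
#'
#' @param p0,p1 numeric(3) segment end points, mm (`p1` is the tip end).
#' @param radius capsule radius, mm.
#' @param segments angular resolution.
#' @param rings latitudinal resolution of each hemispherical cap.
#' @param body_step approximate body ring spacing, mm.
#' @param name mesh name.
#' @export
mesh_capsule <- function(p0, p1, radius, segments = 24, rings = 4,
                         body_step = 10, name = "capsule") {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-9) return(mesh_icosphere(radius, 2, p0, name))
  axis <- d / len
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  circ <- outer(cos(th), u) + outer(sin(th), w)    # segments x 3 unit ring
  ## ring profile along the axis: cap at p0, body, cap at p1
  lat <- seq(-pi / 2, 0, length.out = rings + 1)[-1]
  nb <- max(1L, ceiling(len / body_step))
  body_u <- seq(0, 1, length.out = nb + 1L)[-c(1, nb + 1L)]
  centers <- rbind(
    matrix(p0, length(lat), 3, byrow = TRUE) + outer(radius * sin(lat), axis),
    matrix(p0, length(body_u), 3, byrow = TRUE) + outer(body_u * len, axis),
    matrix(p1, length(lat), 3, byrow = TRUE) + outer(radius * sin(rev(-lat)), axis))
  radii <- c(radius * cos(lat), rep(radius, length(body_u)),
             radius * cos(rev(-lat)))
  nring <- length(radii)
  v <- do.call(rbind, lapply(seq_len(nring), function(r)
    circ * radii[r] + matrix(centers[r, ], segments, 3, byrow = TRUE)))
  south <- nring * segments + 1L; north <- south + 1L
  v <- rbind(v, p0 - axis * radius, p1 + axis * radius)
  i <- seq_len(segments)
  j <- c(i[-1], 1L)
  idx <- function(r) (r - 1L) * segments
  strips <- do.call(rbind, lapply(seq_len(nring - 1L), function(r)
    rbind(cbind(idx(r) + i, idx(r) + j, idx(r + 1) + i),
          cbind(idx(r) + j, idx(r + 1) + j, idx(r + 1) + i))))
  f <- rbind(cbind(south, idx(1) + j, idx(1) + i),
             strips,
             cbind(north, idx(nring) + i, idx(nring) + j))
  triangle_mesh(v, f, name)
}

## ------------------------------------------------------------------- PLY IO

#' Read a PLY mesh
#'
#' Supports ASCII and binary little-endian PLY with float or double vertex
#' properties and list-typed face indices.  Extra properties are ignored.
#'
#' @param path file path.
#' @param name mesh name (defaults to the file stem).
#' @export
read_ply <- function(path, name = NULL) {
  if (!file.exists(path))
    stop(errorCondition(paste("read_ply: no such file:", path),
                        class = c("sl_error_missing_file", "error", "condition")))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character(); repeat {
    ln <- readLines(con, 1L, warn = FALSE)
    if (length(ln) == 0L) stop("read_ply: truncated header", call. = FALSE)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  if (hdr[1] != "ply") stop("read_ply: not a PLY file", call. = FALSE)
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  fmt <- strsplit(fmt, " ")[[1]][1]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("read_ply: unsupported format: ", fmt, call. = FALSE)

  ## parse element/property declarations
  elements <- list(); cur <- NULL
  for (ln in hdr) {
    w <- strsplit(trimws(ln), "\\s+")[[1]]
    if (w[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = w[2], count = as.integer(w[3]), props = list())
    } else if (w[1] == "property" && !is.null(cur)) {
      if (w[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = w[5], list = TRUE, ctype = w[3], vtype = w[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = w[3], list = FALSE, vtype = w[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("read_ply: missing vertex or face element", call. = FALSE)

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4,
                 double = 8, float64 = 8)
  read_bin_scalar <- function(type, n = 1L) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n, size = sz, endian = "little")
    else
      readBin(con, "integer", n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  verts <- NULL; faces <- NULL
  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    pos <- 1L
    for (el in elements) {
      vals <- lines[pos:(pos + el$count - 1L)]; pos <- pos + el$count
      toks <- strsplit(trimws(vals), "\\s+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        m <- do.call(rbind, lapply(toks, as.numeric))
        verts <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(toks, function(tk) {
          n <- as.integer(tk[1])
          if (n != 3L) stop("read_ply: non-triangular face", call. = FALSE)
          as.integer(tk[2:4])
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        types <- vapply(el$props, `[[`, "", "vtype")
        if (length(unique(types)) == 1L && !any(vapply(el$props, `[[`, TRUE, "list"))) {
          m <- matrix(read_bin_scalar(types[1], el$count * length(pn)),
                      ncol = length(pn), byrow = TRUE)
        } else {
          m <- matrix(0, el$count, length(pn))
          for (i in seq_len(el$count))
            for (j in seq_along(el$props))
              m[i, j] <- read_bin_scalar(types[j])
        }
        verts <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        faces <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          n <- read_bin_scalar(p$ctype)
          if (n != 3L) stop("read_ply: non-triangular face", call. = FALSE)
          faces[i, ] <- read_bin_scalar(p$vtype, 3L)
        }
      }
    }
  }
  triangle_mesh(verts, faces + 1L, name)
}

#' Write a PLY mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"binary_little_endian"` (default; vertices stored as
#'   doubles, lossless) or `"ascii"`.
#' @export
write_ply <- function(mesh, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  stopifnot(is_triangle_mesh(mesh))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", paste("format", format, "1.0"),
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (format == "ascii") {
    writeLines(apply(mesh$vertices, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con, sep = "\n")
    writeLines(apply(mesh$faces - 1L, 1L, function(r)
      paste(c(3L, r), collapse = " ")), con, sep = "\n")
  } else {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    fm <- t(cbind(3L, mesh$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read an STL mesh (read-only)
#'
#' Binary and ASCII STL.  Duplicate vertices are welded exactly so the result
#' can support watertightness checks.
#'
#' @param path file path.
#' @param name mesh name (defaults to the file stem).
#' @export
read_stl <- function(path, name = NULL) {
  if (!file.exists(path))
    stop(errorCondition(paste("read_stl: no such file:", path),
                        class = c("sl_error_missing_file", "error", "condition")))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  head <- readBin(path, "raw", 512)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0))
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- grep("^vertex ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(w) as.numeric(w[2:4])))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    v <- matrix(0, ntri * 3L, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", 12, size = 4, endian = "little")
      v[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  }
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  wd <- mesh_weld(v, f)
  triangle_mesh(wd$vertices, wd$faces, name)
}
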