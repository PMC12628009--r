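## Point-mesh distance and containment queries.
##
## Distances are unsigned; "inside" is a separate predicate (anatomy meshes
## may be open, so signed distance is ill-defined in general).  The collision
## predicate used by the event rules is
##   (mesh_distance <= contact tolerance) OR point_in_mesh.

#' Exact point-to-triangle distance
#'
#' Unsigned Euclidean distance from a point to a triangle via barycentric
#' region classification, with the closest point on the triangle.
#'
#' @param p numeric(3) query point, mm.
#' @param a,b,c numeric(3) triangle vertices, mm.
#' @return `list(distance, closest_point)`.
#' @export
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  if (sqrt(sum(cr^2)) / 2 < MIN_FACE_AREA)
    stop(errorCondition("point_triangle_distance: degenerate triangle",
                        class = c("sl_error_degenerate", "error", "condition")))
  cpp_point_triangle_distance(as.numeric(p), as.numeric(a),
                              as.numeric(b), as.numeric(c))
}

#' Minimum distance from point(s) to a mesh
#'
#' Minimum over all faces.  `method = "accel"` prunes faces with per-face
#' bounding-box lower bounds; by contract it returns results identical to
#' `method = "brute"` (exhaustive scan).
#'
#' @param p numeric(3) point or N x 3 matrix of points, mm.
#' @param mesh a `triangle_mesh`.
#' @param method `"accel"` (default) or `"brute"`.
#' @return For a single point: `list(distance, face, closest_point)`; for a
#'   matrix: `list(distance (N), face (N), closest_point (N x 3))`.
#' @export
mesh_distance <- function(p, mesh, method = c("accel", "brute")) {
  method <- match.arg(method)
  stopifnot(is_triangle_mesh(mesh))
  if (nrow(mesh$faces) == 0L)
    stop(errorCondition("mesh_distance: empty mesh",
                        class = c("sl_error_empty_mesh", "error", "condition")))
  single <- !is.matrix(p)
  pm <- if (single) matrix(as.numeric(p), 1, 3) else as.matrix(p)
  res <- cpp_mesh_distance(pm, mesh$vertices, mesh$faces - 1L,
                           method == "accel")
  if (single)
    list(distance = res$distance[1], face = res$face[1],
         closest_point = as.numeric(res$closest_point[1, ]))
  else res
}

#' Point-in-mesh containment test
#'
#' Ray-crossing parity with a fixed ray direction; intersections that graze
#' a triangle edge or vertex trigger a deterministic retry with a perturbed
#' direction.  Requires a watertight mesh.
#'
#' @param p numeric(3) point or N x 3 matrix, mm.
#' @param mesh a watertight `triangle_mesh`.
#' @param check_watertight verify closedness first (skippable when the
#'   caller already knows, e.g. generated primitives).
#' @return logical, TRUE iff strictly inside.
#' @export
point_in_mesh <- function(p, mesh, check_watertight = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  if (check_watertight && !mesh_is_watertight(mesh))
    stop(errorCondition("point_in_mesh: mesh is not watertight; containment unsupported",
                        class = c("sl_error_not_watertight", "error", "condition")))
  single <- !is.matrix(p)
  pm <- if (single) matrix(as.numeric(p), 1, 3) else as.matrix(p)
  res <- cpp_point_in_mesh(pm, mesh$vertices, mesh$faces - 1L)
  if (single) res[1] else res
}

#' Generalized winding number of a point w.r.t. a mesh
#'
#' Sum of signed solid angles subtended by the faces, divided by 4*pi
#' (van Oosterom & Strackee).  For a watertight mesh this is ~1 inside and
#' ~0 outside; it serves as the independent containment oracle for
#' [point_in_mesh()].
#'
#' @param p numeric(3) query point, mm.
#' @param mesh a `triangle_mesh`.
#' @return numeric(1) winding number.
#' @export
winding_number <- function(p, mesh) {
  stopifnot(is_triangle_mesh(mesh))
  v <- mesh$vertices; f <- mesh$faces
  a <- sweep(v[f[, 1], , drop = FALSE], 2, p)
  b <- sweep(v[f[, 2], , drop = FALSE], 2, p)
  c3 <- sweep(v[f[, 3], , drop = FALSE], 2, p)
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c3^2))
  det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c3) * lb +
         rowSums(b * c3) * la
  sum(2 * atan2(det, den)) / (4 * pi)
}

#' Collision predicate
#'
#' An instrument tip "collides" with a structure when its unsigned mesh
#' distance is at or below `tolerance` or the tip lies inside the mesh.
#'
#' @param p numeric(3) point, mm.
#' @param mesh a `triangle_mesh`.
#' @param tolerance contact tolerance, mm.
#' @export
check_collision <- function(p, mesh, tolerance = 1) {
  d <- mesh_distance(p, mesh)$distance
  if (d <= tolerance) return(TRUE)
  if (mesh_is_watertight(mesh)) point_in_mesh(p, mesh, check_watertight = FALSE)
  else FALSE
}
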