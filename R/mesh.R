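#' @title Triangle mesh container
#' @description
#' `triangle_mesh()` builds the package's surface-mesh container: a numeric
#' vertex matrix, an integer face matrix of vertex-index triples, and a free
#' text name.  All coordinates are interpreted as millimetres by contract;
#' no unit autodetection is performed.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name free-text identifier carried through reports.
#' @param validate if `TRUE` (default) enforce the container invariants.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh", validate = TRUE) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3,
                  dimnames = NULL)
  m <- structure(list(vertices = vertices, faces = faces,
                      name = as.character(name)[1]),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

#' Validate a triangle mesh
#'
#' Checks the container invariants: finite coordinates, in-range face
#' indices, and at least 4 vertices and 4 faces (the smallest closed
#' surface, a tetrahedron).
#'
#' @param mesh a `triangle_mesh`.
#' @param min_faces minimum accepted face count (4 for measurement use;
#'   I/O round-trip tolerates smaller via `min_faces = 1`).
#' @return `mesh`, invisibly.
#' @export
validate_mesh <- function(mesh, min_faces = 4L) {
  if (!inherits(mesh, "triangle_mesh"))
    stop("not a triangle_mesh", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(v)))
    stop("mesh '", mesh$name, "': non-finite vertex coordinate",
         call. = FALSE)
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("faces must be an n x 3 matrix", call. = FALSE)
  if (nrow(f) < min_faces || nrow(v) < min(4L, min_faces + 2L))
    stop("mesh '", mesh$name, "': too small (", nrow(v), " vertices, ",
         nrow(f), " faces)", call. = FALSE)
  if (anyNA(f) || min(f) < 1L || max(f) > nrow(v))
    stop("mesh '", mesh$name, "': face index out of range", call. = FALSE)
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh '", x$name, "': ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Per-face unit normals and areas
#'
#' Outward orientation follows the stored winding order (counter-clockwise
#' seen from outside, the STL convention).
#'
#' @param mesh a `triangle_mesh`.
#' @return list with `normals` (F x 3, unit length; zero rows for
#'   degenerate faces) and `areas` (length F, mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  normals <- cr / ifelse(nrm > 0, nrm, 1)
  list(normals = normals, areas = nrm / 2)
}

#' Merge duplicate vertices
#'
#' Collapses vertices that coincide within `tol` (1e-6 mm by default, the
#' I/O round-trip contract) and reindexes the faces.  Needed because STL
#' stores each facet's corners independently.
#'
#' @param vertices n x 3 coordinate matrix.
#' @param faces face index matrix referring to `vertices`.
#' @param tol merge tolerance in mm.
#' @return list with deduplicated `vertices` and reindexed `faces`.
#' @keywords internal
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3))
}

#' Check that every edge is shared by exactly two faces
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` for a closed 2-manifold edge structure.
#' @export
is_closed_manifold <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

as_point_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  dimnames(x) <- list(rownames(x), c("x", "y", "z"))
  x
}
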