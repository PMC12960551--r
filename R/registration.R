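#' Rigid transform container
#'
#' A proper rigid motion `p -> R p + t`.  The rotation must be orthonormal
#' with determinant +1 within 1e-9.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not a proper orthonormal matrix", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points n x 3 matrix or length-3 vector.
#' @return transformed points, same shape as input.
#' @export
transform_points <- function(t, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(t$rotation) +
    matrix(t$translation, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*%
                                               t$translation))
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform`s.
#' @return `rigid_transform` equal to applying `b` first, then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) +
                    a$translation)
}

#' Build the anatomical foot frame from plantar landmarks
#'
#' The three plantar landmarks (HEEL, MT1, MT5) define the plantar plane.
#' The heel is the origin; the longitudinal Y axis is the in-plane unit
#' component of heel -> midpoint(MT1, MT5); the vertical Z axis is the
#' plane normal oriented dorsally (towards ARCH, falling back to the
#' malleoli midpoint); the mediolateral X axis completes the right-handed
#' frame as Y x Z, pointing from MT1 towards MT5.
#'
#' @param lms a [landmark_set] containing at least HEEL, MT1, MT5 and one
#'   dorsal disambiguation point (ARCH or both malleoli).
#' @return object of class `foot_frame`: list with `origin`, `x_axis`,
#'   `y_axis`, `z_axis`.
#' @export
build_foot_frame <- function(lms) {
  heel <- landmark(lms, "HEEL")
  mt1 <- landmark(lms, "MT1")
  mt5 <- landmark(lms, "MT5")
  u <- mt1 - heel
  v <- mt5 - heel
  n <- cross3(u, v)
  # non-collinearity guard: triangle area > 1 mm^2
  if (sqrt(sum(n^2)) / 2 <= 1)
    stop("degenerate plantar landmarks (collinear or coincident: ",
         "triangle area <= 1 mm^2)", call. = FALSE)
  z <- n / sqrt(sum(n^2))
  dorsal <- if (has_landmark(lms, "ARCH")) {
    landmark(lms, "ARCH")
  } else if (has_malleoli(lms)) {
    (landmark(lms, "MED_MAL") + landmark(lms, "LAT_MAL")) / 2
  } else {
    stop("cannot orient dorsal direction: need ARCH or both malleoli",
         call. = FALSE)
  }
  if (sum(z * (dorsal - heel)) < 0) z <- -z
  mid <- (mt1 + mt5) / 2
  yraw <- mid - heel
  y <- yraw - sum(yraw * z) * z          # in-plane component
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9)
    stop("degenerate frame: heel lies under the metatarsal midpoint",
         call. = FALSE)
  y <- y / ny
  x <- cross3(y, z)
  structure(list(origin = heel, x_axis = x, y_axis = y, z_axis = z),
            class = "foot_frame")
}

#' Registration transform taking a foot frame to the world frame
#'
#' Maps the frame origin (heel) to (0,0,0), the longitudinal axis to
#' +Y, the dorsal normal to +Z; the plantar plane lands on the world XY
#' plane (z = 0).
#'
#' @param frame a `foot_frame` from [build_foot_frame()].
#' @return a [rigid_transform].
#' @export
compute_registration <- function(frame) {
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% frame$origin))
}

#' Rigidly register a mesh and its landmarks
#'
#' @param mesh a [triangle_mesh].
#' @param lms a [landmark_set].
#' @param t a [rigid_transform] (typically from [compute_registration()]).
#' @return list with transformed `mesh` and `landmarks`.
#' @export
register_scene <- function(mesh, lms, t) {
  m2 <- mesh
  m2$vertices <- transform_points(t, mesh$vertices)
  l2 <- lms
  l2$points <- as_point_matrix(transform_points(t, lms$points),
                               "landmark points")
  rownames(l2$points) <- rownames(lms$points)
  list(mesh = m2, landmarks = l2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
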