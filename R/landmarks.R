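#' Recognised anatomical landmark identifiers
#'
#' HEEL: centre of the heel on the plantar surface.  MT1 / MT5: heads of
#' the first and fifth metatarsals.  ARCH: apex of the medial longitudinal
#' arch.  MED_MAL / LAT_MAL: medial and lateral malleoli.
#' @export
LANDMARK_IDS <- c("HEEL", "MT1", "MT5", "ARCH", "MED_MAL", "LAT_MAL")

#' Landmarks required for any measurement run
#' @rdname LANDMARK_IDS
#' @export
CORE_LANDMARKS <- c("HEEL", "MT1", "MT5", "ARCH")

#' Named anatomical landmark set
#'
#' Holds the 3-D positions (mm) of up to six named foot landmarks.  The
#' measurement pipeline needs at least `HEEL`, `MT1`, `MT5` and `ARCH`;
#' the malleoli are optional but required for foot-length trimming,
#' hindfoot girth and ankle angle.  A set missing the malleoli is accepted
#' and flagged `partial`.
#'
#' @param points numeric matrix with 3 columns whose rownames are landmark
#'   ids from [LANDMARK_IDS], millimetres.
#' @param side `"left"` or `"right"` (metadata only; measurements are
#'   unsigned and side-agnostic).
#' @param source `"guided"` (palpation-guided stickers) or
#'   `"scan_derived"` (visual placement on the bare mesh).
#' @return object of class `landmark_set`: list with `points`, `side`,
#'   `source`, `partial`.
#' @export
landmark_set <- function(points, side = "right", source = "guided") {
  points <- as_point_matrix(points, "landmark points")
  ids <- rownames(points)
  if (is.null(ids)) stop("landmark points must have id rownames",
                         call. = FALSE)
  bad <- setdiff(ids, LANDMARK_IDS)
  if (length(bad))
    stop("unknown landmark id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate landmark id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(points)))
    stop("non-finite landmark coordinate", call. = FALSE)
  missing_core <- setdiff(CORE_LANDMARKS, ids)
  if (length(missing_core))
    stop("landmark set missing required id(s): ",
         paste(missing_core, collapse = ", "), call. = FALSE)
  side <- match.arg(side, c("left", "right"))
  source <- match.arg(source, c("guided", "scan_derived"))
  structure(list(points = points[intersect(LANDMARK_IDS, ids), ,
                                 drop = FALSE],
                 side = side, source = source,
                 partial = !all(c("MED_MAL", "LAT_MAL") %in% ids)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (", x$side, ", ", x$source,
      if (x$partial) ", partial" else "", "): ",
      paste(rownames(x$points), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Extract one landmark position
#'
#' @param lms a `landmark_set`.
#' @param id one of [LANDMARK_IDS].
#' @return numeric length-3 vector, or an error if absent.
#' @export
landmark <- function(lms, id) {
  if (!id %in% rownames(lms$points))
    stop("landmark '", id, "' absent from set", call. = FALSE)
  as.numeric(lms$points[id, ])
}

has_landmark <- function(lms, id) id %in% rownames(lms$points)

has_malleoli <- function(lms) {
  all(c("MED_MAL", "LAT_MAL") %in% rownames(lms$points))
}

#' Check landmarks sit near a companion mesh
#'
#' Every present landmark must lie within the mesh's axis-aligned bounding
#' box expanded by 10 mm -- a sanity guard against unit mix-ups or stale
#' landmark files.
#'
#' @param lms a `landmark_set`.
#' @param mesh a `triangle_mesh`.
#' @param margin expansion in mm (default 10).
#' @return `lms`, invisibly; errors listing offending ids otherwise.
#' @export
check_landmarks_in_bbox <- function(lms, mesh, margin = 10) {
  lo <- apply(mesh$vertices, 2, min) - margin
  hi <- apply(mesh$vertices, 2, max) + margin
  p <- lms$points
  ok <- p[, 1] >= lo[1] & p[, 1] <= hi[1] &
        p[, 2] >= lo[2] & p[, 2] <= hi[2] &
        p[, 3] >= lo[3] & p[, 3] <= hi[3]
  if (!all(ok))
    stop("landmark(s) outside mesh bounding box (+", margin, " mm): ",
         paste(rownames(p)[!ok], collapse = ", "), call. = FALSE)
  invisible(lms)
}
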