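#' Plantar silhouette trace of a registered mesh
#'
#' Projects the weight-bearing (lower) surface of a registered foot mesh
#' onto the support plane z = 0 and returns its outline polygon.  Faces
#' are kept when every vertex lies below `height_cutoff` and the outward
#' face normal points downwards; for a closed scan whose lower surface is
#' a height field (true of feet resting on a base plane) those faces tile
#' the silhouette exactly once, so the outline is the set of projected
#' edges used by exactly one kept face, chained into loops.  When several
#' closed loops result, the largest-area one is returned.
#'
#' @param mesh a registered [triangle_mesh] (plantar plane on z = 0,
#'   coherent outward normals).
#' @param height_cutoff keep faces entirely below this height (mm, > 0).
#' @return object of class `plantar_trace`: list with `polygon` (n x 2
#'   matrix, closed implicitly), `area` (mm^2, shoelace), and
#'   `height_cutoff`.
#' @export
plantar_trace <- function(mesh, height_cutoff) {
  stopifnot(height_cutoff > 0)
  v <- mesh$vertices
  f <- mesh$faces
  below <- v[, 3] < height_cutoff
  keep <- below[f[, 1]] & below[f[, 2]] & below[f[, 3]]
  if (!any(keep))
    stop("empty plantar trace: no face lies fully below cutoff ",
         height_cutoff, " mm", call. = FALSE)
  nz <- face_normals(mesh)$normals[, 3]
  keep <- keep & nz < -1e-9
  if (!any(keep))
    stop("empty plantar trace: no downward-facing face below cutoff",
         call. = FALSE)
  fk <- f[keep, , drop = FALSE]
  e <- rbind(fk[, c(1, 2)], fk[, c(2, 3)], fk[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  boundary <- e[key %in% names(tab)[tab == 1L], , drop = FALSE]
  loops <- chain_edge_loops(boundary)
  if (!length(loops))
    stop("plantar trace boundary does not close", call. = FALSE)
  areas <- vapply(loops, function(idx) {
    abs(shoelace_area(v[idx, 1], v[idx, 2]))
  }, numeric(1))
  idx <- loops[[which.max(areas)]]
  poly <- v[idx, c(1, 2), drop = FALSE]
  structure(list(polygon = poly, area = max(areas),
                 height_cutoff = height_cutoff),
            class = "plantar_trace")
}

# Chain undirected boundary edges into closed vertex loops.
chain_edge_loops <- function(edges) {
  if (!nrow(edges)) return(list())
  adj <- new.env(hash = TRUE, parent = emptyenv())
  addv <- function(a, b) {
    k <- as.character(a)
    assign(k, c(if (exists(k, adj)) get(k, adj), b), adj)
  }
  for (i in seq_len(nrow(edges))) {
    addv(edges[i, 1], edges[i, 2]); addv(edges[i, 2], edges[i, 1])
  }
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  loops <- list()
  for (i in seq_len(nrow(edges))) {
    if (exists(ekey(edges[i, 1], edges[i, 2]), used)) next
    start <- edges[i, 1]; cur <- edges[i, 2]
    assign(ekey(start, cur), TRUE, used)
    loop <- c(start, cur)
    repeat {
      nbrs <- get(as.character(cur), adj)
      nxt <- nbrs[!vapply(nbrs, function(n)
        exists(ekey(cur, n), used), logical(1))]
      if (!length(nxt)) break
      nxt <- nxt[1]
      assign(ekey(cur, nxt), TRUE, used)
      if (nxt == start) { loops[[length(loops) + 1L]] <- loop; break }
      loop <- c(loop, nxt)
      cur <- nxt
    }
  }
  loops
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Horizontal chord of a trace polygon through a point
#'
#' Intersects the X-parallel line through `(px, py)` with the trace
#' outline; among the resulting inside intervals, the one containing `px`
#' (or nearest to it) is returned.
#'
#' @param trace a [plantar_trace].
#' @param px,py query point (mm) in the projected plane.
#' @return chord length (mm).
#' @export
trace_chord_x <- function(trace, px, py) {
  P <- trace$polygon
  n <- nrow(P)
  j <- c(2:n, 1)
  y1 <- P[, 2]; y2 <- P[j, 2]
  # half-open crossing rule avoids double counting at vertices
  hit <- (y1 <= py & y2 > py) | (y2 <= py & y1 > py)
  if (sum(hit) < 2)
    stop("chord at y = ", signif(py, 6), " misses the trace polygon",
         call. = FALSE)
  t <- (py - y1[hit]) / (y2[hit] - y1[hit])
  xs <- sort(P[hit, 1] + t * (P[j, 1][hit] - P[hit, 1]))
  lo <- xs[seq(1, length(xs) - 1, by = 2)]
  hi <- xs[seq(2, length(xs), by = 2)]
  inside <- px >= lo & px <= hi
  k <- if (any(inside)) which(inside)[1] else
    which.min(pmin(abs(px - lo), abs(px - hi)))
  hi[k] - lo[k]
}

#' Section plane
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalised internally).
#' @param anchor point used to pick among multiple intersection loops
#'   (defaults to `point`).
#' @return object of class `section_plane`.
#' @export
section_plane <- function(point, normal, anchor = point) {
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("zero-length plane normal", call. = FALSE)
  structure(list(point = as.numeric(point),
                 normal = as.numeric(normal) / nn,
                 anchor = as.numeric(anchor)),
            class = "section_plane")
}

#' Perimeter of a closed mesh--plane cross-section
#'
#' Intersects the mesh with the plane, chains the intersection segments
#' into loops via shared mesh edges, selects the closed loop whose
#' centroid lies nearest the plane's anchor point, and returns its
#' polyline length.  Girth accuracy is limited only by the mesh
#' tessellation (inscribed-polygon error, O(1/n^2) for smooth sections).
#'
#' @param mesh a [triangle_mesh] (closed across the cutting region).
#' @param plane a [section_plane].
#' @return perimeter in mm.
#' @export
cross_section_perimeter <- function(mesh, plane) {
  sec <- cross_section_loops(mesh, plane)
  if (!length(sec$loops))
    stop("open section: mesh-plane intersection has no closed loop",
         call. = FALSE)
  cents <- vapply(sec$loops, function(L) colMeans(sec$points[L, ,
                                                             drop = FALSE]),
                  numeric(3))
  d2 <- colSums((cents - plane$anchor)^2)
  L <- sec$loops[[which.min(d2)]]
  pts <- sec$points[L, , drop = FALSE]
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# Mesh-plane intersection: returns unique intersection points (one per
# cut mesh edge) and closed loops as index sequences into them.
cross_section_loops <- function(mesh, plane) {
  v <- mesh$vertices; f <- mesh$faces
  d <- as.numeric(v %*% plane$normal) - sum(plane$point * plane$normal)
  d[abs(d) < 1e-12] <- 1e-12          # nudge on-plane vertices to one side
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  cut <- (s1 != s2) | (s2 != s3)
  if (!any(cut)) return(list(points = NULL, loops = list()))
  fc <- f[cut, , drop = FALSE]
  # for each cut face, identify its two cut edges (canonical i<j ids)
  cut_edges_of <- function(a, b, c) {
    es <- rbind(c(a, b), c(b, c), c(c, a))
    hit <- (d[es[, 1]] > 0) != (d[es[, 2]] > 0)
    es[hit, , drop = FALSE]
  }
  seg_a <- character(nrow(fc)); seg_b <- character(nrow(fc))
  all_edges <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  for (k in seq_len(nrow(fc))) {
    es <- cut_edges_of(fc[k, 1], fc[k, 2], fc[k, 3])
    seg_a[k] <- ekey(es[1, 1], es[1, 2])
    seg_b[k] <- ekey(es[2, 1], es[2, 2])
    assign(seg_a[k], es[1, ], all_edges)
    assign(seg_b[k], es[2, ], all_edges)
  }
  keys <- ls(all_edges)
  emat <- t(vapply(keys, function(k) get(k, all_edges), numeric(2)))
  ti <- d[emat[, 1]] / (d[emat[, 1]] - d[emat[, 2]])
  pts <- v[emat[, 1], , drop = FALSE] +
    ti * (v[emat[, 2], , drop = FALSE] - v[emat[, 1], , drop = FALSE])
  ia <- match(seg_a, keys); ib <- match(seg_b, keys)
  # chain: each edge point connects the (<=2) segments that share it
  nseg <- length(ia)
  segs_at <- split(rep(seq_len(nseg), 2), c(ia, ib))
  used <- logical(nseg)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- ia[s0]; cur <- ib[s0]
    loop <- c(start, cur)
    closed <- FALSE
    repeat {
      cand <- segs_at[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- cand[1]
      used[s] <- TRUE
      nxt <- if (ia[s] == cur) ib[s] else ia[s]
      if (nxt == start) { closed <- TRUE; break }
      loop <- c(loop, nxt)
      cur <- nxt
    }
    if (closed && length(loop) >= 3)
      loops[[length(loops) + 1L]] <- loop
  }
  list(points = pts, loops = loops)
}

# ---- individual measurements ---------------------------------------------

#' Overall foot length of a registered scan
#'
#' Vertices above the mean malleoli height are discarded (trimming away
#' the distal leg), then the Y extent of the remaining axis-aligned
#' bounding box is returned.  Without malleoli the full bounding box is
#' used and the result flagged `untrimmed`.
#'
#' @param mesh registered [triangle_mesh].
#' @param lms registered [landmark_set].
#' @return length in mm, with attribute `untrimmed` when no malleoli were
#'   available.
#' @export
foot_length <- function(mesh, lms) {
  v <- mesh$vertices
  untrimmed <- !has_malleoli(lms)
  if (!untrimmed) {
    zcut <- malleoli_height(lms)
    v <- v[v[, 3] <= zcut, , drop = FALSE]
    if (!nrow(v)) stop("no mesh vertices below malleoli height",
                       call. = FALSE)
  }
  out <- diff(range(v[, 2]))
  attr(out, "untrimmed") <- untrimmed
  out
}

malleoli_height <- function(lms) {
  (landmark(lms, "MED_MAL")[3] + landmark(lms, "LAT_MAL")[3]) / 2
}

#' Truncated lengths from the heel end to the metatarsal heads
#'
#' Y-axis distances from the rear face of the (malleoli-trimmed) bounding
#' box to the Y coordinates of MT1 and MT5.
#'
#' @inheritParams foot_length
#' @return named vector `heel_to_mt1_length`, `heel_to_mt5_length` (mm).
#' @export
truncated_lengths <- function(mesh, lms) {
  v <- mesh$vertices
  if (has_malleoli(lms)) {
    zcut <- malleoli_height(lms)
    v <- v[v[, 3] <= zcut, , drop = FALSE]
  }
  y_rear <- min(v[, 2])
  l1 <- landmark(lms, "MT1")[2] - y_rear
  l5 <- landmark(lms, "MT5")[2] - y_rear
  if (l1 <= 0 || l5 <= 0)
    stop("metatarsal landmark lies behind the heel face", call. = FALSE)
  c(heel_to_mt1_length = l1, heel_to_mt5_length = l5)
}

#' Pairwise 3-D distances between the marked plantar landmarks
#'
#' @param lms a [landmark_set].
#' @return named vector `dist_mt1_heel`, `dist_mt1_mt5`, `dist_mt5_heel`
#'   (mm).
#' @export
landmark_distances <- function(lms) {
  heel <- landmark(lms, "HEEL"); mt1 <- landmark(lms, "MT1")
  mt5 <- landmark(lms, "MT5")
  c(dist_mt1_heel = sqrt(sum((mt1 - heel)^2)),
    dist_mt1_mt5 = sqrt(sum((mt1 - mt5)^2)),
    dist_mt5_heel = sqrt(sum((mt5 - heel)^2)))
}

#' Foot widths from the plantar trace
#'
#' Forefoot width is the planar distance between the z = 0 projections of
#' MT1 and MT5.  Midfoot and heel widths are X-parallel chords of the
#' trace outline through the projected ARCH and HEEL points.
#'
#' @param trace a [plantar_trace].
#' @param lms registered [landmark_set].
#' @return named vector `forefoot_width`, `midfoot_width`, `heel_width`
#'   (mm).
#' @export
foot_widths <- function(trace, lms) {
  mt1 <- landmark(lms, "MT1"); mt5 <- landmark(lms, "MT5")
  arch <- landmark(lms, "ARCH"); heel <- landmark(lms, "HEEL")
  c(forefoot_width = sqrt(sum((mt1[1:2] - mt5[1:2])^2)),
    midfoot_width = trace_chord_x(trace, arch[1], arch[2]),
    heel_width = trace_chord_x(trace, heel[1], heel[2]))
}

#' Foot girths (closed surface circumferences)
#'
#' Forefoot (ball) girth cuts through MT1 and MT5, perpendicular to the
#' plantar plane.  Midfoot (instep) girth cuts perpendicular to the long
#' axis through the midpoint of HEEL and MT1.  Hindfoot girth is the
#' diagonal circumference on the inclined plane through the rearmost heel
#' surface point and the midpoint of the medial malleolus and arch point,
#' with the plane containing the mediolateral X direction.
#'
#' @param mesh registered [triangle_mesh].
#' @param lms registered [landmark_set]; all six landmarks required for
#'   hindfoot girth.
#' @return named vector `forefoot_girth`, `midfoot_girth`,
#'   `hindfoot_girth` (mm); hindfoot is `NA` without malleoli.
#' @export
foot_girths <- function(mesh, lms) {
  mt1 <- landmark(lms, "MT1"); mt5 <- landmark(lms, "MT5")
  heel <- landmark(lms, "HEEL")
  d15 <- mt5 - mt1
  fore_pl <- section_plane(point = (mt1 + mt5) / 2,
                           normal = cross3(c(0, 0, 1), d15),
                           anchor = (mt1 + mt5) / 2)
  fore <- cross_section_perimeter(mesh, fore_pl)
  mid_pt <- (heel + mt1) / 2
  mid_pl <- section_plane(point = mid_pt, normal = c(0, 1, 0),
                          anchor = mid_pt)
  midg <- cross_section_perimeter(mesh, mid_pl)
  hind <- NA_real_
  if (has_malleoli(lms)) {
    pr <- heel_rear_point(mesh, lms)
    m <- (landmark(lms, "MED_MAL") + landmark(lms, "ARCH")) / 2
    hind_pl <- section_plane(point = pr,
                             normal = cross3(c(1, 0, 0), m - pr),
                             anchor = (pr + m) / 2)
    hind <- cross_section_perimeter(mesh, hind_pl)
  }
  c(forefoot_girth = fore, midfoot_girth = midg, hindfoot_girth = hind)
}

# Rearmost surface point of the heel: minimal Y among vertices within
# +/- 5 mm of the heel landmark's X, at or below the malleoli height so
# leg geometry never wins.
heel_rear_point <- function(mesh, lms, window = 5) {
  v <- mesh$vertices
  hx <- landmark(lms, "HEEL")[1]
  sel <- abs(v[, 1] - hx) <= window
  if (has_malleoli(lms)) sel <- sel & v[, 3] <= malleoli_height(lms)
  if (!any(sel))
    stop("no surface vertex near the heel landmark's X", call. = FALSE)
  vv <- v[sel, , drop = FALSE]
  as.numeric(vv[which.min(vv[, 2]), ])
}

#' Arch height and arch height index
#'
#' Arch height is the elevation of the marked arch point above the
#' plantar plane (its registered z coordinate); the index is that height
#' divided by the truncated heel-to-MT1 length.
#'
#' @param lms registered [landmark_set].
#' @param heel_to_mt1_length truncated length from [truncated_lengths()]
#'   (mm, > 0).
#' @return named vector `arch_height` (mm), `arch_height_index` (ratio).
#' @export
arch_metrics <- function(lms, heel_to_mt1_length) {
  stopifnot(heel_to_mt1_length > 0)
  ah <- landmark(lms, "ARCH")[3]
  if (ah < -1e-9)
    stop("arch point lies below the plantar plane", call. = FALSE)
  ah <- max(ah, 0)
  c(arch_height = ah, arch_height_index = ah / heel_to_mt1_length)
}

#' Ankle angle
#'
#' Angle in degrees between the line from the heel point to the midpoint
#' of the two malleoli and the vertical (+Z) reference through the heel.
#'
#' @param lms registered [landmark_set] with HEEL and both malleoli.
#' @return angle in degrees, in [0, 180).
#' @export
ankle_angle <- function(lms) {
  heel <- landmark(lms, "HEEL")
  m <- (landmark(lms, "MED_MAL") + landmark(lms, "LAT_MAL")) / 2
  d <- m - heel
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9)
    stop("malleoli midpoint coincides with the heel point", call. = FALSE)
  acos(pmin(1, pmax(-1, d[3] / nd))) * 180 / pi
}

# ---- orchestration --------------------------------------------------------

#' Names of the 15 foot measurements, in report order
#' @export
MEASUREMENT_NAMES <- c(
  "foot_length", "heel_to_mt1_length", "heel_to_mt5_length",
  "dist_mt1_heel", "dist_mt1_mt5", "dist_mt5_heel",
  "forefoot_width", "midfoot_width", "heel_width",
  "forefoot_girth", "midfoot_girth", "hindfoot_girth",
  "arch_height_index", "arch_height", "ankle_angle")

MEASUREMENT_UNITS <- stats::setNames(
  c(rep("mm", 12), "ratio", "mm", "deg"), MEASUREMENT_NAMES)

#' Compute the full 15-measurement report for a foot scan
#'
#' Registers the scene into the canonical plantar frame and derives all
#' fifteen measurements: three lengths, three landmark distances, three
#' widths, three girths, arch height and index, and the ankle angle.
#' Runs unattended; any sub-operation failure is re-raised with the
#' affected measurement named.  With a partial landmark set (no
#' malleoli), `hindfoot_girth` and `ankle_angle` are `NA`, foot length is
#' untrimmed, and the report carries a `flags` entry in its metadata.
#'
#' @param mesh a [triangle_mesh] in any pose.
#' @param lms the matching [landmark_set] (same pose).
#' @param height_cutoff trace cutoff in mm; default is the registered
#'   mean malleoli height, or 40 mm for partial sets.
#' @param condition free-text provenance tag (e.g. "NWB").
#' @return object of class `measurement_report`: named numeric vector of
#'   the 15 measurements with attributes `units` and `meta`.
#' @export
measure_foot <- function(mesh, lms, height_cutoff = NULL,
                         condition = NA_character_) {
  validate_mesh(mesh)
  check_landmarks_in_bbox(lms, mesh)
  frame <- build_foot_frame(lms)
  t <- compute_registration(frame)
  sc <- register_scene(mesh, lms, t)
  rm_ <- sc$mesh; rl <- sc$landmarks
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("measurement '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fl <- step("foot_length", foot_length(rm_, rl))
  tl <- step("heel_to_mt1_length", truncated_lengths(rm_, rl))
  ld <- step("dist_mt1_heel", landmark_distances(rl))
  if (is.null(height_cutoff))
    height_cutoff <- if (has_malleoli(rl)) malleoli_height(rl) else 40
  tr <- step("midfoot_width", plantar_trace(rm_, height_cutoff))
  w <- step("midfoot_width", foot_widths(tr, rl))
  g <- step("forefoot_girth", foot_girths(rm_, rl))
  am <- step("arch_height", arch_metrics(rl, tl[["heel_to_mt1_length"]]))
  aa <- if (has_malleoli(rl)) step("ankle_angle", ankle_angle(rl)) else
    NA_real_
  vals <- c(foot_length = as.numeric(fl), tl, ld, w, g,
            arch_height_index = am[["arch_height_index"]],
            arch_height = am[["arch_height"]],
            ankle_angle = aa)[MEASUREMENT_NAMES]
  flags <- character(0)
  if (isTRUE(attr(fl, "untrimmed"))) flags <- c(flags, "untrimmed")
  if (!has_malleoli(rl)) flags <- c(flags, "partial_landmarks")
  measurement_report(vals, mesh_name = mesh$name, source = lms$source,
                     side = lms$side, condition = condition,
                     flags = flags)
}

#' Construct and validate a measurement report
#'
#' @param values named numeric vector covering [MEASUREMENT_NAMES].
#' @param mesh_name,source,side,condition,flags provenance metadata.
#' @return a `measurement_report`.
#' @export
measurement_report <- function(values, mesh_name = NA_character_,
                               source = NA_character_,
                               side = NA_character_,
                               condition = NA_character_,
                               flags = character(0)) {
  if (!setequal(names(values), MEASUREMENT_NAMES) ||
      length(values) != 15L)
    stop("report must contain exactly the 15 named measurements",
         call. = FALSE)
  values <- values[MEASUREMENT_NAMES]
  lin <- setdiff(MEASUREMENT_NAMES,
                 c("arch_height_index", "arch_height", "ankle_angle"))
  bad <- names(values)[!is.na(values) &
                         ((names(values) %in% lin & values <= 0) |
                          (names(values) == "arch_height" & values < 0))]
  if (length(bad))
    stop("non-positive measurement(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ahi <- values[["arch_height_index"]]
  if (!is.na(ahi) && (ahi < 0 || ahi >= 1))
    stop("arch_height_index out of [0, 1)", call. = FALSE)
  aa <- values[["ankle_angle"]]
  if (!is.na(aa) && (aa < 0 || aa >= 90))
    stop("ankle_angle out of [0, 90) degrees", call. = FALSE)
  structure(values, class = "measurement_report",
            units = MEASUREMENT_UNITS,
            meta = list(mesh_name = mesh_name, source = source,
                        side = side, condition = condition,
                        flags = flags))
}

#' @export
print.measurement_report <- function(x, digits = 4, ...) {
  meta <- attr(x, "meta")
  cat("measurement_report for '", meta$mesh_name, "' (",
      meta$source, if (!is.na(meta$condition))
        paste0(", ", meta$condition), ")\n", sep = "")
  df <- report_as_table(x)
  df$value <- round(df$value, digits)
  print(df, row.names = FALSE)
  if (length(meta$flags))
    cat("flags:", paste(meta$flags, collapse = ", "), "\n")
  invisible(x)
}
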