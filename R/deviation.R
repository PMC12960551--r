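#' Signed surface deviation of a test mesh from a reference mesh
#'
#' For every test-mesh vertex the closest point on the reference surface
#' is located (exact point-to-triangle distances, with a
#' centroid-plus-circumradius bound to prune candidate faces), and the
#' distance is signed by the outward normal of the nearest reference
#' face: positive means the test surface lies outside the reference.
#' Sampling at test vertices is deterministic and adequate at scan
#' resolution; it is a documented difference from samplers that ray-cast
#' from the reference.
#'
#' @param test,reference [triangle_mesh]es; the reference needs coherent
#'   outward normals.
#' @return object of class `deviation_field`: list with `points` (test
#'   vertices), `distance` (signed mm per point), `test`, `reference`
#'   (names).
#' @export
signed_deviation <- function(test, reference) {
  validate_mesh(test); validate_mesh(reference)
  p <- test$vertices
  v <- reference$vertices; f <- reference$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cent <- (a + b + cc) / 3
  circ <- sqrt(pmax(rowSums((a - cent)^2),
                    rowSums((b - cent)^2),
                    rowSums((cc - cent)^2)))
  nrm <- face_normals(reference)$normals
  n <- nrow(p)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    q <- p[i, ]
    dc <- sqrt((cent[, 1] - q[1])^2 + (cent[, 2] - q[2])^2 +
                 (cent[, 3] - q[3])^2)
    j0 <- which.min(dc)
    r0 <- point_triangle_dist(q, a[j0, , drop = FALSE],
                              b[j0, , drop = FALSE],
                              cc[j0, , drop = FALSE])
    ub <- sqrt(r0$d2)
    cand <- which(dc - circ <= ub + 1e-12)
    r <- point_triangle_dist(q, a[cand, , drop = FALSE],
                             b[cand, , drop = FALSE],
                             cc[cand, , drop = FALSE])
    jbest <- which.min(r$d2)
    jface <- cand[jbest]
    d <- sqrt(r$d2[jbest])
    sgn <- sum((q - r$closest[jbest, ]) * nrm[jface, ])
    dist[i] <- if (sgn < 0) -d else d
  }
  structure(list(points = p, distance = dist,
                 test = test$name, reference = reference$name),
            class = "deviation_field")
}

# Vectorised exact point-to-triangle distance (Ericson's region method):
# one query point against m triangles. Returns squared distances and the
# closest point on each triangle.
point_triangle_dist <- function(q, a, b, cc) {
  m <- nrow(a)
  qm <- matrix(q, m, 3, byrow = TRUE)
  ab <- b - a; ac <- cc - a; ap <- qm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- qm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- qm - cc
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  closest <- matrix(NA_real_, m, 3)
  done <- logical(m)
  set_pt <- function(idx, pts) {
    closest[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  r1 <- !done & d1 <= 0 & d2 <= 0                       # vertex A
  if (any(r1)) set_pt(r1, a[r1, , drop = FALSE])
  r2 <- !done & d3 >= 0 & d4 <= d3                      # vertex B
  if (any(r2)) set_pt(r2, b[r2, , drop = FALSE])
  r3 <- !done & d6 >= 0 & d5 <= d6                      # vertex C
  if (any(r3)) set_pt(r3, cc[r3, , drop = FALSE])
  r4 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0             # edge AB
  if (any(r4)) {
    t <- d1[r4] / (d1[r4] - d3[r4])
    set_pt(r4, a[r4, , drop = FALSE] + t * ab[r4, , drop = FALSE])
  }
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0             # edge AC
  if (any(r5)) {
    t <- d2[r5] / (d2[r5] - d6[r5])
    set_pt(r5, a[r5, , drop = FALSE] + t * ac[r5, , drop = FALSE])
  }
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0   # edge BC
  if (any(r6)) {
    t <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
    set_pt(r6, b[r6, , drop = FALSE] +
             t * (cc[r6, , drop = FALSE] - b[r6, , drop = FALSE]))
  }
  rin <- !done                                          # interior
  if (any(rin)) {
    denom <- va[rin] + vb[rin] + vc[rin]
    vv <- vb[rin] / denom; ww <- vc[rin] / denom
    set_pt(rin, a[rin, , drop = FALSE] + vv * ab[rin, , drop = FALSE] +
             ww * ac[rin, , drop = FALSE])
  }
  diffp <- closest - qm
  list(d2 = rowSums(diffp^2), closest = closest)
}

#' Tolerance-band summary of a deviation field
#'
#' Fraction of sample points inside, above and below a symmetric
#' deviation band; boundary points (|d| = tol) count as in-tolerance
#' ("within" read inclusively).
#'
#' @param field a `deviation_field` from [signed_deviation()].
#' @param tolerance symmetric band half-width in mm (default 1.0, the
#'   orthotic-industry acceptance band).
#' @return object of class `tolerance_summary`: named numeric vector
#'   `tolerance`, `fraction_in`, `fraction_over`, `fraction_under`,
#'   `mean`, `sd`, `max_abs` with units attribute.
#' @export
tolerance_summary <- function(field, tolerance = 1.0) {
  stopifnot(inherits(field, "deviation_field"), tolerance > 0)
  d <- field$distance
  out <- c(tolerance = tolerance,
           fraction_in = mean(abs(d) <= tolerance),
           fraction_over = mean(d > tolerance),
           fraction_under = mean(d < -tolerance),
           mean = mean(d), sd = stats::sd(d), max_abs = max(abs(d)))
  structure(out, class = "tolerance_summary",
            units = stats::setNames(
             c("mm", "fraction", "fraction", "fraction", "mm", "mm",
               "mm"), names(out)),
            meta = list(test = field$test, reference = field$reference,
                        n_points = length(d)))
}

#' @export
print.tolerance_summary <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "deviation %s vs %s (n=%d): %.1f%% within +/-%g mm (over %.1f%%, under %.1f%%)\n",
    meta$test, meta$reference, meta$n_points, 100 * x[["fraction_in"]],
    x[["tolerance"]], 100 * x[["fraction_over"]],
    100 * x[["fraction_under"]]))
  cat(sprintf("  mean %.3f mm, sd %.3f mm, max |d| %.3f mm\n",
              x[["mean"]], x[["sd"]], x[["max_abs"]]))
  invisible(x)
}

#' Pairwise design-consistency matrix
#'
#' Runs [signed_deviation()] + [tolerance_summary()] for every mesh pair
#' in each named group and reports the mean and SD of the percentage of
#' surface within tolerance per group -- the summary used to compare
#' orthotic designs across designers and landmarking methods.
#'
#' @param designs named list of [triangle_mesh]es.
#' @param groups named list; each element is a character vector (length
#'   >= 2) of design names forming one comparison category.
#' @param tolerance band half-width in mm.
#' @param symmetric if `TRUE` (default) each unordered pair is evaluated
#'   both ways and both fractions enter the summary.
#' @return data.frame with one row per group: `group`, `n_pairs`,
#'   `mean_pct_in`, `sd_pct_in`.
#' @export
consistency_matrix <- function(designs, groups, tolerance = 1.0,
                               symmetric = TRUE) {
  stopifnot(length(designs) >= 2)
  out <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    if (length(members) < 2)
      stop("group '", g, "' has fewer than 2 designs", call. = FALSE)
    bad <- setdiff(members, names(designs))
    if (length(bad))
      stop("group '", g, "' names unknown design(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    fr <- c()
    for (i in seq_along(members)[-length(members)])
      for (j in (i + 1):length(members)) {
        s1 <- tolerance_summary(
          signed_deviation(designs[[members[i]]],
                           designs[[members[j]]]), tolerance)
        fr <- c(fr, s1[["fraction_in"]])
        if (symmetric) {
          s2 <- tolerance_summary(
            signed_deviation(designs[[members[j]]],
                             designs[[members[i]]]), tolerance)
          fr <- c(fr, s2[["fraction_in"]])
        }
      }
    out[[length(out) + 1L]] <- data.frame(
      group = g, n_pairs = length(fr),
      mean_pct_in = mean(100 * fr),
      sd_pct_in = if (length(fr) > 1) stats::sd(100 * fr) else 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export a deviation field
#'
#' CSV columns `x,y,z,distance`; or PLY with the signed distance attached
#' as a per-vertex `quality` property for colour mapping.
#'
#' @param field a `deviation_field`.
#' @param path output path (`.csv` or `.ply`).
#' @return `path`, invisibly.
#' @export
write_deviation_field <- function(field, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    p <- field$points
    writeLines(c("ply", "format ascii 1.0",
                 paste("comment deviation", field$test, "vs",
                       field$reference),
                 paste("element vertex", nrow(p)),
                 "property double x", "property double y",
                 "property double z", "property double quality",
                 "element face 0",
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3],
                       field$distance), con)
  } else {
    df <- data.frame(x = field$points[, 1], y = field$points[, 2],
                     z = field$points[, 3], distance = field$distance)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
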