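#' Read a surface mesh from STL or PLY
#'
#' Binary and ASCII STL are auto-detected; PLY is ASCII only.  STL stores
#' each facet's corner coordinates independently, so duplicate vertices
#' are merged within 1e-6 mm on read.  Coordinates are taken to be in
#' millimetres; there is no unit autodetection.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"stl"` or `"ply"`.
#' @return a [triangle_mesh].
#' @export
read_triangle_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read mesh: file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension '",
                          ext, "'", call. = FALSE))
  }
  m <- if (format == "stl") read_stl(path) else read_ply(path)
  if (nrow(m$faces) == 0L)
    stop("mesh file contains zero faces: ", path, call. = FALSE)
  m
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"auto"` (by extension), `"stl"` (binary), `"stl_ascii"`
#'   or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_triangle_mesh <- function(mesh,
                                path,
                                format = c("auto", "stl", "stl_ascii",
                                           "ply")) {
  format <- match.arg(format)
  validate_mesh(mesh, min_faces = 1L)
  if (nrow(mesh$faces) == 0L)
    stop("refusing to write a mesh with no faces", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension '",
                          ext, "'", call. = FALSE))
  }
  switch(format,
         stl = write_stl_binary(mesh, path),
         stl_ascii = write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path))
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

# A file is binary STL iff its size matches 84 + 50*n for the declared
# facet count n; ASCII files start with "solid" but so may binary headers,
# so the size check decides.
read_stl <- function(path) {
  size <- file.info(path)$size
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.numeric(n)) {
      is_binary <- TRUE
      body <- readBin(con, "raw", 50 * n)
      close(con)
      on.exit()
      return(parse_stl_binary_body(body, n, basename(path)))
    }
    close(con)
    on.exit()
    # header said binary-like count but size mismatched: if it does not
    # read as ASCII either, report truncation
    head1 <- readLines(path, n = 1, warn = FALSE)
    if (!grepl("^\\s*solid", head1) && !is.na(n))
      stop("malformed binary STL (declared ", n,
           " facets, file size inconsistent): ", path, call. = FALSE)
  }
  if (!is_binary) read_stl_ascii(path)
}

parse_stl_binary_body <- function(body, n, name) {
  if (n == 0L) stop("STL file declares zero facets", call. = FALSE)
  m <- matrix(body, nrow = 50)
  tri <- m[13:48, , drop = FALSE]  # skip 12-byte normal, keep 9 floats
  coords <- readBin(as.vector(tri), "numeric", n = 9L * n, size = 4,
                    endian = "little")
  verts <- matrix(coords, ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * n), ncol = 3, byrow = TRUE)
  md <- merge_vertices(verts, faces)
  triangle_mesh(md$vertices, md$faces, name = name, validate = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl))
    stop("not a valid ASCII STL (no vertex lines): ", path, call. = FALSE)
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
  verts <- t(coords)
  if (anyNA(verts))
    stop("non-numeric vertex coordinate in ASCII STL: ", path,
         call. = FALSE)
  if (nrow(verts) %% 3 != 0)
    stop("ASCII STL vertex count not a multiple of 3: ", path,
         call. = FALSE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  md <- merge_vertices(verts, faces)
  triangle_mesh(md$vertices, md$faces, name = basename(path),
                validate = FALSE)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fn <- face_normals(mesh)$normals
  v <- mesh$vertices; f <- mesh$faces
  # per facet: normal (3f), v1 v2 v3 (9f), attribute count (uint16)
  dat <- cbind(fn, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ])
  floats <- as.numeric(t(dat))
  fl_raw <- writeBin(floats, raw(), size = 4, endian = "little")
  fl_mat <- matrix(fl_raw, nrow = 48)
  rec <- rbind(fl_mat, matrix(as.raw(0), nrow = 2, ncol = nf))
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(mesh)$normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("solid ", mesh$name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3]),
                 con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(paste0("endsolid ", mesh$name), con)
  invisible(path)
}

# ---- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated: ", path, call. = FALSE)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  el <- grep("^element ", header, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(strsplit(el, "\\s+"), `[`, "", 3)),
    vapply(strsplit(el, "\\s+"), `[`, "", 2))
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vt, function(t) as.numeric(t[1:3]), numeric(3)))
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(ft, function(t) {
    k <- as.integer(t[1])
    if (k != 3L) stop("non-triangular PLY face", call. = FALSE)
    as.integer(t[2:4]) + 1L
  }, integer(3)))
  triangle_mesh(verts, faces, name = basename(path), validate = FALSE)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("ply", "format ascii 1.0",
               paste("comment", mesh$name),
               paste("element vertex", nrow(v)),
               "property double x", "property double y",
               "property double z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

# ---- landmark files -------------------------------------------------------

#' Read a landmark set from CSV or JSON
#'
#' CSV schema: columns `id,x,y,z` with ids from [LANDMARK_IDS],
#' coordinates in mm.  JSON schema: an object keyed by id with `[x,y,z]`
#' arrays, plus optional `"side"` and `"source"` string members.  Sets
#' missing the malleoli are accepted and flagged partial (with a warning);
#' unknown or duplicate ids and non-numeric coordinates are rejected.
#'
#' @param path file path (`.csv` or `.json`).
#' @param side,source metadata defaults when the file carries none; see
#'   [landmark_set()].
#' @return a [landmark_set].
#' @export
read_landmark_set <- function(path, side = "right", source = "guided") {
  if (!file.exists(path))
    stop("cannot read landmarks: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$side)) { side <- obj$side; obj$side <- NULL }
    if (!is.null(obj$source)) { source <- obj$source; obj$source <- NULL }
    ids <- names(obj)
    pts <- do.call(rbind, lapply(obj, function(p) {
      p <- suppressWarnings(as.numeric(unlist(p)))
      if (length(p) != 3 || anyNA(p))
        stop("landmark JSON entries must be numeric [x,y,z]",
             call. = FALSE)
      p
    }))
    rownames(pts) <- ids
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns id,x,y,z: ", path,
           call. = FALSE)
    xyz <- as.matrix(df[, c("x", "y", "z")])
    if (!is.numeric(xyz) || anyNA(suppressWarnings(
          matrix(as.numeric(xyz), ncol = 3))))
      stop("non-numeric coordinate in landmark CSV: ", path,
           call. = FALSE)
    pts <- matrix(as.numeric(xyz), ncol = 3,
                  dimnames = list(df$id, NULL))
  }
  lms <- landmark_set(pts, side = side, source = source)
  if (lms$partial)
    warning("landmark set is partial (malleoli absent): ", path,
            call. = FALSE)
  lms
}

#' Write a landmark set to CSV or JSON
#'
#' @param lms a [landmark_set].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_landmark_set <- function(lms, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- c(
      stats::setNames(lapply(seq_len(nrow(lms$points)),
                             function(i) as.numeric(lms$points[i, ])),
                      rownames(lms$points)),
      list(side = lms$side, source = lms$source))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(id = rownames(lms$points),
                     x = lms$points[, 1], y = lms$points[, 2],
                     z = lms$points[, 3])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- reports --------------------------------------------------------------

#' Write a measurement report or tolerance summary
#'
#' CSV layout is one row per quantity with columns `name,value,units`;
#' JSON carries the same fields plus provenance metadata and round-trips
#' losslessly via [read_report()].
#'
#' @param report a `measurement_report` (see [measure_foot()]) or a
#'   `tolerance_summary` (see [tolerance_summary()]).
#' @param path output path.
#' @param format `"csv"` or `"json"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else
      "csv"
  df <- report_as_table(report)
  if (anyNA(df$value) || any(!is.finite(df$value)))
    stop("report contains non-finite values: ",
         paste(df$name[!is.finite(df$value)], collapse = ", "),
         call. = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(type = class(report)[1],
                values = stats::setNames(as.list(df$value), df$name),
                units = stats::setNames(as.list(df$units), df$name),
                meta = attr(report, "meta"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON report path.
#' @return the reconstructed `measurement_report` or `tolerance_summary`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.numeric(unlist(obj$values))
  names(out) <- names(obj$values)
  structure(out, class = obj$type,
            units = unlist(obj$units),
            meta = obj$meta)
}

report_as_table <- function(report) {
  data.frame(name = names(report),
             value = as.numeric(report),
             units = as.character(attr(report, "units")),
             stringsAsFactors = FALSE)
}
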