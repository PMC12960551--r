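# Geometric fixtures built in code, plus independent oracles.

# axis-aligned closed box [0,dx] x [0,dy] x [0,dz], outward normals
make_box <- function(dx, dy, dz, origin = c(0, 0, 0), name = "box") {
  g <- expand.grid(x = c(0, dx), y = c(0, dy), z = c(0, dz))
  v <- as.matrix(g) + matrix(origin, 8, 3, byrow = TRUE)
  # vertex order: (0,0,0)=1 (x)=2 (y)=3 (xy)=4 (z)=5 (xz)=6 (yz)=7 (xyz)=8
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),      # bottom z=0, normal -z
    c(5, 6, 8), c(5, 8, 7),      # top z=dz, normal +z
    c(1, 2, 6), c(1, 6, 5),      # front y=0
    c(3, 7, 8), c(3, 8, 4),      # back y=dy
    c(1, 5, 7), c(1, 7, 3),      # left x=0
    c(2, 4, 8), c(2, 8, 6))      # right x=dx
  triangle_mesh(v, f, name)
}

# lat-long sphere, outward normals
make_sphere <- function(r, nu = 64, nv = 32, name = paste0("sphere", r)) {
  th <- 2 * pi * (0:(nu - 1)) / nu
  ph <- pi * (1:(nv - 1)) / nv
  v <- do.call(rbind, lapply(ph, function(p)
    cbind(r * sin(p) * cos(th), r * sin(p) * sin(th), r * cos(p))))
  f <- NULL
  for (i in 1:(nv - 2)) {
    r0 <- (i - 1) * nu; r1 <- i * nu
    j <- 1:nu; jn <- c(2:nu, 1)
    f <- rbind(f, cbind(r0 + j, r0 + jn, r1 + jn),
               cbind(r0 + j, r1 + jn, r1 + j))
  }
  np <- (nv - 1) * nu + 1; sp <- np + 1
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  j <- 1:nu; jn <- c(2:nu, 1)
  f <- rbind(f, cbind(np, jn, j), cbind(sp, (nv - 2) * nu + j,
                                        (nv - 2) * nu + jn))
  triangle_mesh(v, f[, c(1, 3, 2)], name)   # flip to outward
}

# closed cylinder, axis +Y, base at y = 0, outward normals
make_cylinder <- function(r, len, n = 128, nz = 8, name = "cylinder") {
  th <- 2 * pi * (0:(n - 1)) / n
  ys <- seq(0, len, length.out = nz)
  v <- do.call(rbind, lapply(ys, function(y)
    cbind(r * cos(th), y, r * sin(th))))
  f <- NULL
  for (i in 1:(nz - 1)) {
    r0 <- (i - 1) * n; r1 <- i * n
    j <- 1:n; jn <- c(2:n, 1)
    f <- rbind(f, cbind(r0 + j, r0 + jn, r1 + jn),
               cbind(r0 + j, r1 + jn, r1 + j))
  }
  p1 <- nz * n + 1; p2 <- nz * n + 2
  v <- rbind(v, c(0, 0, 0), c(0, len, 0))
  j <- 1:n; jn <- c(2:n, 1)
  f <- rbind(f, cbind(p1, jn, j), cbind(p2, (nz - 1) * n + j,
                                        (nz - 1) * n + jn))
  m <- triangle_mesh(v, f, name)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# open L-shaped slab: bottom faces (normal -z) of the L footprint
# {[0,2]x[0,1]} U {[0,1]x[1,2]} at z = 0, matching top at z = h
make_lprism <- function(h = 5) {
  v2 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1),
              c(0, 2), c(1, 2))
  tri2 <- rbind(c(1, 4, 5), c(1, 5, 2), c(2, 5, 6), c(2, 6, 3),
                c(4, 7, 8), c(4, 8, 5))
  v <- rbind(cbind(v2, 0), cbind(v2, h))
  f <- rbind(tri2[, c(1, 3, 2)],        # bottom, normal -z
             tri2 + 8L)                 # top, normal +z
  triangle_mesh(v, f, "lprism")
}

signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# independent ICC(A,1) oracle: mean squares from stats::aov
icc_oracle <- function(x) {
  df <- data.frame(
    y = as.vector(x),
    subj = factor(rep(seq_len(nrow(x)), ncol(x))),
    rater = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  n <- nrow(x); k <- ncol(x)
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] +
                       (k / n) * (ms[2] - ms[3]))
}

# canonical small landmark layout on a 250 x 90 x 40 box scene
box_scene_landmarks <- function() {
  landmark_set(rbind(
    HEEL = c(0, 5, 0), MT1 = c(-30, 180, 0), MT5 = c(30, 180, 0),
    ARCH = c(-10, 100, 10), MED_MAL = c(-40, 55, 50),
    LAT_MAL = c(40, 55, 50)))
}

small_foot <- function(resolution = 24, ...) {
  generate_foot(foot_params(...), resolution = resolution)
}

scale_scene <- function(mesh, lms, s) {
  m2 <- mesh; m2$vertices <- mesh$vertices * s
  l2 <- lms; l2$points <- lms$points * s
  list(mesh = m2, landmarks = l2)
}
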