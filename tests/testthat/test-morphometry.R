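test_that("box trace is the exact footprint rectangle", {
  box <- make_box(250, 90, 40)
  tr <- plantar_trace(box, 50)
  expect_equal(tr$area, 250 * 90)
  expect_equal(range(tr$polygon[, 1]), c(0, 250))
  expect_equal(range(tr$polygon[, 2]), c(0, 90))
  expect_error(plantar_trace(box, -1))
  above <- box; above$vertices[, 3] <- above$vertices[, 3] + 100
  expect_error(plantar_trace(above, 50), "empty")
})

test_that("L-prism trace recovers the concave outline and its area", {
  tr <- plantar_trace(make_lprism(), 50)
  expect_equal(tr$area, 3)           # three unit squares
  expect_equal(nrow(tr$polygon) >= 6, TRUE)
})

test_that("trace chords behave at the rectangle and off-polygon queries", {
  box <- make_box(250, 90, 40)
  tr <- plantar_trace(box, 50)
  expect_equal(trace_chord_x(tr, 125, 45), 250)
  expect_error(trace_chord_x(tr, 125, 1000), "misses")
})

test_that("cross-section perimeters match analytic circumferences", {
  cyl <- make_cylinder(30, 100, n = 128)
  per <- cross_section_perimeter(cyl,
                                 section_plane(c(0, 50, 0), c(0, 1, 0)))
  expect_lt(abs(per - 2 * pi * 30) / (2 * pi * 30), 0.005)

  # 30 degree oblique cut: ellipse semi-axes (r, r / cos 30)
  per2 <- cross_section_perimeter(
    cyl, section_plane(c(0, 50, 0), c(0, cos(pi / 6), sin(pi / 6))))
  expected <- ramanujan_perimeter(30, 30 / cos(pi / 6))
  expect_lt(abs(per2 - expected) / expected, 0.005)

  cube <- make_box(10, 10, 10)
  expect_equal(cross_section_perimeter(
    cube, section_plane(c(5, 5, 5), c(0, 0, 1))), 40)
})

test_that("multi-loop sections select the loop nearest the anchor", {
  b1 <- make_box(10, 10, 10)
  b2 <- make_box(10, 10, 10, origin = c(100, 0, 0))
  two <- triangle_mesh(rbind(b1$vertices, b2$vertices),
                       rbind(b1$faces, b2$faces + 8L), "two")
  pl <- section_plane(c(0, 0, 5), c(0, 0, 1), anchor = c(105, 5, 5))
  expect_equal(cross_section_perimeter(two, pl), 40)
  # open surface -> open-section error
  expect_error(cross_section_perimeter(
    make_lprism(), section_plane(c(0.5, 0.5, 2.5), c(1, 0, 0))),
    "open section")
})

test_that("foot length trims the leg above the malleoli", {
  foot <- make_box(90, 250, 40, origin = c(-45, 0, 0))
  leg <- make_box(50, 50, 60, origin = c(-25, 30, 40))
  scene <- triangle_mesh(rbind(foot$vertices, leg$vertices),
                         rbind(foot$faces, leg$faces + 8L), "boxfoot")
  lms <- box_scene_landmarks()
  fl <- foot_length(scene, lms)
  expect_equal(as.numeric(fl), 250)
  expect_false(attr(fl, "untrimmed"))
  # without malleoli the full box is used and flagged
  lpart <- landmark_set(lms$points[1:4, ])
  fl2 <- foot_length(scene, lpart)
  expect_true(attr(fl2, "untrimmed"))
  tl <- truncated_lengths(scene, lms)
  expect_equal(as.numeric(tl), c(180, 180))
})

test_that("landmark distances are Euclidean and obey the triangle inequality", {
  lms <- landmark_set(rbind(HEEL = c(0, 0, 0), MT1 = c(-40, 180, 0),
                            MT5 = c(40, 180, 0), ARCH = c(-10, 100, 15)))
  d <- landmark_distances(lms)
  expect_equal(d[["dist_mt1_heel"]], sqrt(40^2 + 180^2))
  expect_equal(d[["dist_mt1_mt5"]], 80)
  expect_lt(d[["dist_mt1_mt5"]],
            d[["dist_mt1_heel"]] + d[["dist_mt5_heel"]])
})

test_that("widths: projection distance for forefoot, chords for midfoot/heel", {
  box <- make_box(90, 250, 40, origin = c(-45, 0, 0))
  tr <- plantar_trace(box, 50)
  lms <- landmark_set(rbind(HEEL = c(0, 5, 0), MT1 = c(-40, 180, 5),
                            MT5 = c(42, 175, 6), ARCH = c(-10, 100, 10)))
  w <- foot_widths(tr, lms)
  expect_equal(w[["forefoot_width"]], sqrt(82^2 + 5^2))
  expect_equal(w[["heel_width"]], 90)
  expect_equal(w[["midfoot_width"]], 90)
})

test_that("arch metrics and ankle angle match hand arithmetic", {
  lms <- landmark_set(rbind(HEEL = c(0, 0, 0), MT1 = c(-40, 180, 0),
                            MT5 = c(40, 180, 0), ARCH = c(-10, 100, 15)))
  am <- arch_metrics(lms, 180)
  expect_equal(am[["arch_height"]], 15)
  expect_equal(am[["arch_height_index"]], 15 / 180)
  flat <- lms; flat$points["ARCH", 3] <- 0
  expect_equal(arch_metrics(flat, 180)[["arch_height"]], 0)
  below <- lms; below$points["ARCH", 3] <- -2
  expect_error(arch_metrics(below, 180), "below")

  full <- landmark_set(rbind(HEEL = c(0, 0, 0), MT1 = c(-40, 180, 0),
                             MT5 = c(40, 180, 0), ARCH = c(-10, 100, 15),
                             MED_MAL = c(-30, 40, 60),
                             LAT_MAL = c(30, 40, 60)))
  expect_equal(ankle_angle(full), atan2(40, 60) * 180 / pi)
  vert <- full
  vert$points[c("MED_MAL", "LAT_MAL"), 2] <- 0
  expect_equal(ankle_angle(vert), 0)
  diag45 <- full
  diag45$points["MED_MAL", ] <- c(0, 50, 50)
  diag45$points["LAT_MAL", ] <- c(0, 50, 50)
  expect_equal(ankle_angle(diag45), 45)
  coinc <- full
  coinc$points[c("MED_MAL", "LAT_MAL"), ] <-
    matrix(0, 2, 3, byrow = TRUE)
  expect_error(ankle_angle(coinc), "coincides")
})

test_that("measure_foot returns exactly 15 measurements and flags partials", {
  g <- small_foot(24)
  rep <- measure_foot(g$mesh, g$landmarks)
  expect_s3_class(rep, "measurement_report")
  expect_identical(names(rep), MEASUREMENT_NAMES)
  expect_length(rep, 15L)
  expect_true(all(is.finite(as.numeric(rep))))

  lpart <- landmark_set(g$landmarks$points[CORE_LANDMARKS, ])
  rp <- measure_foot(g$mesh, lpart)
  expect_true(is.na(rp[["hindfoot_girth"]]))
  expect_true(is.na(rp[["ankle_angle"]]))
  expect_true(all(c("untrimmed", "partial_landmarks") %in%
                    attr(rp, "meta")$flags))
  expect_true(all(is.finite(as.numeric(
    rp[setdiff(MEASUREMENT_NAMES,
               c("hindfoot_girth", "ankle_angle"))]))))
})

test_that("measurements recover the generator's ground-truth parameters", {
  par <- foot_params(length = 250, forefoot_width = 95, heel_width = 65,
                     arch_height = 22)
  g <- generate_foot(par, resolution = 48)
  rep <- measure_foot(g$mesh, g$landmarks)
  expect_lt(abs(rep[["foot_length"]] - 250), 2)
  expect_lt(abs(rep[["forefoot_width"]] - 95), 2)
  expect_lt(abs(rep[["heel_width"]] - 65), 2)
  expect_lt(abs(rep[["arch_height"]] - 22), 0.5)
  expect_lt(abs(rep[["heel_to_mt1_length"]] - 0.72 * 250), 2)
  expect_lt(rep[["heel_to_mt1_length"]], rep[["foot_length"]])
  expect_gt(rep[["forefoot_girth"]], 2 * rep[["forefoot_width"]])
})

test_that("midfoot girth matches the analytic section of a phantom", {
  # elliptical cylinder phantom along Y standing in for a midfoot
  a <- 40; b <- 25
  th <- 2 * pi * (0:255) / 256
  ys <- seq(0, 200, length.out = 9)
  v <- do.call(rbind, lapply(ys, function(y)
    cbind(a * cos(th), y, b + b * sin(th))))
  f <- NULL
  for (i in 1:8) {
    r0 <- (i - 1) * 256; r1 <- i * 256
    j <- 1:256; jn <- c(2:256, 1)
    f <- rbind(f, cbind(r0 + j, r0 + jn, r1 + jn),
               cbind(r0 + j, r1 + jn, r1 + j))
  }
  p1 <- 9 * 256 + 1; p2 <- p1 + 1
  v <- rbind(v, c(0, 0, b), c(0, 200, b))
  j <- 1:256; jn <- c(2:256, 1)
  f <- rbind(f, cbind(p1, jn, j), cbind(p2, 8 * 256 + j, 8 * 256 + jn))
  phantom <- triangle_mesh(v, f, "ellcyl")
  per <- cross_section_perimeter(
    phantom, section_plane(c(0, 100, 0), c(0, 1, 0)))
  expect_lt(abs(per - ramanujan_perimeter(a, b)) /
              ramanujan_perimeter(a, b), 0.005)
})

test_that("all 15 measurements are rigid-invariant and scale-equivariant", {
  g <- small_foot(24)
  r0 <- measure_foot(g$mesh, g$landmarks)
  for (seed in c(11, 12, 13)) {
    sc <- register_scene(g$mesh, g$landmarks,
                         random_rigid_transform(seed))
    r1 <- measure_foot(sc$mesh, sc$landmarks)
    expect_lt(max(abs(r1 - r0) / pmax(abs(r0), 1e-9)), 1e-6)
  }
  s2 <- scale_scene(g$mesh, g$landmarks, 2)
  r2 <- measure_foot(s2$mesh, s2$landmarks)
  linear <- setdiff(MEASUREMENT_NAMES,
                    c("arch_height_index", "ankle_angle"))
  expect_lt(max(abs(r2[linear] / r0[linear] - 2)), 1e-6)
  expect_lt(abs(r2[["arch_height_index"]] - r0[["arch_height_index"]]),
            1e-6)
  expect_lt(abs(r2[["ankle_angle"]] - r0[["ankle_angle"]]), 1e-6)
})

test_that("measured arch height rises strictly with the arch parameter", {
  heights <- c(8, 14, 20, 26)
  got <- vapply(heights, function(a) {
    g <- generate_foot(foot_params(arch_height = a), resolution = 24)
    r <- measure_foot(g$mesh, g$landmarks)
    c(r[["arch_height"]], r[["arch_height_index"]])
  }, numeric(2))
  expect_true(all(diff(got[1, ]) > 0))
  expect_true(all(diff(got[2, ]) > 0))
})
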