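test_that("generator is deterministic and validates its parameters", {
  a <- generate_foot(resolution = 16, seed = 3)
  b <- generate_foot(resolution = 16, seed = 3)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$landmarks$points, b$landmarks$points)
  expect_error(foot_params(arch_height = 70, instep_height = 60),
               "below")
  expect_error(foot_params(length = -1), "positive")
  expect_error(foot_params(arch_apex_y = 0.7), "0.2")
  expect_error(generate_foot(resolution = 8), ">= 16")
})

test_that("generated meshes are closed manifolds with outward normals", {
  for (res in c(16, 24, 48)) {
    g <- generate_foot(resolution = res)
    expect_true(is_closed_manifold(g$mesh))
    expect_gt(signed_volume(g$mesh), 0)
    check_landmarks_in_bbox(g$landmarks, g$mesh)
  }
})

test_that("doubling the default resolution changes measurements < 0.5%", {
  g1 <- generate_foot(resolution = 64)
  g2 <- generate_foot(resolution = 128)
  r1 <- measure_foot(g1$mesh, g1$landmarks)
  r2 <- measure_foot(g2$mesh, g2$landmarks)
  expect_lt(max(abs(r2 - r1) / pmax(abs(r1), 1)), 0.005)
})

test_that("weight bearing flattens the arch and widens the foot", {
  g <- small_foot(24)
  w0 <- apply_weight_bearing(g$mesh, g$landmarks, g$params, 0)
  expect_identical(w0$mesh$vertices, g$mesh$vertices)
  expect_identical(w0$landmarks$points, g$landmarks$points)

  r0 <- measure_foot(g$mesh, g$landmarks)
  loads <- c(0, 0.5, 1)
  reps <- lapply(loads, function(l) {
    wb <- apply_weight_bearing(g$mesh, g$landmarks, g$params, l)
    measure_foot(wb$mesh, wb$landmarks)
  })
  arch <- vapply(reps, `[[`, 0, "arch_height")
  expect_lt(abs(arch[3] - 0.5 * r0[["arch_height"]]), 0.5)
  expect_true(all(diff(arch) < 0))
  for (w in c("forefoot_width", "heel_width", "midfoot_width")) {
    ws <- vapply(reps, `[[`, 0, w)
    expect_true(all(diff(ws) > 0))
  }
  expect_error(apply_weight_bearing(g$mesh, g$landmarks, g$params, 2))
})

test_that("landmark perturbation is seeded and respects sigma", {
  g <- small_foot(16)
  quiet <- rater_model("guided", sigma = 0)
  same <- perturb_landmarks(g$landmarks, quiet, seed = 1)
  expect_identical(same$points, g$landmarks$points)

  noisy <- rater_model("scan_derived")
  a <- perturb_landmarks(g$landmarks, noisy, seed = 10)
  b <- perturb_landmarks(g$landmarks, noisy, seed = 10)
  d <- perturb_landmarks(g$landmarks, noisy, seed = 11)
  expect_identical(a$points, b$points)
  expect_false(identical(a$points, d$points))
  expect_identical(a$source, "scan_derived")
  # tangential jitter keeps plantar landmarks on the plantar plane
  expect_equal(a$points[c("HEEL", "MT1", "MT5"), 3], c(0, 0, 0),
               ignore_attr = TRUE)
})

test_that("per-axis jitter SD is within 5% of sigma over 10000 draws", {
  lms <- landmark_set(rbind(HEEL = c(0, 0, 0), MT1 = c(-40, 180, 0),
                            MT5 = c(40, 180, 0),
                            ARCH = c(-10, 100, 15)))
  model <- rater_model("guided", sigma = 2, tangential_only = FALSE)
  draws <- vapply(seq_len(10000), function(s)
    perturb_landmarks(lms, model, seed = s)$points["ARCH", ],
    numeric(3))
  sds <- apply(draws - c(-10, 100, 15), 1, sd)
  expect_true(all(abs(sds / 2 - 1) < 0.05))
})

test_that("guided defaults are tighter than scan-derived defaults", {
  gm <- rater_model("guided")
  sm <- rater_model("scan_derived")
  expect_true(all(gm$sigma <= sm$sigma))
  expect_true(all(gm$bias == 0))
  expect_true(any(sm$bias != 0))
})

test_that("a 12-subject x 2-feet design yields 24 scans per condition", {
  des <- study_design(n_subjects = 12, feet_per_subject = 2,
                      conditions = "NWB",
                      raters = list(A = rater_model("guided",
                                                    sigma = 0)),
                      repetitions = 1, seed = 4, resolution = 16)
  panel <- simulate_reliability_study(des)
  expect_equal(length(unique(panel$subject)), 24L)
  expect_equal(nrow(panel), 24L * 15L)
  expect_identical(attr(panel, "seed"), 4L)
  expect_length(attr(panel, "scans"), 24L)
})

test_that("zero rater noise gives ICC = 1 for all 15 measurements", {
  des <- study_design(
    n_subjects = 5, feet_per_subject = 1, conditions = "NWB",
    raters = list(A = rater_model("guided", sigma = 0),
                  B = rater_model("guided", sigma = 0),
                  C = rater_model("guided", sigma = 0)),
    repetitions = 1, seed = 9, resolution = 16)
  panel <- simulate_reliability_study(des)
  tab <- reliability_table(panel, design = "inter")
  expect_equal(nrow(tab), 15L)
  expect_true(all(abs(tab$estimate - 1) < 1e-9))
})

test_that("intra-user design uses repetitions under the mixed model", {
  des <- study_design(
    n_subjects = 4, feet_per_subject = 1, conditions = "NWB",
    raters = list(A = rater_model("guided")),
    repetitions = 3, seed = 21, resolution = 16)
  panel <- simulate_reliability_study(des)
  tab <- reliability_table(panel, design = "intra")
  expect_true(all(tab$model == "mixed"))
  expect_true(all(tab$k == 3))
  expect_true(all(tab$estimate <= 1))
})

test_that("random rigid transforms are proper, seeded and invertible", {
  for (seed in 1:5) {
    t1 <- random_rigid_transform(seed)
    expect_equal(det(t1$rotation), 1, tolerance = 1e-12)
    expect_identical(random_rigid_transform(seed)$rotation, t1$rotation)
    ident <- compose_transforms(t1, invert_transform(t1))
    expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
    expect_lt(max(abs(ident$translation)), 1e-9)
  }
  expect_false(identical(random_rigid_transform(1)$rotation,
                         random_rigid_transform(2)$rotation))
})

test_that("simulation does not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_reliability_study(
    study_design(n_subjects = 1, feet_per_subject = 1,
                 conditions = "NWB",
                 raters = list(A = rater_model("guided")),
                 seed = 2, resolution = 16)))
  expect_identical(.Random.seed, before)
})
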