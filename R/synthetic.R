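#' Parametric foot-shape parameters
#'
#' The synthetic foot is a closed surface lofted from superelliptical
#' cross-sections along the length axis: a flat-bottomed, dome-topped
#' section profile with a rounded heel, a mild midfoot waist, a wide
#' metatarsal region and tapering toes; a medial plantar concavity of
#' depth `arch_height` centred at `arch_apex_y`; and a short distal-leg
#' stub rising above the malleoli at the hindfoot.  Defaults describe an
#' adult foot of length 250 mm scanned in a non-weight-bearing pose.
#'
#' @param length overall heel-to-toe length L (mm).
#' @param forefoot_width MT1 head to MT5 head separation (mm).
#' @param heel_width silhouette width at the heel centre (mm).
#' @param arch_height medial arch elevation above the support plane (mm);
#'   must stay below `instep_height`.
#' @param arch_apex_y arch apex position as a fraction of L, in
#'   [0.2, 0.6].
#' @param instep_height dorsal height of the midfoot (mm).
#' @param toe_taper 0-1, relative width retained at the toe break.
#' @param leg_stub_height extra height of the leg stub above the
#'   malleoli (mm).
#' @param malleoli_height height of the malleoli above the sole (mm).
#' @return validated list of class `foot_params`.
#' @export
foot_params <- function(length = 250, forefoot_width = 95,
                        heel_width = 65, arch_height = 15,
                        arch_apex_y = 0.40, instep_height = 60,
                        toe_taper = 0.70, leg_stub_height = 40,
                        malleoli_height = 65) {
  p <- list(length = length, forefoot_width = forefoot_width,
            heel_width = heel_width, arch_height = arch_height,
            arch_apex_y = arch_apex_y, instep_height = instep_height,
            toe_taper = toe_taper, leg_stub_height = leg_stub_height,
            malleoli_height = malleoli_height)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all foot parameters must be positive and finite",
         call. = FALSE)
  if (arch_height >= instep_height)
    stop("arch_height must be below instep_height", call. = FALSE)
  if (arch_apex_y < 0.2 || arch_apex_y > 0.6)
    stop("arch_apex_y must lie in [0.2, 0.6]", call. = FALSE)
  if (toe_taper > 1) stop("toe_taper must be <= 1", call. = FALSE)
  structure(p, class = "foot_params")
}

# longitudinal profiles, t = y / L in [0, 1] -------------------------------

# silhouette half-width profile; interpolates the named widths exactly at
# the heel (t = 0.12) and metatarsal (t = 0.72) stations
profile_halfwidth <- function(p) {
  hw <- p$heel_width / 2
  # mesh is slightly wider than the MT1-MT5 separation so the metatarsal
  # landmarks sit on the surface a little above the sole
  fw <- p$forefoot_width / 2 / 0.92
  tt <- p$toe_taper
  ts <- c(0, 0.04, 0.12, 0.30, 0.45, 0.60, 0.72, 0.85, 0.96, 1)
  ws <- c(0.02 * hw, 0.62 * hw, hw, 0.90 * hw, 0.97 * hw, 0.95 * fw,
          fw, fw * (0.55 + 0.45 * tt), 0.45 * fw * tt, 0.02 * hw)
  stats::splinefun(ts, ws, method = "natural")
}

# dorsal (top) height profile of the foot proper, without the leg stub
profile_foottop <- function(p) {
  ih <- p$instep_height
  ts <- c(0, 0.04, 0.15, 0.30, 0.45, 0.60, 0.72, 0.85, 0.96, 1)
  hs <- ih * c(0.04, 0.50, 0.88, 0.98, 1.00, 0.80, 0.62, 0.45, 0.28,
               0.04)
  stats::splinefun(ts, hs, method = "natural")
}

# smooth compactly-supported window, 1 at u = 0, 0 beyond |u| >= 1
coswin <- function(u) ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)

LEG_CENTRE <- 0.20   # leg stub station (fraction of L), malleoli live here
LEG_HALFWIDTH <- 0.14

# total section height: foot top plus the hindfoot leg stub
profile_height <- function(p) {
  ft <- profile_foottop(p)
  peak <- p$malleoli_height + p$leg_stub_height
  function(t) {
    base <- ft(t)
    lift <- pmax(0, peak - base) * coswin((t - LEG_CENTRE) /
                                            LEG_HALFWIDTH)
    base + lift
  }
}

ARCH_XC_FRAC <- -0.35   # apex at 35% of the local half-width, medial side
ARCH_XWIN_FRAC <- 0.55
ARCH_YWIN_FRAC <- 0.18

# plantar arch concavity field: bottom-surface lift in mm at (x, y)
arch_lift <- function(x, y, p, halfwidth_fun) {
  yc <- p$arch_apex_y * p$length
  ac <- halfwidth_fun(p$arch_apex_y)
  xc <- ARCH_XC_FRAC * ac
  gx <- coswin((x - xc) / (ARCH_XWIN_FRAC * ac))
  gy <- coswin((y - yc) / (ARCH_YWIN_FRAC * p$length))
  p$arch_height * gx * gy
}

# blending height below which the arch concavity deforms the section
arch_blend <- function(p) max(0.5 * p$instep_height, 1.5 * p$arch_height)

P_LOWER <- 8     # superellipse exponent, flat plantar half
P_UPPER <- 2.2   # superellipse exponent, domed dorsal half

# analytic cross-section curve at station t: S points (x, z), bottom at
# z = 0 before the arch field is applied.  Polar parametrisation of the
# superellipse keeps vertices evenly spread (the power parametrisation
# would leave the flat plantar mid-line almost unsampled and starve the
# arch concavity of vertices)
section_curve <- function(t, S, wfun, hfun) {
  a <- wfun(t); b <- hfun(t) / 2
  phi <- 2 * pi * (seq_len(S) - 1) / S
  cp <- cos(phi); sp <- sin(phi)
  pp <- ifelse(sp < 0, P_LOWER, P_UPPER)
  r <- (abs(cp / a)^pp + abs(sp / b)^pp)^(-1 / pp)
  cbind(x = r * cp, z = b + r * sp)
}

#' Generate a synthetic foot mesh with ground-truth landmarks
#'
#' Builds the closed, manifold loft described in [foot_params()] in the
#' canonical pose (plantar plane on z = 0, heel rear at y = 0, toes
#' towards +Y, medial side towards -X) and emits the six landmarks by
#' construction: HEEL, MT1 and MT5 on the support plane, ARCH at the
#' medial concavity apex, and the malleoli on the sides of the leg stub.
#' The generator is fully deterministic; `seed` is recorded in the mesh
#' name for provenance only.
#'
#' @param params a [foot_params] list.
#' @param resolution segments per cross-section (>= 16); the loft uses
#'   `2 * resolution` stations along the length.
#' @param seed integer recorded for provenance.
#' @param side `"left"` or `"right"` metadata for the landmark set.
#' @return list with `mesh` ([triangle_mesh]), `landmarks`
#'   ([landmark_set]) and `params`.
#' @export
generate_foot <- function(params = foot_params(), resolution = 64,
                          seed = 0L, side = "right") {
  stopifnot(inherits(params, "foot_params"))
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  S <- 4L * as.integer(ceiling(resolution / 4))  # exact rim/sole points
  nring <- 2L * S
  L <- params$length
  wfun <- profile_halfwidth(params)
  hfun <- profile_height(params)
  ts <- seq(0.015, 0.995, length.out = nring)
  verts <- matrix(NA_real_, nring * S + 2L, 3)
  for (i in seq_len(nring)) {
    sec <- section_curve(ts[i], S, wfun, hfun)
    rows <- (i - 1L) * S + seq_len(S)
    verts[rows, 1] <- sec[, "x"]
    verts[rows, 2] <- ts[i] * L
    verts[rows, 3] <- sec[, "z"]
  }
  heel_pole <- nring * S + 1L
  toe_pole <- nring * S + 2L
  verts[heel_pole, ] <- c(0, 0, hfun(0.015) / 2)
  verts[toe_pole, ] <- c(0, L, hfun(0.995) / 2)
  # apply the plantar arch concavity (pure vertical lift of low points)
  zb <- arch_blend(params)
  lift <- arch_lift(verts[, 1], verts[, 2], params, wfun)
  ramp <- pmax(0, 1 - verts[, 3] / zb)
  verts[, 3] <- verts[, 3] + lift * ramp
  # faces: quads between consecutive rings, fans to the two poles;
  # winding chosen so normals point outwards
  faces <- matrix(0L, (nring - 1L) * S * 2L + 2L * S, 3)
  fi <- 0L
  for (i in seq_len(nring - 1L)) {
    r0 <- (i - 1L) * S
    r1 <- i * S
    j <- seq_len(S)
    jn <- c(2:S, 1L)
    idx <- fi + seq_len(S)
    faces[idx, ] <- cbind(r0 + j, r0 + jn, r1 + jn)
    faces[idx + S, ] <- cbind(r0 + j, r1 + jn, r1 + j)
    fi <- fi + 2L * S
  }
  j <- seq_len(S); jn <- c(2:S, 1L)
  faces[fi + j, ] <- cbind(heel_pole, jn, j)
  fi <- fi + S
  r0 <- (nring - 1L) * S
  faces[fi + j, ] <- cbind(toe_pole, r0 + j, r0 + jn)
  faces <- faces[, c(1L, 3L, 2L)]     # outward orientation
  mesh <- triangle_mesh(verts, faces,
                        name = sprintf("synthfoot_L%.0f_seed%d", L,
                                       as.integer(seed)))
  lms <- ground_truth_landmarks(params, side = side)
  list(mesh = mesh, landmarks = lms, params = params)
}

HEEL_STATION <- 0.12
MT_STATION <- 0.72

# analytic landmark positions implied by the parameters
ground_truth_landmarks <- function(params, side = "right") {
  L <- params$length
  wfun <- profile_halfwidth(params)
  hfun <- profile_height(params)
  fw2 <- params$forefoot_width / 2
  yc <- params$arch_apex_y * L
  xc <- ARCH_XC_FRAC * wfun(params$arch_apex_y)
  # malleoli: surface x at the malleoli height on the leg-stub section
  tm <- LEG_CENTRE
  bm <- hfun(tm) / 2
  zrel <- (params$malleoli_height - bm) / bm
  xm <- wfun(tm) * (1 - abs(zrel)^P_UPPER)^(1 / P_UPPER)
  pts <- rbind(
    HEEL = c(0, HEEL_STATION * L, 0),
    MT1 = c(-fw2, MT_STATION * L, 0),
    MT5 = c(fw2, MT_STATION * L, 0),
    ARCH = c(xc, yc, params$arch_height),
    MED_MAL = c(-xm, tm * L, params$malleoli_height),
    LAT_MAL = c(xm, tm * L, params$malleoli_height))
  landmark_set(pts, side = side, source = "guided")
}

#' Deform a synthetic foot for weight bearing
#'
#' Applies the load model: the arch concavity depth scales by
#' `1 - 0.5 * load` (arch flattening) and the foot widens mediolaterally
#' by `1 + 0.05 * load`.  Landmarks move with the surface.  `load = 0`
#' is the identity (non-weight-bearing); `load = 1` full standing load.
#' The scene must be in the canonical generator pose.
#'
#' @param mesh,lms mesh and landmarks from [generate_foot()].
#' @param params the generating [foot_params].
#' @param load fraction of body weight, in [0, 1].
#' @return list with deformed `mesh` and `landmarks`.
#' @export
apply_weight_bearing <- function(mesh, lms, params, load) {
  stopifnot(load >= 0, load <= 1)
  if (load == 0) return(list(mesh = mesh, landmarks = lms))
  wfun <- profile_halfwidth(params)
  zb <- arch_blend(params)
  deform <- function(pts) {
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    cc <- arch_lift(x, y, params, wfun)          # current apex lift
    # invert the generator's lift to recover the undeformed height,
    # then reapply at the reduced arch depth (linear ramp => closed form)
    z0 <- ifelse(z < zb & cc > 0, (z - cc) / (1 - cc / zb), z)
    z1 <- z0 + (1 - 0.5 * load) * cc * pmax(0, 1 - z0 / zb)
    cbind(x * (1 + 0.05 * load), y, z1)
  }
  m2 <- mesh
  m2$vertices <- as_point_matrix(deform(mesh$vertices), "vertices")
  m2$name <- sprintf("%s_load%.2f", mesh$name, load)
  l2 <- lms
  pts <- deform(lms$points)
  rownames(pts) <- rownames(lms$points)
  l2$points <- as_point_matrix(pts, "landmark points")
  list(mesh = m2, landmarks = l2)
}

#' Rater landmark-placement noise model
#'
#' Guided mode mimics palpation-guided stickers: small unbiased jitter.
#' Scan-derived mode mimics visual placement on a bare mesh: larger
#' jitter, largest for the plantar landmarks that lack visual reference
#' points, plus a systematic anterior bias there.
#'
#' @param mode `"guided"` or `"scan_derived"`.
#' @param sigma named per-landmark jitter SD (mm) or a single scalar;
#'   defaults by mode (guided: 1 mm everywhere; scan-derived: 4 mm
#'   plantar, 3 mm arch, 2 mm malleoli).
#' @param bias 6 x 3 matrix of systematic offsets (mm, rows named by
#'   landmark) or NULL; scan-derived default shifts plantar landmarks
#'   3 mm anteriorly.
#' @param tangential_only if `TRUE` (default) jitter acts in the local
#'   surface plane of each landmark (canonical pose normals), mimicking
#'   raters who always click on the surface.
#' @return list of class `rater_model`.
#' @export
rater_model <- function(mode = c("guided", "scan_derived"), sigma = NULL,
                        bias = NULL, tangential_only = TRUE) {
  mode <- match.arg(mode)
  if (is.null(sigma))
    sigma <- if (mode == "guided") {
      stats::setNames(rep(1, 6), LANDMARK_IDS)
    } else {
      stats::setNames(c(4, 4, 4, 3, 2, 2), LANDMARK_IDS)
    }
  if (length(sigma) == 1L && is.null(names(sigma)))
    sigma <- stats::setNames(rep(sigma, 6), LANDMARK_IDS)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(bias)) {
    bias <- matrix(0, 6, 3, dimnames = list(LANDMARK_IDS, c("x", "y",
                                                            "z")))
    if (mode == "scan_derived")
      bias[c("HEEL", "MT1", "MT5"), "y"] <- 3
  }
  structure(list(mode = mode, sigma = sigma, bias = bias,
                 tangential_only = isTRUE(tangential_only)),
            class = "rater_model")
}

# canonical-pose surface normals used to restrict jitter tangentially;
# the arch apex sits on the medial border, so its tangent plane is
# sagittal and vertical placement uncertainty is retained
LANDMARK_NORMALS <- rbind(
  HEEL = c(0, 0, -1), MT1 = c(0, 0, -1), MT5 = c(0, 0, -1),
  ARCH = c(-1, 0, 0), MED_MAL = c(-1, 0, 0), LAT_MAL = c(1, 0, 0))

#' Perturb landmarks with a rater noise model
#'
#' Each landmark moves by its systematic bias plus Gaussian jitter of
#' the model's per-landmark sigma, truncated at three sigma per axis (a
#' rater visibly far off target re-places the point); with
#' `tangential_only` the jitter is projected into the local surface
#' plane.  Deterministic given `seed`; the global RNG state is left
#' untouched.
#'
#' @param lms a [landmark_set] in canonical pose.
#' @param model a [rater_model].
#' @param seed integer seed.
#' @return perturbed [landmark_set] with `source` set from the model.
#' @export
perturb_landmarks <- function(lms, model, seed) {
  stopifnot(inherits(model, "rater_model"))
  pts <- lms$points
  ids <- rownames(pts)
  with_local_seed(seed, {
    for (id in ids) {
      s <- if (id %in% names(model$sigma)) model$sigma[[id]] else 0
      # inverse-CDF truncated normal: fixed draw count keeps the
      # stream deterministic
      u <- stats::runif(3, stats::pnorm(-3), stats::pnorm(3))
      jit <- s * stats::qnorm(u)
      if (model$tangential_only) {
        nrm <- LANDMARK_NORMALS[id, ]
        jit <- jit - sum(jit * nrm) * nrm
      }
      b <- if (id %in% rownames(model$bias)) model$bias[id, ] else
        c(0, 0, 0)
      pts[id, ] <- pts[id, ] + b + jit
      # raters place the arch point on the visible medial contour,
      # never below the support surface
      if (id == "ARCH") pts[id, 3] <- max(pts[id, 3], 1)
    }
  })
  l2 <- lms
  l2$points <- pts
  l2$source <- if (model$mode == "guided") "guided" else "scan_derived"
  l2
}

#' Reliability study design
#'
#' @param n_subjects participants (>= 1).
#' @param feet_per_subject 1 or 2.
#' @param conditions subset of `c("NWB", "PWB", "HWB")` (loads 0, 0.5,
#'   1).
#' @param raters named list of [rater_model]s (>= 1).
#' @param repetitions repeats per rater (>= 1).
#' @param seed master seed; recorded in all outputs.
#' @param resolution mesh resolution passed to [generate_foot()].
#' @return list of class `study_design`.
#' @export
study_design <- function(n_subjects = 12, feet_per_subject = 2,
                         conditions = c("NWB", "HWB"),
                         raters = list(A = rater_model("guided"),
                                       B = rater_model("guided"),
                                       C = rater_model("guided")),
                         repetitions = 1, seed = 1, resolution = 64) {
  stopifnot(n_subjects >= 1, feet_per_subject %in% c(1, 2),
            repetitions >= 1, length(raters) >= 1)
  conditions <- match.arg(conditions, c("NWB", "PWB", "HWB"),
                          several.ok = TRUE)
  if (is.null(names(raters)))
    names(raters) <- LETTERS[seq_along(raters)]
  structure(list(n_subjects = as.integer(n_subjects),
                 feet_per_subject = as.integer(feet_per_subject),
                 conditions = conditions, raters = raters,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed),
                 resolution = as.integer(resolution)),
            class = "study_design")
}

CONDITION_LOADS <- c(NWB = 0, PWB = 0.5, HWB = 1)

#' Population sampler for foot parameters
#'
#' Draws anthropometrically plausible [foot_params] from the RNG stream:
#' foot length around 250 +/- 15 mm with proportional widths, arch
#' height 15 +/- 3 mm.  Used as the default `params_sampler` of
#' [simulate_reliability_study()].
#'
#' @return a [foot_params].
#' @export
sample_foot_params <- function() {
  L <- max(210, min(290, stats::rnorm(1, 250, 15)))
  foot_params(
    length = L,
    forefoot_width = L * max(0.33, stats::rnorm(1, 0.38, 0.012)),
    heel_width = L * max(0.22, stats::rnorm(1, 0.26, 0.010)),
    arch_height = max(6, min(26, stats::rnorm(1, 15, 3))),
    arch_apex_y = max(0.32, min(0.48, stats::rnorm(1, 0.40, 0.02))),
    instep_height = max(45, min(75, stats::rnorm(1, 60, 4))),
    toe_taper = 0.70,
    leg_stub_height = 40,
    malleoli_height = max(50, min(80, stats::rnorm(1, 65, 4))))
}

#' Simulate a complete reliability study
#'
#' For every subject and foot, draws [foot_params], generates the mesh,
#' deforms it per weight-bearing condition, perturbs the ground-truth
#' landmarks for every rater and repetition, measures each scene with
#' [measure_foot()], and returns the long-format panel consumed by
#' [reliability_table()].  Fully deterministic given the design seed.
#'
#' @param design a [study_design].
#' @param params_sampler zero-argument function returning a
#'   [foot_params]; drawn inside the seeded stream.
#' @return panel data.frame (see [panel_from_reports()]) with attributes
#'   `seed` and `scans` (per-scan parameter provenance).
#' @export
simulate_reliability_study <- function(design,
                                       params_sampler =
                                         sample_foot_params) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  scans <- list()
  with_local_seed(design$seed, {
    for (s in seq_len(design$n_subjects)) {
      for (ft in seq_len(design$feet_per_subject)) {
        scan_id <- sprintf("S%02d_%s", s, c("L", "R")[ft])
        side <- c("left", "right")[ft]
        par <- params_sampler()
        gen <- generate_foot(par, resolution = design$resolution,
                             seed = design$seed, side = side)
        scans[[scan_id]] <- par
        for (cond in design$conditions) {
          sc <- apply_weight_bearing(gen$mesh, gen$landmarks, par,
                                     CONDITION_LOADS[[cond]])
          for (rn in names(design$raters)) {
            for (rep_i in seq_len(design$repetitions)) {
              pseed <- sample.int(.Machine$integer.max, 1)
              lmp <- perturb_landmarks(sc$landmarks,
                                       design$raters[[rn]], pseed)
              rep_report <- tryCatch(
                measure_foot(sc$mesh, lmp, condition = cond),
                error = function(e)
                  stop("measurement failed for ", scan_id, "/", cond,
                       "/rater ", rn, "/rep ", rep_i, ": ",
                       conditionMessage(e), call. = FALSE))
              rows[[length(rows) + 1L]] <- panel_from_reports(
                list(rep_report), subject = scan_id, rater = rn,
                repetition = rep_i, condition = cond)
            }
          }
        }
      }
    }
  })
  panel <- do.call(rbind, rows)
  attr(panel, "seed") <- design$seed
  attr(panel, "scans") <- scans
  panel
}

#' Random rigid transform (test fixture)
#'
#' Rotation uniform over SO(3) (normalised quaternion of four standard
#' normals) and translation uniform in a cube of half-width
#' `max_translation`.
#'
#' @param seed integer seed.
#' @param max_translation translation bound per axis (mm).
#' @return a [rigid_transform].
#' @export
random_rigid_transform <- function(seed, max_translation = 100) {
  with_local_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE)
    tr <- stats::runif(3, -max_translation, max_translation)
    rigid_transform(R, tr)
  })
}

# run code under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}
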