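# Synthetic penalty scenes and coded datasets with known ground truth.
#
# Skeletons are laid out analytically in field coordinates (so every target
# quantity is exact by construction), pushed through a field-to-image camera
# homography to pixels, and optionally perturbed with isotropic Gaussian
# pixel noise. The generated files use the same dialects the real pipeline
# reads.

#' Default broadcast-style camera homography (field to image)
#'
#' A perspective map emulating the standardized behind-the-kicker broadcast
#' view at 1280 x 720: the penalty-area corners on the goal line appear high
#' and compressed, the near corners low and wide.
#'
#' @return A `homography` mapping field meters to image pixels.
#' @export
default_camera_homography <- function() {
  corners <- default_field_corners()
  estimate_homography(data.frame(
    img_x = corners$field_x, img_y = corners$field_y,
    field_x = corners$img_x, field_y = corners$img_y))
}

# penalty-area corners: goal line x = 0, area depth 16.5 m, width 40.32 m
default_field_corners <- function() {
  data.frame(
    corner_id = c("goal_left", "goal_right", "near_left", "near_right"),
    img_x = c(235, 1045, 105, 1175),
    img_y = c(215, 215, 410, 410),
    field_x = c(0, 0, -16.5, -16.5),
    field_y = c(20.16, -20.16, 20.16, -20.16))
}

#' Scene-generator configuration
#'
#' @param true_alpha_gk Goalkeeper anticipation angle to plant, degrees.
#' @param true_orientations Named vector `(shoulders, hips, support_foot)`
#'   of kicker orientation angles at ball contact, degrees.
#' @param gk_foot_moves Named vector `(left, right)` of goalkeeper foot
#'   displacements, meters.
#' @param kicking_foot `"right"` or `"left"`.
#' @param camera_homography Field-to-image `homography` (default broadcast
#'   view).
#' @param pixel_noise_sd Isotropic Gaussian pixel noise SD (px).
#' @param confidence_mean,confidence_sd,confidence_floor Normal law for the
#'   decorative landmark confidence scores, clipped to
#'   `[confidence_floor, 1]`.
#' @param fps Frame rate.
#' @param n_frames Number of generated frames; run-up start is frame 0 and
#'   ball contact the last frame, with landmarks linearly interpolated in
#'   field coordinates between the two posed moments.
#' @param seed Integer seed driving all randomness of the scene.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(true_alpha_gk = 30,
                         true_orientations = c(shoulders = 20, hips = 15,
                                               support_foot = 5),
                         gk_foot_moves = c(left = 0.6, right = 0.4),
                         kicking_foot = "right",
                         camera_homography = default_camera_homography(),
                         pixel_noise_sd = 0,
                         confidence_mean = 0.8, confidence_sd = 0.14,
                         confidence_floor = 0,
                         fps = 25, n_frames = 10L, seed = 1L) {
  if (pixel_noise_sd < 0) pp_stop("pixel_noise_sd must be >= 0",
                                  "pp_config_error")
  if (n_frames < 2L) pp_stop("n_frames must be >= 2", "pp_config_error")
  if (!inherits(camera_homography, "homography"))
    camera_homography <- homography(camera_homography)
  structure(list(true_alpha_gk = true_alpha_gk,
                 true_orientations = true_orientations,
                 gk_foot_moves = gk_foot_moves,
                 kicking_foot = kicking_foot,
                 camera_homography = camera_homography,
                 pixel_noise_sd = pixel_noise_sd,
                 confidence_mean = confidence_mean,
                 confidence_sd = confidence_sd,
                 confidence_floor = confidence_floor,
                 fps = fps, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# unit vector of the right-minus-left pair direction for a facing angle
pair_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(sin(a), -cos(a))
}

# 25 x 2 field-coordinate landmark matrix (NA rows = undetected)
empty_skeleton <- function() {
  m <- matrix(NA_real_, 25L, 2L)
  rownames(m) <- body25_parts()
  m
}

kicker_skeleton <- function(center, foot_center, ori, kicking_foot) {
  sk <- empty_skeleton()
  u_sh <- pair_direction(ori[["shoulders"]])
  u_hi <- pair_direction(ori[["hips"]])
  u_sf <- pair_direction(ori[["support_foot"]])
  sk["LShoulder", ] <- center - 0.20 * u_sh + c(0, 0)
  sk["RShoulder", ] <- center + 0.20 * u_sh
  sk["Neck", ] <- center
  sk["LHip", ] <- center - 0.15 * u_hi
  sk["RHip", ] <- center + 0.15 * u_hi
  sk["MidHip", ] <- center
  toe_l <- foot_center - 0.06 * u_sf  # pair's left point
  toe_r <- foot_center + 0.06 * u_sf
  if (kicking_foot == "right") {
    # left support foot: hallux (LBigToe) is the medial / right point
    sk["LSmallToe", ] <- toe_l
    sk["LBigToe", ] <- toe_r
    sk["LAnkle", ] <- foot_center + c(-0.15, 0)
  } else {
    sk["RBigToe", ] <- toe_l
    sk["RSmallToe", ] <- toe_r
    sk["RAnkle", ] <- foot_center + c(-0.15, 0)
  }
  sk
}

gk_skeleton <- function(midhip, axis_deg, ankle_left, ankle_right) {
  sk <- empty_skeleton()
  a <- axis_deg * pi / 180
  d <- c(cos(a), sin(a))          # neck-to-mid-hip direction
  sk["MidHip", ] <- midhip
  # the ground-plane homography maps the elevated neck point meters behind
  # the hip projection, so the projected body axis is long (~4 m)
  sk["Neck", ] <- midhip - 4.0 * d
  sk["LAnkle", ] <- ankle_left
  sk["RAnkle", ] <- ankle_right
  sk
}

field_to_person_frame <- function(sk_field, cam_H, frame_index, person_index,
                                  noise_sd, conf) {
  lm <- matrix(0, 25L, 3L)
  for (i in seq_len(25L)) {
    if (any(is.na(sk_field[i, ]))) next
    img <- project_point(cam_H, sk_field[i, ])
    lm[i, 1:2] <- img + stats::rnorm(2L, 0, noise_sd)
    lm[i, 3] <- conf[i]
  }
  person_frame(frame_index, person_index, lm)
}

#' Simulate one penalty scene
#'
#' Poses a kicker and a goalkeeper in field coordinates so that the
#' noise-free pipeline recovers the configured anticipation angle, body
#' orientations and foot displacements exactly, then projects the skeletons
#' to image pixels through the camera homography, adds Gaussian pixel noise
#' and draws decorative landmark confidences. All randomness flows from
#' `config$seed`.
#'
#' @param config A [scene_config()].
#' @return List with `kicker_track`, `gk_track` ([build_tracks()]-style
#'   `track` objects), `corners` (correspondence data frame), `annotation`
#'   (one-row moment annotation), and `truth` (the planted parameter
#'   record).
#' @export
simulate_scene <- function(config = scene_config()) {
  set.seed(config$seed)
  cam <- config$camera_homography
  f1 <- 0L
  f2 <- config$n_frames - 1L

  # kicker: run-up start far from the ball, ball contact beside the spot
  kick1 <- kicker_skeleton(c(-15.5, 1.2), c(-15.3, 1.4),
                           config$true_orientations, config$kicking_foot)
  kick2 <- kicker_skeleton(c(-11.4, 0.25), c(-11.35, 0.35),
                           config$true_orientations, config$kicking_foot)

  # upright keeper: neck's ground projection falls behind the goal line, so
  # the neck-to-mid-hip direction points toward the camera (-x)
  axis0 <- 180
  gk1 <- gk_skeleton(c(0.8, 0), axis0, c(0.6, 0.4), c(0.6, -0.4))
  dl <- config$gk_foot_moves[["left"]] * c(0.6, 0.8)
  dr <- config$gk_foot_moves[["right"]] * c(0.6, -0.8)
  gk2 <- gk_skeleton(c(0.8, -0.3), axis0 + config$true_alpha_gk,
                     c(0.6, 0.4) + dl, c(0.6, -0.4) + dr)

  draw_conf <- function() pmin(1, pmax(config$confidence_floor,
    stats::rnorm(25L, config$confidence_mean, config$confidence_sd)))

  kicker_frames <- list()
  gk_frames <- list()
  for (fi in f1:f2) {
    t <- (fi - f1) / (f2 - f1)
    kf <- kick1 * (1 - t) + kick2 * t
    gf <- gk1 * (1 - t) + gk2 * t
    kicker_frames[[as.character(fi)]] <-
      field_to_person_frame(kf, cam, fi, 0L, config$pixel_noise_sd,
                            draw_conf())
    gk_frames[[as.character(fi)]] <-
      field_to_person_frame(gf, cam, fi, 1L, config$pixel_noise_sd,
                            draw_conf())
  }
  truth <- list(alpha_gk = config$true_alpha_gk,
                orientations = config$true_orientations,
                foot_moves = config$gk_foot_moves,
                kicking_foot = config$kicking_foot,
                runup_start_frame = f1, ball_contact_frame = f2,
                fps = config$fps)
  list(kicker_track = structure(list(role = "kicker", frames = kicker_frames),
                                class = "track"),
       gk_track = structure(list(role = "goalkeeper", frames = gk_frames),
                            class = "track"),
       corners = default_field_corners(),
       annotation = data.frame(penalty_id = "synthetic",
                               runup_start_frame = f1,
                               ball_contact_frame = f2, fps = config$fps),
       truth = truth,
       config = config)
}

#' Write a simulated scene as pipeline-readable files
#'
#' Emits the per-frame keypoint JSON files (both persons per frame), the
#' corner-correspondence CSV and the moment-annotation CSV that
#' [run_pipeline()] consumes.
#'
#' @param scene Output of [simulate_scene()].
#' @param dir Output directory.
#' @param penalty_id Identifier used in file names and the annotation.
#' @return Invisibly, a list of the written paths.
#' @export
write_scene_bundle <- function(scene, dir, penalty_id = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kp_dir <- file.path(dir, "keypoints")
  frames <- c(unname(scene$kicker_track$frames), unname(scene$gk_track$frames))
  write_openpose_frames(frames, kp_dir, prefix = penalty_id)
  corners_path <- file.path(dir, "corners.csv")
  utils::write.csv(scene$corners, corners_path, row.names = FALSE)
  ann <- scene$annotation
  ann$penalty_id <- penalty_id
  ann_path <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, ann_path, row.names = FALSE)
  invisible(list(keypoints = kp_dir, corners = corners_path,
                 annotations = ann_path))
}

## ---- coded-dataset simulation ---------------------------------------------

#' Population phi coefficient of a 2 x 2 probability table
#'
#' `phi = |p11 p22 - p12 p21| / sqrt(p1. p2. p.1 p.2)` for a joint
#' probability table; the population counterpart of Cramer's V for 2 x 2
#' tables.
#'
#' @param joint 2 x 2 matrix of joint probabilities (non-negative, summing
#'   to 1, non-degenerate margins).
#' @return Phi in `[0, 1]`.
#' @export
population_phi <- function(joint) {
  m <- as.matrix(joint)
  if (any(dim(m) != 2L) || any(m < 0) || abs(sum(m) - 1) > 1e-9)
    pp_stop("joint must be a 2x2 probability table summing to 1",
            "pp_domain_error")
  marg <- c(rowSums(m), colSums(m))
  if (any(marg <= 0))
    pp_stop("degenerate margin in probability table", "pp_degenerate_error")
  unname(abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) / sqrt(prod(marg)))
}

#' Study-simulation configuration
#'
#' Defaults emulate the study conditions this package targets: 34 coded
#' penalties, a balanced goalkeeper strategy, the keeper's tactical action
#' strongly associated with their strategy (population phi 0.8), the
#' kicker's run-up speed moderately associated (phi 0.35), a large
#' strategy-dependent shift in the anticipation angle, and every other
#' variable independent of the strategy.
#'
#' @param n_penalties Number of simulated penalties.
#' @param strategy_prevalence Probability of the dependent strategy.
#' @param outcome Which strategy variable the binary label drives
#'   (`"gk_strategy"` or `"taker_strategy"`).
#' @param conditional_probs Named list: OSPAF variable ->
#'   `P(level | strategy)` matrix with 2 rows (independent, dependent
#'   strategy) and one column per level (colnames = levels, rows sum to 1).
#'   Variables not listed are drawn uniformly, independent of the strategy.
#' @param numeric_effects Named list: numeric variable ->
#'   `c(mean, shift, sd)`; values are drawn `N(mean + shift * strategy,
#'   sd)`.
#' @param seed Integer seed.
#' @return List of class `sim_study_config`.
#' @export
sim_study_config <- function(n_penalties = 34L,
                             strategy_prevalence = 0.5,
                             outcome = "gk_strategy",
                             conditional_probs = list(
                               gk_tactical_action = matrix(
                                 c(0.1, 0.9, 0.9, 0.1), 2L, byrow = TRUE,
                                 dimnames = list(NULL, c("await", "guess"))),
                               run_up_speed = matrix(
                                 c(0.675, 0.325, 0.325, 0.675), 2L,
                                 byrow = TRUE,
                                 dimnames = list(NULL, c("fast", "slow")))),
                             numeric_effects = list(
                               alpha_gk = c(mean = 70, shift = -50, sd = 10),
                               ball_speed = c(mean = 27, shift = 0, sd = 2.5)),
                             seed = 1L) {
  for (v in names(conditional_probs)) {
    p <- conditional_probs[[v]]
    if (nrow(p) != 2L || any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
      pp_stop(sprintf(
        "conditional probabilities for '%s' must be a 2-row matrix with rows summing to 1",
        v), "pp_config_error")
  }
  if (!(strategy_prevalence > 0 && strategy_prevalence < 1))
    pp_stop("strategy_prevalence must be in (0, 1)", "pp_config_error")
  structure(list(n_penalties = as.integer(n_penalties),
                 strategy_prevalence = strategy_prevalence,
                 outcome = outcome,
                 conditional_probs = conditional_probs,
                 numeric_effects = numeric_effects,
                 seed = as.integer(seed)),
            class = "sim_study_config")
}

#' Simulate a coded penalty dataset with a planted strategy association
#'
#' Draws the binary strategy at the configured prevalence, each listed
#' OSPAF variable from its strategy-conditional law, every other OSPAF
#' variable uniformly and independently, and each numeric variable from a
#' Gaussian whose mean shifts with the strategy. Returns the population phi
#' of every 2-level conditioned variable so association-recovery tests have
#' an exact target.
#'
#' @param config A [sim_study_config()].
#' @return List with `features` (per-penalty analysis table) and
#'   `population` (prevalence and named population phi values).
#' @export
simulate_ospaf_dataset <- function(config = sim_study_config()) {
  set.seed(config$seed)
  n <- config$n_penalties
  schema <- ospaf_schema()
  strategy <- stats::rbinom(n, 1L, config$strategy_prevalence)

  pos <- strategy_positive_level(config$outcome)
  neg <- setdiff(schema[[config$outcome]], c(pos, "unclear"))
  features <- data.frame(penalty_id = sprintf("pk%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
  for (v in setdiff(names(schema), config$outcome)) {
    cp <- config$conditional_probs[[v]]
    features[[v]] <- if (is.null(cp)) {
      sample(schema[[v]], n, replace = TRUE)
    } else {
      vapply(strategy + 1L, function(s)
        sample(colnames(cp), 1L, prob = cp[s, ]), "")
    }
  }
  features[[config$outcome]] <- ifelse(strategy == 1L, pos, neg)
  for (v in names(config$numeric_effects)) {
    eff <- config$numeric_effects[[v]]
    features[[v]] <- stats::rnorm(n, eff[["mean"]] + eff[["shift"]] * strategy,
                                  eff[["sd"]])
  }

  phi <- list()
  pi1 <- config$strategy_prevalence
  for (v in names(config$conditional_probs)) {
    cp <- config$conditional_probs[[v]]
    if (ncol(cp) == 2L) {
      joint <- rbind((1 - pi1) * cp[1L, ], pi1 * cp[2L, ])
      phi[[v]] <- population_phi(joint)
    }
  }
  list(features = features,
       population = list(prevalence = pi1, phi = phi,
                         outcome = config$outcome))
}
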