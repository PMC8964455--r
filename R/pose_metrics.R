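# Pose-derived penalty variables: body-orientation angles of the kicker,
# goalkeeper anticipation angle, foot displacements, and a ball-speed helper.

deg <- function(rad) rad * 180 / pi

#' Body orientation from a left-right landmark pair
#'
#' The segment between an anatomically left and right landmark (shoulders,
#' hips, or hallux / fifth toe of the support foot), projected onto the
#' field plane, defines the player's facing: the facing vector is the
#' right-to-left segment direction `right - left` rotated +90 degrees
#' counter-clockwise. The angle is measured counter-clockwise from +x
#' (toward the attacked goal) in `[0, 360)`. Orientation toward the right
#' half of the field (angles in `[0, 90)` or `[270, 360)`) codes the side as
#' `"right"`, toward `[90, 270)` as `"left"`; the boundary angles 90 and 270
#' fall to left and right respectively (half-open buckets).
#'
#' @param left_point,right_point Field points (x, y) in meters.
#' @param confidences Length-2 confidence scores of the two landmarks.
#' @return List with `angle` (degrees), `side` (`"right"`/`"left"`), and
#'   `confidence` (mean of the pair's scores); class `orientation_measure`.
#' @export
pair_orientation <- function(left_point, right_point, confidences = c(NA, NA)) {
  d <- c(right_point[1] - left_point[1], right_point[2] - left_point[2])
  if (sqrt(sum(d^2)) <= 1e-6)
    pp_stop("left and right landmarks coincide (degenerate pair)",
            "pp_degenerate_error")
  facing <- unname(c(-d[2], d[1]))  # +90 deg counter-clockwise
  angle <- deg(atan2(facing[2], facing[1])) %% 360
  side <- if (angle < 90 || angle >= 270) "right" else "left"
  structure(list(angle = angle, side = side,
                 confidence = mean(as.numeric(confidences))),
            class = "orientation_measure")
}

#' @export
print.orientation_measure <- function(x, ...) {
  cat(sprintf("<orientation> %.1f deg, side %s, confidence %.2f\n",
              x$angle, x$side, x$confidence))
  invisible(x)
}

# (left, right) BODY_25 part indices for each measured pair
pair_parts <- function(measure, kicking_foot) {
  switch(measure,
    shoulders = c(5L, 2L),
    hips = c(12L, 9L),
    support_foot = if (kicking_foot == "right") {
      # left support foot: hallux (19) is medial = player's right of the pair
      c(20L, 19L)
    } else {
      # right support foot: hallux (22) is medial = player's left of the pair
      c(22L, 23L)
    })
}

#' Kicker body orientations at one frame
#'
#' Projects the shoulder, hip and support-foot landmark pairs to field
#' coordinates and derives one [pair_orientation()] measure per pair. The
#' support foot is the foot contralateral to the kicking foot; its pair is
#' the hallux (big toe) and fifth toe, with the hallux taken as the medial
#' point. A pair with a missing landmark yields `NULL` for that measure
#' only; the other measures are still returned.
#'
#' @param frame `person_frame` of the kicker.
#' @param H Image-to-field [homography].
#' @param kicking_foot `"right"` or `"left"`.
#' @param conf_floor Landmark confidence acceptance floor.
#' @return Named list `shoulders`, `hips`, `support_foot`, each an
#'   `orientation_measure` or `NULL` when a landmark is missing.
#' @export
kicker_orientations <- function(frame, H, kicking_foot = c("right", "left"),
                                conf_floor = PP_CONF_FLOOR) {
  kicking_foot <- match.arg(kicking_foot)
  out <- list()
  for (measure in c("shoulders", "hips", "support_foot")) {
    parts <- pair_parts(measure, kicking_foot)
    l <- get_part(frame, parts[1L], conf_floor)
    r <- get_part(frame, parts[2L], conf_floor)
    out[[measure]] <- if (is.null(l) || is.null(r)) NULL else {
      pair_orientation(project_point(H, l[1:2]), project_point(H, r[1:2]),
                       c(l[3], r[3]))
    }
  }
  out
}

#' Goalkeeper anticipation angle
#'
#' The goalkeeper's body axis is the directed neck-to-mid-hip vector; the
#' anticipation angle is the angle between the axes at run-up start and at
#' ball contact, in `[0, 180]` degrees. A keeper who holds posture scores
#' near 0, one who commits early into a lean scores high. The measure's
#' confidence is the mean of the four landmark scores.
#'
#' @param neck_1,midhip_1 Points at the first moment (field coordinates).
#' @param neck_2,midhip_2 Points at the second moment.
#' @param confidences Length-4 confidence scores (neck, mid-hip at each
#'   moment).
#' @return List with `alpha_gk` (degrees) and `confidence`.
#' @export
anticipation_angle <- function(neck_1, midhip_1, neck_2, midhip_2,
                               confidences = rep(NA, 4)) {
  v1 <- c(midhip_1[1] - neck_1[1], midhip_1[2] - neck_1[2])
  v2 <- c(midhip_2[1] - neck_2[1], midhip_2[2] - neck_2[2])
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= 1e-9 || n2 <= 1e-9)
    pp_stop("degenerate neck-to-mid-hip segment", "pp_degenerate_error")
  cosang <- unname(min(1, max(-1, sum(v1 * v2) / (n1 * n2))))
  list(alpha_gk = deg(acos(cosang)),
       confidence = mean(as.numeric(confidences)))
}

#' Goalkeeper foot displacements between the two analyzed moments
#'
#' Ankles stand in for the feet; displacement is the Euclidean distance in
#' field meters between the projected ankle positions at run-up start and
#' ball contact. A missing ankle at either moment yields `NA` for that foot.
#'
#' @param gk_frame_1,gk_frame_2 Goalkeeper `person_frame`s at the two
#'   moments.
#' @param H Image-to-field [homography].
#' @param conf_floor Landmark confidence acceptance floor.
#' @return Named numeric `(d_gk_left, d_gk_right)` in meters (possibly NA).
#' @export
foot_displacements <- function(gk_frame_1, gk_frame_2, H,
                               conf_floor = PP_CONF_FLOOR) {
  one <- function(part) {
    a <- get_part(gk_frame_1, part, conf_floor)
    b <- get_part(gk_frame_2, part, conf_floor)
    if (is.null(a) || is.null(b)) return(NA_real_)
    sqrt(sum((project_point(H, a[1:2]) - project_point(H, b[1:2]))^2))
  }
  c(d_gk_left = one(14L), d_gk_right = one(11L))
}

#' Ball speed from two field positions
#'
#' @param p1,p2 Field points (meters) at the two frames.
#' @param frame_gap Number of frames between the positions (>= 1).
#' @param fps Video frame rate (frames/s, > 0).
#' @return Speed in m/s.
#' @export
ball_speed <- function(p1, p2, frame_gap, fps) {
  if (fps <= 0) pp_stop("fps must be > 0", "pp_domain_error")
  if (frame_gap < 1) pp_stop("frame_gap must be >= 1", "pp_domain_error")
  sqrt(sum((c(p2[1], p2[2]) - c(p1[1], p1[2]))^2)) * fps / frame_gap
}

## ---- per-penalty extraction ------------------------------------------------

resolve_or_relax <- function(track, target, requirement_sets, max_offset,
                             conf_floor) {
  for (req in requirement_sets) {
    idx <- tryCatch(resolve_frame(track, target, req, max_offset, conf_floor),
                    pp_resolution_error = function(e) NULL)
    if (!is.null(idx)) return(idx)
  }
  pp_stop(sprintf("no usable frame near frame %d", target),
          "pp_resolution_error")
}

measure_na <- function(m, what) {
  if (is.null(m)) NA_real_
  else switch(what, angle = m$angle, side = m$side, conf = m$confidence)
}

#' Extract the full pose-metric record for one penalty
#'
#' Runs the two-moment analysis: kicker orientations (shoulders, hips,
#' support foot) at ball contact, goalkeeper anticipation angle between
#' run-up start and ball contact, and goalkeeper foot displacements. When a
#' required landmark is undetected at an annotated moment the nearest
#' neighbouring frame with the needed parts is used; measures whose
#' landmarks are missing everywhere in the window are flagged `NA`.
#'
#' @param kicker_track,gk_track `track` objects for the two players.
#' @param H Image-to-field [homography].
#' @param runup_start_frame,ball_contact_frame Annotated moment frames.
#' @param kicking_foot `"right"` or `"left"`.
#' @param max_offset Neighbour-frame search window.
#' @param conf_floor Landmark confidence acceptance floor.
#' @return One-row data frame with columns `alpha_sh, lr_sh, c_sh, alpha_hi,
#'   lr_hi, c_hi, alpha_sf, lr_sf, c_sf, alpha_gk, d_gkl, d_gkr, c_gk`.
#' @export
extract_penalty_metrics <- function(kicker_track, gk_track, H,
                                    runup_start_frame, ball_contact_frame,
                                    kicking_foot = "right",
                                    max_offset = 5L,
                                    conf_floor = PP_CONF_FLOOR) {
  toe_parts <- pair_parts("support_foot", kicking_foot)
  kicker_req <- list(c(2L, 5L, 9L, 12L, toe_parts), c(2L, 5L, 9L, 12L),
                     c(2L, 5L), integer(0))
  kf <- track_frame(kicker_track,
                    resolve_or_relax(kicker_track, ball_contact_frame,
                                     kicker_req, max_offset, conf_floor))
  ori <- kicker_orientations(kf, H, kicking_foot, conf_floor)

  gk_req <- list(c(1L, 8L, 11L, 14L), c(1L, 8L), integer(0))
  g1 <- track_frame(gk_track,
                    resolve_or_relax(gk_track, runup_start_frame, gk_req,
                                     max_offset, conf_floor))
  g2 <- track_frame(gk_track,
                    resolve_or_relax(gk_track, ball_contact_frame, gk_req,
                                     max_offset, conf_floor))

  n1 <- get_part(g1, 1L, conf_floor); h1 <- get_part(g1, 8L, conf_floor)
  n2 <- get_part(g2, 1L, conf_floor); h2 <- get_part(g2, 8L, conf_floor)
  ant <- if (is.null(n1) || is.null(h1) || is.null(n2) || is.null(h2)) {
    list(alpha_gk = NA_real_, confidence = NA_real_)
  } else {
    anticipation_angle(project_point(H, n1[1:2]), project_point(H, h1[1:2]),
                       project_point(H, n2[1:2]), project_point(H, h2[1:2]),
                       c(n1[3], h1[3], n2[3], h2[3]))
  }
  disp <- foot_displacements(g1, g2, H, conf_floor)

  data.frame(
    alpha_sh = measure_na(ori$shoulders, "angle"),
    lr_sh = measure_na(ori$shoulders, "side"),
    c_sh = measure_na(ori$shoulders, "conf"),
    alpha_hi = measure_na(ori$hips, "angle"),
    lr_hi = measure_na(ori$hips, "side"),
    c_hi = measure_na(ori$hips, "conf"),
    alpha_sf = measure_na(ori$support_foot, "angle"),
    lr_sf = measure_na(ori$support_foot, "side"),
    c_sf = measure_na(ori$support_foot, "conf"),
    alpha_gk = ant$alpha_gk,
    d_gkl = unname(disp["d_gk_left"]),
    d_gkr = unname(disp["d_gk_right"]),
    c_gk = ant$confidence,
    stringsAsFactors = FALSE)
}
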