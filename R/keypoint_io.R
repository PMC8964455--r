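# Reading, validating and indexing 25-landmark pose-estimator output.

#' BODY_25 part catalogue
#'
#' Names of the 25 skeleton landmarks emitted by common 2D pose estimators,
#' in catalogue order (part index 0 to 24).
#'
#' @return Character vector of length 25; element `i + 1` names part index `i`.
#' @export
body25_parts <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
    "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar", "LBigToe",
    "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")
}

#' Default confidence acceptance floor
#'
#' Landmarks whose confidence score falls below this value are treated as
#' missing, in addition to the (0, 0, 0) sentinel. The floor catches
#' near-zero garbage detections that carry a nominally non-zero score.
#' @export
PP_CONF_FLOOR <- 0.05

pp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "penaltypose_error")))
}

#' Construct a single-person single-frame skeleton
#'
#' @param frame_index Integer frame number (>= 0).
#' @param person_index Integer person slot within the frame (>= 0).
#' @param landmarks Numeric 25 x 3 matrix, columns x (px), y (px,
#'   downward-positive image convention) and confidence in `[0, 1]`.
#' @return An object of class `person_frame`.
#' @export
person_frame <- function(frame_index, person_index, landmarks) {
  landmarks <- as.matrix(landmarks)
  if (!is.numeric(landmarks) || nrow(landmarks) != 25L || ncol(landmarks) != 3L)
    pp_stop("landmarks must be a numeric 25 x 3 matrix", "pp_format_error")
  conf <- landmarks[, 3]
  ok <- is.na(conf) | (conf >= 0 & conf <= 1)
  if (!all(ok))
    pp_stop("confidence scores must lie in [0, 1]", "pp_format_error")
  dimnames(landmarks) <- list(body25_parts(), c("x", "y", "confidence"))
  structure(list(frame_index = as.integer(frame_index),
                 person_index = as.integer(person_index),
                 landmarks = landmarks),
            class = "person_frame")
}

#' @export
print.person_frame <- function(x, ...) {
  n_miss <- sum(apply(x$landmarks, 1, function(l) all(l == 0)))
  cat(sprintf("<person_frame> frame %d, person %d, %d/25 landmarks detected\n",
              x$frame_index, x$person_index, 25L - n_miss))
  invisible(x)
}

is_missing_landmark <- function(lm, conf_floor = PP_CONF_FLOOR) {
  all(lm == 0) || is.na(lm[3]) || lm[3] < conf_floor
}

#' Fetch one landmark from a skeleton
#'
#' Returns the landmark, or `NULL` when the landmark is missing: either the
#' pose-estimator sentinel (0, 0, 0) or a confidence below the acceptance
#' floor.
#'
#' @param frame A `person_frame`.
#' @param part BODY_25 part index, 0 to 24 (e.g. 1 = Neck, 8 = MidHip).
#' @param conf_floor Minimum confidence for a landmark to be accepted.
#' @return Named numeric vector `(x, y, confidence)`, or `NULL` if missing.
#' @export
get_part <- function(frame, part, conf_floor = PP_CONF_FLOOR) {
  if (!is.numeric(part) || length(part) != 1L || part < 0 || part > 24)
    pp_stop(sprintf("part index must be in 0..24, got %s", toString(part)),
            "pp_domain_error")
  lm <- frame$landmarks[part + 1L, ]
  if (is_missing_landmark(lm, conf_floor)) return(NULL)
  lm
}

## ---- reading ---------------------------------------------------------------

parse_people_json <- function(path, frame_index) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  people <- doc$people
  if (is.null(people)) people <- list()
  out <- vector("list", length(people))
  for (i in seq_along(people)) {
    kp <- unlist(people[[i]]$pose_keypoints_2d, use.names = FALSE)
    if (length(kp) != 75L)
      pp_stop(sprintf(
        "frame %d person %d: expected 75 values in pose_keypoints_2d, got %d",
        frame_index, i - 1L, length(kp)), "pp_format_error")
    out[[i]] <- person_frame(frame_index, i - 1L,
                             matrix(kp, ncol = 3L, byrow = TRUE))
  }
  out
}

frame_index_from_name <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("([0-9]+)_keypoints", basename(path)))
  if (length(m) == 0L)
    pp_stop(sprintf("cannot parse frame index from file name '%s'",
                    basename(path)), "pp_format_error")
  as.integer(sub("_keypoints", "", m))
}

#' Read pose-estimator keypoint output
#'
#' Reads per-frame keypoint JSON (the `<prefix>_<frame:012d>_keypoints.json`
#' layout, each file holding a `people` list with 75 floats of
#' `pose_keypoints_2d` per person) or a consolidated long CSV with columns
#' `frame, person, part, x, y, conf`. `(0, 0, 0)` triplets are kept verbatim
#' and act as the missing-landmark sentinel downstream.
#'
#' @param source Path to a keypoint JSON file, a directory of them, or a CSV.
#' @param dialect `"auto"` (default), `"json"`, `"json_dir"`, or `"csv"`.
#' @return List of [person_frame] objects, ordered by frame then person.
#' @export
read_openpose_frames <- function(source,
                                 dialect = c("auto", "json", "json_dir", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source))
    pp_stop(sprintf("keypoint source '%s' does not exist", source),
            "pp_io_error")
  if (dialect == "auto") {
    dialect <- if (dir.exists(source)) "json_dir"
               else if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv"
               else "json"
  }
  if (dialect == "json_dir") {
    files <- sort(list.files(source, pattern = "_keypoints\\.json$",
                             full.names = TRUE))
    if (length(files) == 0L)
      pp_stop(sprintf("no *_keypoints.json files under '%s'", source),
              "pp_io_error")
    frames <- lapply(files, function(f)
      parse_people_json(f, frame_index_from_name(f)))
    out <- do.call(c, frames)
  } else if (dialect == "json") {
    out <- parse_people_json(source, frame_index_from_name(source))
  } else {
    df <- utils::read.csv(source)
    need <- c("frame", "person", "part", "x", "y", "conf")
    if (!all(need %in% names(df)))
      pp_stop(sprintf("keypoint CSV must have columns %s", toString(need)),
              "pp_format_error")
    out <- list()
    for (key in split(df, list(df$frame, df$person), drop = TRUE)) {
      if (nrow(key) != 25L || !setequal(key$part, 0:24))
        pp_stop(sprintf(
          "frame %d person %d: expected 75 values (25 parts), got %d rows",
          key$frame[1], key$person[1], nrow(key)), "pp_format_error")
      key <- key[order(key$part), ]
      out[[length(out) + 1L]] <-
        person_frame(key$frame[1], key$person[1],
                     cbind(key$x, key$y, key$conf))
    }
  }
  ord <- order(vapply(out, `[[`, 0L, "frame_index"),
               vapply(out, `[[`, 0L, "person_index"))
  out[ord]
}

#' Write skeletons back to per-frame keypoint JSON
#'
#' Inverse of [read_openpose_frames()] for the JSON dialect; landmark values
#' are written at full double precision so a read/write/read round trip is
#' lossless.
#'
#' @param frames List of `person_frame` objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_openpose_frames <- function(frames, dir, prefix = "clip") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- vapply(frames, `[[`, 0L, "frame_index")
  paths <- character(0)
  for (fi in sort(unique(idx))) {
    ppl <- frames[idx == fi]
    ppl <- ppl[order(vapply(ppl, `[[`, 0L, "person_index"))]
    doc <- list(version = 1.3, people = lapply(ppl, function(p) list(
      person_id = list(-1L),
      pose_keypoints_2d = as.numeric(t(p$landmarks)))))
    path <- file.path(dir, sprintf("%s_%012d_keypoints.json", prefix, fi))
    # 17 significant digits: lossless double round trip
    jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

## ---- tracks ----------------------------------------------------------------

#' Assemble per-person tracks from a flat frame list
#'
#' Links person detections across frames. When a frame holds the same number
#' of persons as the previous one, identity follows greedy nearest-MidHip
#' linking (falling back to stable ordering when MidHip is missing); scenes
#' with a single kicker and a single goalkeeper make this sufficient.
#'
#' @param frames List of `person_frame` objects.
#' @return List of objects of class `track`, each
#'   `list(role, frames)` with `role` initially `"unassigned"` and `frames`
#'   keyed (named) by frame index.
#' @export
build_tracks <- function(frames) {
  idx <- vapply(frames, `[[`, 0L, "frame_index")
  tracks <- list()
  anchors <- list()  # last known MidHip per track
  for (fi in sort(unique(idx))) {
    ppl <- frames[idx == fi]
    ppl <- ppl[order(vapply(ppl, `[[`, 0L, "person_index"))]
    hips <- lapply(ppl, function(p) get_part(p, 8L))
    assigned <- rep(NA_integer_, length(ppl))
    if (length(tracks) > 0L) {
      free_tracks <- seq_along(tracks)
      for (j in seq_along(ppl)) {
        if (length(free_tracks) == 0L) break
        if (!is.null(hips[[j]])) {
          d <- vapply(free_tracks, function(t) {
            a <- anchors[[t]]
            if (is.null(a)) Inf else sqrt(sum((a - hips[[j]][1:2])^2))
          }, 0)
          if (any(is.finite(d))) {
            assigned[j] <- free_tracks[which.min(d)]
            free_tracks <- setdiff(free_tracks, assigned[j])
          }
        }
      }
      # stable-order fallback for persons without a usable MidHip
      for (j in which(is.na(assigned))) {
        if (length(free_tracks) == 0L) break
        assigned[j] <- free_tracks[1L]
        free_tracks <- free_tracks[-1L]
      }
    }
    for (j in seq_along(ppl)) {
      t <- assigned[j]
      if (is.na(t)) {
        tracks[[length(tracks) + 1L]] <-
          structure(list(role = "unassigned", frames = list()),
                    class = "track")
        anchors[[length(tracks)]] <- NULL
        t <- length(tracks)
      }
      key <- as.character(fi)
      if (!is.null(tracks[[t]]$frames[[key]]))
        pp_stop(sprintf("track %d already holds frame %d", t, fi),
                "pp_format_error")
      tracks[[t]]$frames[[key]] <- ppl[[j]]
      if (!is.null(hips[[j]])) anchors[[t]] <- hips[[j]][1:2]
    }
  }
  tracks
}

track_frame <- function(track, frame_index) {
  track$frames[[as.character(frame_index)]]
}

#' Resolve the nearest usable frame around an annotated moment
#'
#' Pose estimators fail on blurred or occluded frames; when the annotated
#' moment lacks a required landmark, the closest neighbouring frame in which
#' all required parts are detected is used instead. Ties between equally
#' close frames resolve to the earlier one.
#'
#' @param track A `track`.
#' @param target Annotated frame index.
#' @param required_parts Integer vector of BODY_25 part indices that must all
#'   be non-missing.
#' @param max_offset Maximum search distance in frames (0 = target only).
#' @param conf_floor Confidence acceptance floor.
#' @return The resolved frame index.
#' @export
resolve_frame <- function(track, target, required_parts,
                          max_offset = 5L, conf_floor = PP_CONF_FLOOR) {
  if (length(track$frames) == 0L)
    pp_stop("track is empty", "pp_resolution_error")
  if (max_offset < 0) pp_stop("max_offset must be >= 0", "pp_domain_error")
  complete_at <- function(fi) {
    pf <- track_frame(track, fi)
    if (is.null(pf)) return(FALSE)
    all(vapply(required_parts,
               function(p) !is.null(get_part(pf, p, conf_floor)), TRUE))
  }
  for (off in 0:max_offset) {
    for (cand in unique(c(target - off, target + off))) {
      if (complete_at(cand)) return(as.integer(cand))
    }
  }
  missing_desc <- paste(body25_parts()[required_parts + 1L], collapse = ", ")
  pp_stop(sprintf(
    "no frame within %d of frame %d has all required parts (%s) detected",
    max_offset, target, missing_desc), "pp_resolution_error")
}

#' Assign kicker and goalkeeper roles
#'
#' Projects each person's MidHip to field coordinates; the person nearest the
#' goal line becomes the goalkeeper and the farthest the kicker. Equidistant
#' persons tie-break to the lower person index as goalkeeper.
#'
#' @param frames List of `person_frame` objects at the ball-contact moment
#'   (>= 2 persons).
#' @param H Image-to-field [homography].
#' @param goal_line_x Field x of the goal line in meters (0 in the default
#'   field frame, whose origin is the center of the attacked goal line).
#' @return Named integer vector with elements `goalkeeper` and `kicker`
#'   holding person indices.
#' @export
assign_roles <- function(frames, H, goal_line_x = 0) {
  if (length(frames) < 2L)
    pp_stop("role assignment needs at least two detected persons",
            "pp_role_error")
  pid <- vapply(frames, `[[`, 0L, "person_index")
  dist_goal <- vapply(frames, function(p) {
    hip <- get_part(p, 8L)
    if (is.null(hip))
      pp_stop(sprintf("person %d: MidHip missing at role-assignment frame",
                      p$person_index), "pp_role_error")
    fp <- project_point(H, hip[1:2])
    abs(fp[1] - goal_line_x)
  }, 0)
  ord <- order(dist_goal, pid)  # nearest goal first; ties -> lower index
  c(goalkeeper = pid[ord[1L]], kicker = pid[ord[length(ord)]])
}

#' Read run-up / ball-contact moment annotations
#'
#' @param path JSON or CSV file with fields `penalty_id`,
#'   `runup_start_frame`, `ball_contact_frame` and `fps`.
#' @return Data frame, one row per penalty.
#' @export
read_moment_annotations <- function(path) {
  if (!file.exists(path))
    pp_stop(sprintf("annotation file '%s' does not exist", path),
            "pp_io_error")
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  need <- c("penalty_id", "runup_start_frame", "ball_contact_frame", "fps")
  if (!all(need %in% names(df)))
    pp_stop(sprintf("annotations must have columns %s", toString(need)),
            "pp_format_error")
  bad <- df$runup_start_frame >= df$ball_contact_frame
  if (any(bad))
    pp_stop(sprintf(
      "penalty %s: runup_start_frame must precede ball_contact_frame",
      toString(df$penalty_id[bad])), "pp_format_error")
  df
}
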