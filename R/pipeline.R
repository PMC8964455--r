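# Pipeline orchestration: extract -> merge -> analyze, plus simulate and
# validate subcommands. A thin command-line front-end over these functions
# ships in inst/cli/penaltypose.

penalty_prefixes <- function(keypoints_dir) {
  files <- list.files(keypoints_dir, pattern = "_keypoints\\.json$")
  unique(sub("_[0-9]+_keypoints\\.json$", "", files))
}

#' Extract pose metrics for every annotated penalty
#'
#' For each penalty in the annotation table: reads its keypoint frames
#' (files named `<penalty_id>_<frame>_keypoints.json`), estimates the
#' image-to-field homography from the corner file (rows may carry a
#' `penalty_id` column for per-clip corners), links persons into tracks,
#' assigns kicker / goalkeeper roles at the ball-contact frame, and computes
#' the per-penalty metric record.
#'
#' @param keypoints Directory of per-frame keypoint JSON files.
#' @param corners Corner-correspondence CSV.
#' @param annotations Moment-annotation CSV/JSON (may carry a
#'   `kicking_foot` column; defaults to `"right"`).
#' @param conf_floor Landmark confidence acceptance floor.
#' @param max_offset Neighbour-frame search window.
#' @param goal_line_x Field x of the goal line (m).
#' @return Data frame: `penalty_id` + the [extract_penalty_metrics()]
#'   columns, one row per penalty.
#' @export
pk_extract <- function(keypoints, corners, annotations,
                       conf_floor = PP_CONF_FLOOR, max_offset = 5L,
                       goal_line_x = 0) {
  ann <- read_moment_annotations(annotations)
  corner_df <- tryCatch(read_corners(corners), penaltypose_error = function(e)
    pp_stop(sprintf("field_geometry stage: %s", conditionMessage(e)),
            "pp_stage_error"))
  out <- list()
  for (i in seq_len(nrow(ann))) {
    pid <- as.character(ann$penalty_id[i])
    step <- function(stage, expr) tryCatch(expr, error = function(e)
      pp_stop(sprintf("%s stage (penalty %s): %s", stage, pid,
                      conditionMessage(e)), "pp_stage_error"))
    cdf <- if ("penalty_id" %in% names(corner_df)) {
      corner_df[corner_df$penalty_id == pid, , drop = FALSE]
    } else corner_df
    H <- step("field_geometry", estimate_homography(cdf))
    files <- list.files(keypoints,
                        pattern = sprintf("^%s_[0-9]+_keypoints\\.json$", pid),
                        full.names = TRUE)
    if (length(files) == 0L)
      pp_stop(sprintf("keypoint_io stage (penalty %s): no keypoint files", pid),
              "pp_stage_error")
    frames <- step("keypoint_io",
                   do.call(c, lapply(files, function(f)
                     parse_people_json(f, frame_index_from_name(f)))))
    tracks <- step("keypoint_io", build_tracks(frames))
    contact <- ann$ball_contact_frame[i]
    at_contact <- Filter(Negate(is.null),
                         lapply(tracks, track_frame, frame_index = contact))
    roles <- step("keypoint_io", assign_roles(at_contact, H, goal_line_x))
    by_person <- vapply(tracks, function(t)
      t$frames[[1L]]$person_index, 0L)
    gk_track <- tracks[[match(roles[["goalkeeper"]], by_person)]]
    kicker_track <- tracks[[match(roles[["kicker"]], by_person)]]
    foot <- if ("kicking_foot" %in% names(ann))
      as.character(ann$kicking_foot[i]) else "right"
    rec <- step("pose_metrics",
                extract_penalty_metrics(kicker_track, gk_track, H,
                                        ann$runup_start_frame[i], contact,
                                        foot, max_offset, conf_floor))
    out[[pid]] <- cbind(data.frame(penalty_id = pid,
                                   stringsAsFactors = FALSE), rec)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a merged per-penalty feature table
#'
#' Schema columns are normalized to canonical level tokens; everything else
#' (pose metrics, ball speed) is coerced to numeric where possible.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_features_table <- function(path) {
  if (!file.exists(path))
    pp_stop(sprintf("feature table '%s' does not exist", path), "pp_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- ospaf_schema()
  for (v in intersect(names(schema), names(df)))
    df[[v]] <- normalize_level(df[[v]])
  df
}

#' Run one pipeline command
#'
#' Dispatches the four pipeline stages over a single configuration list:
#' \describe{
#'   \item{extract}{pose metrics from keypoints + corners + annotations,
#'     written to `metrics.csv`.}
#'   \item{analyze}{strategy association report from a merged feature
#'     table, written as JSON and text.}
#'   \item{simulate}{synthetic scene bundle and coded dataset with ground
#'     truth, written under the output directory.}
#'   \item{validate}{lint an OSPAF table; errors on the first violation.}
#' }
#' Every run writes `run_log.json` (package version, command, config, seed)
#' into the output directory.
#'
#' @param config Named list; recognized fields: `keypoints`, `corners`,
#'   `annotations`, `features`, `ospaf`, `out_dir`, `outcome`, `alpha`,
#'   `conf_floor`, `max_offset`, `goal_line_x`, `seed`, `scene`
#'   (a [scene_config()]), `study` (a [sim_study_config()]).
#' @param command One of `"extract"`, `"analyze"`, `"simulate"`,
#'   `"validate"`.
#' @return The command's primary artifact (data frame, report, or paths),
#'   invisibly for file-writing commands.
#' @export
run_pipeline <- function(config, command = c("extract", "analyze",
                                             "simulate", "validate")) {
  command <- match.arg(command)
  cfg <- function(name, default = NULL)
    if (!is.null(config[[name]])) config[[name]] else default
  out_dir <- cfg("out_dir", ".")
  if (command != "validate")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  result <- switch(command,
    extract = {
      metrics <- pk_extract(cfg("keypoints"), cfg("corners"),
                            cfg("annotations"),
                            cfg("conf_floor", PP_CONF_FLOOR),
                            cfg("max_offset", 5L), cfg("goal_line_x", 0))
      utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      metrics
    },
    analyze = {
      feats <- read_features_table(cfg("features"))
      rep <- strategy_report(feats, cfg("outcome", "gk_strategy"),
                             cfg("alpha", 0.05))
      jsonlite::write_json(
        list(outcome = rep$outcome, alpha = rep$alpha, n = rep$n,
             screening = rep$screening,
             model_ospaf = report_model_block(rep$model_ospaf),
             model_full = report_model_block(rep$model_full),
             accuracy_delta = rep$accuracy_delta),
        file.path(out_dir, "strategy_report.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
      txt <- utils::capture.output(print(rep))
      writeLines(txt, file.path(out_dir, "strategy_report.txt"))
      rep
    },
    simulate = {
      seed <- cfg("seed", 1L)
      scene <- simulate_scene(cfg("scene", scene_config(seed = seed)))
      paths <- write_scene_bundle(scene, out_dir)
      study <- simulate_ospaf_dataset(cfg("study", sim_study_config(seed = seed)))
      write_ospaf_table(study$features, file.path(out_dir, "ospaf.csv"))
      jsonlite::write_json(scene$truth, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      c(paths, list(ospaf = file.path(out_dir, "ospaf.csv")))
    },
    validate = {
      read_ospaf_table(cfg("ospaf"))
    })

  if (command != "validate") {
    log <- list(package = "penaltypose",
                version = as.character(utils::packageVersion("penaltypose")),
                command = command,
                config_hash = sum(utf8ToInt(paste(
                  names(config), sapply(config, function(x)
                    paste(format(x), collapse = ",")), collapse = ";"))),
                seed = cfg("seed", NA),
                r_version = R.version.string)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  invisible(result)
}

report_model_block <- function(m) {
  if (is.null(m)) return(NULL)
  list(coefficients = as.list(m$coefficients), model_chi2 = m$model_chi2,
       df = m$df, p = m$p, accuracy = m$accuracy, separation = m$separation)
}
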