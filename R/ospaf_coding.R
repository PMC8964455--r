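# Data model, validation and I/O for the OSPAF observational coding scheme
# (Observational System for Penalty-kick Analysis in Football): 21
# categorical variables coded per penalty, plus the merge with pose-derived
# metrics and ball speed into one analysis table.

#' OSPAF coding schema
#'
#' Canonical snake_case level tokens for each of the 21 OSPAF variables.
#' `gk_performance` is an ordinal 0-5 scale (0 = keeper moved to the wrong
#' side ... 5 = keeper saved the kick).
#'
#' @return Named list mapping each variable to its character vector of legal
#'   levels.
#' @export
ospaf_schema <- function() {
  list(
    run_up_speed = c("fast", "slow"),
    run_up_fluency = c("continuous", "with_pauses"),
    run_up_angle = c("frontal", "diagonal"),
    number_of_steps = c("1-3", "3-5", "5+"),
    kicking_technique = c("side_foot", "instep"),
    foot_used = c("right", "left"),
    kicker_gaze = c("at_ball", "not_at_ball"),
    gk_initial_posture = c("arms_raised", "arms_down", "arms_perpendicular"),
    deception = c("yes", "no"),
    gk_tactical_action = c("guess", "await"),
    gk_performance = c("0", "1", "2", "3", "4", "5"),
    match_moment = c("first_half", "second_half", "extra_time_or_shootout"),
    location = c("home", "neutral", "away"),
    momentary_result_kicker = c("winning", "drawing", "losing"),
    momentary_result_gk = c("winning", "drawing", "losing"),
    match_importance = c("final", "decisive_knockout", "group_stage",
                         "early_season", "season_final_stages"),
    kick_direction = c("left", "center", "right"),
    kick_height = c("upper", "center", "down"),
    outcome = c("goal", "saved", "missed"),
    taker_strategy = c("gk_dependent", "unclear", "gk_independent"),
    gk_strategy = c("kicker_independent", "unclear", "kicker_dependent")
  )
}

# verbose phrasings -> canonical tokens, applied case-insensitively
ospaf_synonyms <- function() {
  c("continuous running" = "continuous",
    "running with pauses" = "with_pauses",
    "side foot kick" = "side_foot",
    "instep kick" = "instep",
    "gaze at the ball" = "at_ball",
    "at the ball" = "at_ball",
    "not at the ball" = "not_at_ball",
    "arms extended in a position perpendicular to the trunk" = "arms_perpendicular",
    "try to guess" = "guess",
    "awaiting" = "await",
    "awaiting the penalty taker action" = "await",
    "extra time" = "extra_time_or_shootout",
    "shoot out" = "extra_time_or_shootout",
    "shootout" = "extra_time_or_shootout",
    "championship final match" = "final",
    "decisive knockout match" = "decisive_knockout",
    "group stage match" = "group_stage",
    "early season game" = "early_season",
    "match in final stages of the season" = "season_final_stages",
    "saved by goalkeeper" = "saved",
    "shot misses goal" = "missed",
    "goalkeeper dependent" = "gk_dependent",
    "goalkeeper independent" = "gk_independent",
    "kicker dependent" = "kicker_dependent",
    "kicker independent" = "kicker_independent",
    "1-3" = "1-3", "3-5" = "3-5", "+5" = "5+")
}

normalize_level <- function(value) {
  v <- trimws(tolower(as.character(value)))
  v <- gsub("–", "-", v)  # en dash in step ranges
  syn <- ospaf_synonyms()
  hit <- match(v, tolower(names(syn)))
  out <- ifelse(is.na(hit), gsub("[ -]+", "_", v), unname(syn[hit]))
  # step ranges keep their hyphen form
  ifelse(v %in% c("1-3", "3-5", "5+", "+5"),
         ifelse(v == "+5", "5+", v), out)
}

#' Validate one OSPAF record
#'
#' Checks every schema field of a coded penalty against its legal level set.
#' Total on arbitrary input: violations are returned, never raised.
#'
#' @param record Named list or one-row data frame of coded values (canonical
#'   or verbose level spellings).
#' @return Character vector of violations; empty when the record is valid.
#' @export
validate_record <- function(record) {
  schema <- ospaf_schema()
  record <- as.list(record)
  violations <- character(0)
  for (field in names(schema)) {
    if (!field %in% names(record) || is.na(record[[field]])) {
      violations <- c(violations, sprintf("%s: value missing", field))
      next
    }
    value <- normalize_level(record[[field]])
    if (!value %in% schema[[field]]) {
      hint <- if (field == "gk_performance") "valid range 0-5"
              else sprintf("legal levels: %s",
                           paste(schema[[field]], collapse = ", "))
      violations <- c(violations,
                      sprintf("%s: '%s' is not a legal level (%s)",
                              field, record[[field]], hint))
    }
  }
  violations
}

#' Read and validate an OSPAF coding table
#'
#' One row per penalty, the 21 coded columns plus a `penalty_id` key; level
#' strings are normalized case-insensitively to the canonical snake_case
#' tokens of [ospaf_schema()] (verbose phrasings are accepted via a synonym
#' map). Extra columns beyond the schema raise a schema error unless
#' `allow_extra` lists them (numeric companions such as `ball_speed` are
#' always allowed).
#'
#' @param source CSV path.
#' @param allow_extra Character vector of permitted non-schema columns
#'   (default: ball speed and the standard pose-metric columns).
#' @return Data frame of validated, canonical-level records.
#' @export
read_ospaf_table <- function(source,
                             allow_extra = c("ball_speed",
                                             pose_metric_columns())) {
  if (!file.exists(source))
    pp_stop(sprintf("OSPAF table '%s' does not exist", source), "pp_io_error")
  df <- utils::read.csv(source, colClasses = "character")
  schema <- ospaf_schema()
  if (!"penalty_id" %in% names(df))
    pp_stop("OSPAF table must have a penalty_id column", "pp_schema_error")
  unknown <- setdiff(names(df), c("penalty_id", names(schema), allow_extra))
  if (length(unknown) > 0L)
    pp_stop(sprintf("unknown OSPAF column(s): %s", toString(unknown)),
            "pp_schema_error")
  if (anyDuplicated(df$penalty_id))
    pp_stop(sprintf("duplicate penalty_id: %s",
                    toString(unique(df$penalty_id[duplicated(df$penalty_id)]))),
            "pp_schema_error")
  for (field in intersect(names(schema), names(df)))
    df[[field]] <- normalize_level(df[[field]])
  for (i in seq_len(nrow(df))) {
    v <- validate_record(df[i, intersect(names(schema), names(df))])
    if (length(v) > 0L)
      pp_stop(sprintf("row %d (penalty %s): %s",
                      i, df$penalty_id[i], paste(v, collapse = "; ")),
              "pp_validation_error")
  }
  # coerce extra columns to numeric where the conversion is clean
  for (col in intersect(allow_extra, names(df))) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    was_blank <- is.na(df[[col]]) | df[[col]] == ""
    if (!any(is.na(num) & !was_blank)) df[[col]] <- num
  }
  df
}

#' Column names of the per-penalty pose-metric record
#' @return Character vector of the metric-table columns.
#' @export
pose_metric_columns <- function() {
  c("alpha_sh", "lr_sh", "c_sh", "alpha_hi", "lr_hi", "c_hi",
    "alpha_sf", "lr_sf", "c_sf", "alpha_gk", "d_gkl", "d_gkr", "c_gk")
}

#' Write an OSPAF (or merged feature) table to CSV
#' @param table Data frame.
#' @param path Output CSV path.
#' @export
write_ospaf_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Merge OSPAF codes, pose metrics and ball speed into one analysis table
#'
#' Joins the three per-penalty sources on `penalty_id`. The default inner
#' join keeps only ids present in every input; `"outer_with_flags"` keeps
#' every coded penalty and carries `NA` for its absent pose or speed values.
#' Unmatched ids are reported via an attribute.
#'
#' @param ospaf Data frame of coded records (from [read_ospaf_table()]).
#' @param pose Data frame of pose metrics with a `penalty_id` column.
#' @param ball_speed Optional data frame with `penalty_id` and `ball_speed`
#'   (m/s); omit when the OSPAF table already carries the speed column.
#' @param join `"inner"` (default) or `"outer_with_flags"`.
#' @return Data frame of per-penalty features, one row per `penalty_id`,
#'   with attribute `unmatched` listing ids dropped or flagged.
#' @export
merge_features <- function(ospaf, pose, ball_speed = NULL,
                           join = c("inner", "outer_with_flags")) {
  join <- match.arg(join)
  sources <- list(ospaf = ospaf, pose = pose)
  if (!is.null(ball_speed)) sources$ball_speed <- ball_speed
  for (nm in names(sources))
    if (!"penalty_id" %in% names(sources[[nm]]))
      pp_stop(sprintf("%s table lacks a penalty_id column", nm),
              "pp_merge_error")
  ids <- lapply(sources, function(s) unique(as.character(s$penalty_id)))
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L)
    pp_stop("no penalty_id shared across all inputs", "pp_merge_error")
  all_ids <- sort(unique(unlist(ids)))
  out <- Reduce(function(a, b) merge(a, b, by = "penalty_id",
                                     all = (join == "outer_with_flags")),
                sources)
  out <- out[order(match(out$penalty_id, all_ids)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- setdiff(all_ids, shared)
  out
}
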