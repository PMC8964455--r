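# Shared fixtures: hand-built skeletons, independent oracles, and a valid
# coded record.

# person_frame with named parts set and everything else at the missing
# sentinel; `parts` is a named list: part name -> c(x, y, conf)
make_frame <- function(frame_index, person_index = 0L, parts = list()) {
  lm <- matrix(0, 25L, 3L)
  rownames(lm) <- body25_parts()
  for (nm in names(parts)) lm[nm, ] <- parts[[nm]]
  person_frame(frame_index, person_index, lm)
}

make_track <- function(frames, role = "unassigned") {
  names(frames) <- vapply(frames, function(f) as.character(f$frame_index), "")
  structure(list(role = role, frames = frames), class = "track")
}

identity_H <- function() homography(diag(3))

# independent DLT oracle: raw null-space solve of the unnormalized stacked
# constraint matrix (no Hartley conditioning)
bruteforce_homography <- function(corr) {
  n <- nrow(corr)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- corr$img_x[i]; y <- corr$img_y[i]
    u <- corr$field_x[i]; v <- corr$field_y[i]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  Hm <- matrix(svd(A, nu = 0, nv = 9)$v[, 9], 3, 3, byrow = TRUE)
  Hm / Hm[3, 3]
}

rel_diff <- function(A, B) max(abs(A - B)) / max(abs(B))

# random well-conditioned 4-point correspondence set from a known map
random_four_point_set <- function() {
  img <- rbind(c(100, 80), c(1100, 120), c(1150, 600), c(80, 640)) +
    matrix(stats::runif(8, -30, 30), 4, 2)
  Hgen <- matrix(c(0.02, 0.003, -12,
                   -0.002, 0.025, -8,
                   runif(1, 0, 3e-4), runif(1, 0, 2e-4), 1),
                 3, 3, byrow = TRUE)
  fld <- t(apply(img, 1, function(p) {
    q <- Hgen %*% c(p, 1)
    q[1:2] / q[3]
  }))
  list(corr = data.frame(img_x = img[, 1], img_y = img[, 2],
                         field_x = fld[, 1], field_y = fld[, 2]),
       H = Hgen)
}

# hand Pearson correlation, independent of stats::cor
pearson_by_hand <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

valid_ospaf_record <- function(penalty_id = "pk001") {
  list(penalty_id = penalty_id,
       run_up_speed = "fast", run_up_fluency = "continuous",
       run_up_angle = "frontal", number_of_steps = "3-5",
       kicking_technique = "instep", foot_used = "right",
       kicker_gaze = "at_ball", gk_initial_posture = "arms_down",
       deception = "no", gk_tactical_action = "await",
       gk_performance = "3", match_moment = "second_half",
       location = "home", momentary_result_kicker = "drawing",
       momentary_result_gk = "drawing", match_importance = "group_stage",
       kick_direction = "left", kick_height = "down", outcome = "goal",
       taker_strategy = "gk_independent", gk_strategy = "kicker_dependent")
}

write_ospaf_fixture <- function(path, n = 3L) {
  rows <- lapply(seq_len(n), function(i)
    as.data.frame(valid_ospaf_record(sprintf("pk%03d", i)),
                  stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  df
}
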