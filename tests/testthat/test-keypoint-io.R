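test_that("keypoint JSON round trip preserves landmark values exactly", {
  dir <- withr::local_tempdir()
  set.seed(42)
  frames <- lapply(0:3, function(fi)
    person_frame(fi, 0L, matrix(c(runif(25, 0, 1280), runif(25, 0, 720),
                                  runif(25)), 25L, 3L)))
  frames <- c(frames, lapply(0:3, function(fi)
    person_frame(fi, 1L, matrix(c(runif(25, 0, 1280), runif(25, 0, 720),
                                  runif(25)), 25L, 3L))))
  write_openpose_frames(frames, dir, prefix = "clip")
  back <- read_openpose_frames(dir)
  expect_length(back, 8L)
  ord <- order(vapply(frames, `[[`, 0L, "frame_index"),
               vapply(frames, `[[`, 0L, "person_index"))
  for (i in seq_along(back))
    expect_identical(back[[i]]$landmarks, frames[[ord[i]]]$landmarks)
})

test_that("sentinel triplets are flagged missing and bad records rejected", {
  dir <- withr::local_tempdir()
  kp <- as.numeric(t(cbind(runif(25, 1, 100), runif(25, 1, 100), 0.9)))
  kp[4:6] <- 0  # Neck (part 1) sentinel
  jsonlite::write_json(
    list(version = 1.3, people = list(list(pose_keypoints_2d = kp))),
    file.path(dir, "a_000000000007_keypoints.json"),
    digits = NA, auto_unbox = TRUE)
  fr <- read_openpose_frames(dir)
  expect_length(fr, 1L)
  expect_equal(fr[[1]]$frame_index, 7L)
  expect_null(get_part(fr[[1]], 1L))          # Neck missing
  expect_false(is.null(get_part(fr[[1]], 0L)))

  jsonlite::write_json(
    list(version = 1.3, people = list(list(pose_keypoints_2d = kp[-1]))),
    file.path(dir, "b_000000000008_keypoints.json"),
    digits = NA, auto_unbox = TRUE)
  expect_error(
    read_openpose_frames(file.path(dir, "b_000000000008_keypoints.json")),
    "expected 75 values")
})

test_that("get_part applies the confidence floor and bounds the part index", {
  f <- make_frame(0L, parts = list(Neck = c(412.0, 220.5, 0.93),
                                   MidHip = c(400, 300, 0.01)))
  expect_equal(unname(get_part(f, 1L)), c(412.0, 220.5, 0.93))
  expect_null(get_part(f, 8L))                 # below the 0.05 floor
  expect_false(is.null(get_part(f, 8L, conf_floor = 0.005)))
  expect_error(get_part(f, 25L), "part index")
})

test_that("consolidated CSV dialect parses to the same skeletons", {
  dir <- withr::local_tempdir()
  set.seed(7)
  lm <- cbind(runif(25, 0, 1280), runif(25, 0, 720), runif(25))
  df <- data.frame(frame = 3L, person = 0L, part = 0:24,
                   x = lm[, 1], y = lm[, 2], conf = lm[, 3])
  path <- file.path(dir, "kp.csv")
  write.csv(df, path, row.names = FALSE)
  fr <- read_openpose_frames(path)
  expect_length(fr, 1L)
  expect_equal(unname(fr[[1]]$landmarks), unname(lm))
})

test_that("resolve_frame picks nearest usable frame, earlier on ties", {
  complete <- function(fi) make_frame(fi, parts = list(
    Neck = c(10, 10, 0.9), MidHip = c(10, 20, 0.9)))
  no_neck <- function(fi) make_frame(fi, parts = list(MidHip = c(10, 20, 0.9)))
  trk <- make_track(list(complete(4L), no_neck(5L), complete(6L), complete(7L)))

  expect_equal(resolve_frame(trk, 4L, c(1L, 8L), 2L), 4L)   # identity
  # target misses Neck; both neighbours at distance 1 usable -> earlier
  expect_equal(resolve_frame(trk, 5L, c(1L, 8L), 2L), 4L)
  # window 0 either returns the target or errors, never a neighbour
  expect_equal(resolve_frame(trk, 6L, c(1L, 8L), 0L), 6L)
  expect_error(resolve_frame(trk, 5L, c(1L, 8L), 0L), class = "pp_resolution_error")
  expect_error(resolve_frame(trk, 5L, c(0L), 3L), "Nose",
               class = "pp_resolution_error")
})

test_that("roles follow projected goal-line distance with index tie-break", {
  H <- identity_H()  # image coordinates already in meters
  gk <- make_frame(10L, person_index = 3L,
                   parts = list(MidHip = c(0.8, 0, 0.9)))
  kicker <- make_frame(10L, person_index = 1L,
                       parts = list(MidHip = c(-11.2, 0, 0.9)))
  roles <- assign_roles(list(gk, kicker), H, goal_line_x = 0)
  expect_equal(roles[["goalkeeper"]], 3L)
  expect_equal(roles[["kicker"]], 1L)

  expect_error(assign_roles(list(gk), H), class = "pp_role_error")

  a <- make_frame(10L, person_index = 0L, parts = list(MidHip = c(5, 1, 0.9)))
  b <- make_frame(10L, person_index = 1L, parts = list(MidHip = c(5, -3, 0.9)))
  tie <- assign_roles(list(b, a), H, goal_line_x = 0)
  expect_equal(tie[["goalkeeper"]], 0L)  # equidistant -> lower person index
})

test_that("track building keeps identity via nearest mid-hip linking", {
  p_at <- function(fi, pid, x) make_frame(fi, pid, parts = list(
    MidHip = c(x, 100, 0.9)))
  # person order swaps between frames; positions stay put
  frames <- list(p_at(0L, 0L, 100), p_at(0L, 1L, 900),
                 p_at(1L, 0L, 905), p_at(1L, 1L, 102))
  trks <- build_tracks(frames)
  expect_length(trks, 2L)
  xs <- vapply(trks, function(t)
    get_part(track_frame(t, 1L), 8L)[1], 0)
  x0 <- vapply(trks, function(t)
    get_part(track_frame(t, 0L), 8L)[1], 0)
  expect_equal(order(x0), order(xs))  # near stays near, far stays far
})

test_that("moment annotations are validated on read", {
  dir <- withr::local_tempdir()
  ok <- data.frame(penalty_id = "pk001", runup_start_frame = 10L,
                   ball_contact_frame = 40L, fps = 25)
  path <- file.path(dir, "ann.csv")
  write.csv(ok, path, row.names = FALSE)
  expect_equal(read_moment_annotations(path)$ball_contact_frame, 40L)

  bad <- ok; bad$ball_contact_frame <- 5L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_moment_annotations(path), "precede")
})
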