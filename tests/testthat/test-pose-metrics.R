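test_that("pair orientation follows the rotate-right-to-left-by-90 rule", {
  # symmetric pair across the goal axis: facing the goal exactly
  m <- pair_orientation(c(0, 1), c(0, -1), c(0.9, 0.8))
  expect_equal(m$angle, 0)
  expect_equal(m$side, "right")
  expect_equal(m$confidence, 0.85)

  # boundary 90 degrees belongs to the left bucket (half-open)
  m90 <- pair_orientation(c(-1, 0), c(1, 0))
  expect_equal(m90$angle, 90)
  expect_equal(m90$side, "left")

  m45 <- pair_orientation(c(0, 0), c(1, -1))
  expect_equal(m45$angle, 45)
  expect_equal(m45$side, "right")

  # boundary 270 degrees belongs to the right bucket
  m270 <- pair_orientation(c(1, 0), c(-1, 0))
  expect_equal(m270$angle, 270)
  expect_equal(m270$side, "right")

  expect_error(pair_orientation(c(1, 1), c(1, 1)), class = "pp_degenerate_error")
})

test_that("rotating the field rotates angles and swapping the pair flips the side", {
  set.seed(21)
  for (rep in 1:30) {
    l <- runif(2, -5, 5); r <- runif(2, -5, 5)
    if (sqrt(sum((l - r)^2)) < 1e-3) next
    base <- pair_orientation(l, r)
    theta <- runif(1, 0, 360)
    rot <- function(p) {
      a <- theta * pi / 180
      c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2])
    }
    rotated <- pair_orientation(rot(l), rot(r))
    expect_equal(rotated$angle, (base$angle + theta) %% 360, tolerance = 1e-9)

    swapped <- pair_orientation(r, l)
    expect_equal(swapped$angle, (base$angle + 180) %% 360, tolerance = 1e-9)
    expect_false(swapped$side == base$side &&
                   !(base$angle %in% c(90, 270)))  # flip except exactly at bounds
  }
})

test_that("kicker orientations use contralateral toes and tolerate missing pairs", {
  parts <- list(
    LShoulder = c(10, 1, 0.9), RShoulder = c(10, -1, 0.8),
    LHip = c(10, 0.5, 0.7), RHip = c(10, -0.5, 0.7),
    LBigToe = c(10.2, 0.05, 0.6), LSmallToe = c(10.2, 0.15, 0.5),
    RBigToe = c(10.2, -0.05, 0.6), RSmallToe = c(10.2, -0.15, 0.5))
  f <- make_frame(0L, parts = parts)
  H <- identity_H()

  ori_r <- kicker_orientations(f, H, "right")   # support foot = left
  expect_equal(ori_r$shoulders$angle, 0)
  expect_equal(ori_r$shoulders$confidence, 0.85)
  # left foot: hallux medial -> pair (small toe, big toe) faces the goal
  expect_equal(ori_r$support_foot$angle, 0)

  ori_l <- kicker_orientations(f, H, "left")    # support foot = right
  expect_equal(ori_l$support_foot$angle, 0)

  # hips pair with a missing RHip: hips flagged, shoulders still returned
  f2 <- make_frame(0L, parts = parts[setdiff(names(parts), "RHip")])
  ori2 <- kicker_orientations(f2, H, "right")
  expect_null(ori2$hips)
  expect_false(is.null(ori2$shoulders))
})

test_that("anticipation angle is the angle between directed body axes", {
  expect_equal(anticipation_angle(c(0, 0), c(0, 2), c(5, 5), c(5, 7))$alpha_gk, 0)
  a45 <- anticipation_angle(c(0, 0), c(0, 2), c(0, 0), c(2, 2),
                            confidences = c(0.9, 0.8, 0.7, 0.6))
  expect_equal(a45$alpha_gk, 45)
  expect_equal(a45$confidence, 0.75)
  expect_equal(anticipation_angle(c(0, 0), c(0, 2), c(0, 0), c(2, 0))$alpha_gk, 90)
  # a full reversal of the lean scores 180, not 0
  expect_equal(anticipation_angle(c(0, 0), c(0, 2), c(0, 0), c(0, -2))$alpha_gk, 180)
  expect_error(anticipation_angle(c(0, 0), c(0, 0), c(0, 0), c(1, 1)),
               class = "pp_degenerate_error")
})

test_that("anticipation angle is invariant to translation, scale and moment order", {
  set.seed(22)
  for (rep in 1:20) {
    n1 <- runif(2, -3, 3); h1 <- n1 + runif(2, -1, 1)
    n2 <- runif(2, -3, 3); h2 <- n2 + runif(2, -1, 1)
    if (sqrt(sum((h1 - n1)^2)) < 0.1 || sqrt(sum((h2 - n2)^2)) < 0.1) next
    base <- anticipation_angle(n1, h1, n2, h2)$alpha_gk
    shift <- runif(2, -10, 10); s <- runif(1, 0.5, 4)
    expect_equal(anticipation_angle(n1 + shift, h1 + shift,
                                    n2 + shift, h2 + shift)$alpha_gk,
                 base, tolerance = 1e-9)
    expect_equal(anticipation_angle(s * n1, s * h1, s * n2, s * h2)$alpha_gk,
                 base, tolerance = 1e-9)
    expect_equal(anticipation_angle(n2, h2, n1, h1)$alpha_gk,
                 base, tolerance = 1e-9)
    expect_gte(base, 0); expect_lte(base, 180)
  }
})

test_that("foot displacements are per-foot Euclidean field distances", {
  g1 <- make_frame(0L, parts = list(LAnkle = c(0, 0, 0.9),
                                    RAnkle = c(1, 1, 0.9)))
  g2_same <- make_frame(9L, parts = list(LAnkle = c(0, 0, 0.9),
                                         RAnkle = c(1, 1, 0.9)))
  H <- identity_H()
  expect_equal(unname(foot_displacements(g1, g2_same, H)), c(0, 0))

  g2 <- make_frame(9L, parts = list(LAnkle = c(3, 4, 0.9)))  # RAnkle missing
  d <- foot_displacements(g1, g2, H)
  expect_equal(unname(d["d_gk_left"]), 5)   # 3-4-5 triangle
  expect_true(is.na(d["d_gk_right"]))
})

test_that("displacements obey the triangle inequality across three moments", {
  set.seed(23)
  H <- identity_H()
  for (rep in 1:20) {
    pos <- matrix(runif(6, -3, 3), 3, 2)
    fr <- lapply(1:3, function(i)
      make_frame(i, parts = list(LAnkle = c(pos[i, ], 0.9),
                                 RAnkle = c(pos[i, ] + c(0.3, 0), 0.9))))
    d12 <- foot_displacements(fr[[1]], fr[[2]], H)
    d23 <- foot_displacements(fr[[2]], fr[[3]], H)
    d13 <- foot_displacements(fr[[1]], fr[[3]], H)
    expect_lte(d13["d_gk_left"], d12["d_gk_left"] + d23["d_gk_left"] + 1e-12)
    expect_lte(d13["d_gk_right"], d12["d_gk_right"] + d23["d_gk_right"] + 1e-12)
  }
})

test_that("ball speed is distance times rate over the frame gap", {
  expect_equal(ball_speed(c(0, 0), c(7, 0), frame_gap = 10, fps = 25), 17.5)
  expect_equal(ball_speed(c(2, 3), c(2, 3), frame_gap = 5, fps = 30), 0)
  expect_error(ball_speed(c(0, 0), c(1, 0), 10, 0), class = "pp_domain_error")
  expect_error(ball_speed(c(0, 0), c(1, 0), 0, 25), class = "pp_domain_error")
})
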