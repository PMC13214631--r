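test_that("the bisector halves the angle between the normal and the visual axis", {
  erp <- build_erp()
  eye <- erp$right

  # target straight ahead of the optical center: bisector is the normal
  ahead <- eye$optical_center + c(0, 80, 0)
  expect_vec_equal(bisector(eye, ahead), c(0, 1, 0), 1e-12)

  e <- bisector(eye, ref_F1())
  expect_vec_equal(e, c(0.184, 0.975, 0.121), 1e-3)
  v <- ref_F1() - eye$optical_center
  expect_equal(angle_between(e, c(0, 1, 0)), angle_between(e, v),
               tolerance = 1e-10)

  expect_error(bisector(eye, eye$optical_center), "coincides")
})

test_that("alignment angles of the printed transfer vectors sit just off 90 degrees", {
  erp <- build_erp()
  er <- bisector(erp$right, ref_F1())
  el <- bisector(erp$left, ref_F1())
  pi_r <- alignment_angle(ref_rr12(), er)
  pi_l <- alignment_angle(ref_rl12(), el)
  expect_lt(abs(pi_r - 89.53), 0.1)
  expect_lt(abs(pi_l - 89.37), 0.1)

  # reverse move, bisector at the end target: angles cross 90
  er2 <- bisector(erp$right, ref_F2())
  el2 <- bisector(erp$left, ref_F2())
  pi_r_rev <- alignment_angle(-ref_rr12(), er2)
  pi_l_rev <- alignment_angle(-ref_rl12(), el2)
  expect_gt(pi_r_rev, 90)
  expect_gt(pi_l_rev, 90)
  expect_lt(pi_r, 90)
  expect_lt(pi_l, 90)

  # exact perpendicularity when the vector lies in the displacement plane
  e <- bisector(erp$right, ref_F1())
  perp <- c(e[2], -e[1], 0)
  expect_equal(alignment_angle(perp, e), 90, tolerance = 1e-9)
  expect_error(alignment_angle(c(0, 0, 0), e), "zero rotation")
})

test_that("the overlay check certifies the transfer rotations at small residual", {
  erp <- build_erp()
  conv <- "gimbal_vertical_first"
  for (side in c("right", "left")) {
    eye <- erp[[side]]
    p1 <- rotate_eye_to_target(eye, ref_F1(), conv, erp$fixation)
    p2 <- rotate_eye_to_target(eye, ref_F2(), conv, erp$fixation)
    tr <- transfer_rvs(decompose_posture(p1, eye), decompose_posture(p2, eye))
    expect_lt(overlay_check(eye, ref_F1(), p2, tr$r12), 0.5)
    # reverse: -r12 carries F2 back onto the visual axis of F1
    expect_lt(overlay_check(eye, ref_F2(), p1, -tr$r12), 0.5)
  }
  # trivial case: no move, no residual
  eye <- erp$right
  p1 <- rotate_eye_to_target(eye, ref_F1(), conv, erp$fixation)
  expect_equal(overlay_check(eye, ref_F1(), p1, c(0, 0, 0)), 0, tolerance = 1e-9)
})

test_that("tac_report reproduces the worked tilt-angle coefficients", {
  erp <- build_erp()
  conv <- "gimbal_vertical_first"
  refs <- list(right = c(fwd = 0.48, rev = 0.46), left = c(fwd = 0.45, rev = 0.46))
  for (side in c("right", "left")) {
    eye <- erp[[side]]
    p1 <- rotate_eye_to_target(eye, ref_F1(), conv, erp$fixation)
    p2 <- rotate_eye_to_target(eye, ref_F2(), conv, erp$fixation)
    tr <- transfer_rvs(decompose_posture(p1, eye), decompose_posture(p2, eye))
    fwd <- tac_report(eye, ref_F1(), p1, tr$r12)
    rev <- tac_report(eye, ref_F2(), p2, -tr$r12)
    expect_equal(fwd$tac, refs[[side]]["fwd"], tolerance = 0.05,
                 ignore_attr = TRUE)
    expect_equal(rev$tac, refs[[side]]["rev"], tolerance = 0.05,
                 ignore_attr = TRUE)
    expect_true(fwd$tac > 0.4 && fwd$tac < 0.6)
  }
  # the right-eye eccentricity at F1 matches the worked 25.38 degrees
  eye <- erp$right
  p1 <- rotate_eye_to_target(eye, ref_F1(), conv, erp$fixation)
  tr <- transfer_rvs(decompose_posture(p1, eye),
                     decompose_posture(
                       rotate_eye_to_target(eye, ref_F2(), conv, erp$fixation), eye))
  rep <- tac_report(eye, ref_F1(), p1, tr$r12)
  expect_equal(rep$xi_deg, 25.38, tolerance = 0.01)
})

test_that("a transfer vector in the resting plane gives zero tilt", {
  erp <- build_erp()
  rep <- tac_report(erp$right, ref_F1(), NULL, c(0.1, 0, -0.2))
  expect_equal(rep$nu_deg, 0, tolerance = 1e-9)
  expect_equal(rep$tac, 0, tolerance = 1e-9)
})

test_that("the symmetric-eye limit obeys the half-angle rule exactly", {
  # cyclopean symmetric eye: rotation center at the origin, resting gaze
  # along the optical axis, so the optical center coincides with it
  cfg <- binocular_config(a_cm = 1e-9, angles = misalignment_angles(0, 0, 0, 0),
                          fa_cm = c(0, 100, 0))
  erp <- build_erp(cfg)
  eye <- erp$right
  set.seed(17)
  for (i in 1:25) {
    t1 <- stats::runif(1, 0, 2 * pi); t2 <- stats::runif(1, 0, 2 * pi)
    r1 <- rv_from_axis_angle(c(cos(t1), 0, sin(t1)), stats::runif(1, 5, 25))
    r2 <- rv_from_axis_angle(c(cos(t2), 0, sin(t2)), stats::runif(1, 5, 25))
    F1 <- eye$rotation_center + rv_apply(r1, 50 * c(0, 1, 0))
    r12 <- rv_compose(r2, rv_inverse(r1))
    expect_lt(abs(alignment_angle(r12, bisector(eye, F1)) - 90), 0.01)
  }
})

test_that("tac stays in the half-angle band for oblique tertiary moves", {
  erp <- build_erp()
  conv <- "gimbal_vertical_first"
  pairs <- list(list(c(20, 45, 10), c(-10, 55, 18)),
                list(c(12, 35, -14), c(25, 60, 8)),
                list(c(-22, 50, -5), c(-5, 40, 16)))
  for (pr in pairs) {
    eye <- erp$right
    p1 <- rotate_eye_to_target(eye, pr[[1]], conv, erp$fixation)
    p2 <- rotate_eye_to_target(eye, pr[[2]], conv, erp$fixation)
    tr <- transfer_rvs(decompose_posture(p1, eye), decompose_posture(p2, eye))
    rep <- tac_report(eye, pr[[1]], p1, tr$r12)
    expect_gt(rep$tac, 0.4)
    expect_lt(rep$tac, 0.6)
  }
})
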