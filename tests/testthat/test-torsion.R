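make_dec <- function(r, tau_deg, side = "right") {
  # minimal decomposition object for algebraic tests on printed values
  structure(list(side = side, r = r, q = tan(pi / 180 * tau_deg / 2) * c(0, 1, 0),
                 phi_deg = listingr::rv_angle(r), tau_deg = tau_deg),
            class = "torsion_decomposition")
}

test_that("identity and pure-torsion postures decompose trivially", {
  erp <- build_erp()
  p0 <- posture_from_rotation(erp$right, c(0, 0, 0))
  d0 <- decompose_posture(p0, erp$right)
  expect_equal(d0$phi_deg, 0)
  expect_equal(d0$tau_deg, 0)
  expect_equal(d0$r, c(0, 0, 0))
  expect_equal(d0$q, c(0, 0, 0))

  p5 <- posture_from_rotation(erp$right, rv_from_axis_angle(c(0, 1, 0), 5))
  d5 <- decompose_posture(p5, erp$right)
  expect_equal(d5$phi_deg, 0, tolerance = 1e-10)
  expect_equal(d5$tau_deg, 5, tolerance = 1e-10)
})

test_that("the decomposition is exact and its axis lies in the resting plane", {
  erp <- build_erp()
  set.seed(31)
  for (i in 1:200) {
    r_full <- random_rv(100)
    p <- posture_from_rotation(erp$right, r_full)
    d <- decompose_posture(p, erp$right)
    expect_vec_equal(rv_compose(d$r, d$q), r_full, 1e-10)
    expect_equal(d$r[2], 0)
    # the primed frame's middle vector returns to j
    expect_vec_equal(d$primed_frame$j, c(0, 1, 0), 1e-10)
    # |tau| equals both frame angles
    expect_equal(abs(d$tau_deg),
                 angle_between(c(0, 0, 1), d$primed_frame$c), tolerance = 1e-9)
    expect_equal(abs(d$tau_deg),
                 angle_between(c(1, 0, 0), d$primed_frame$a), tolerance = 1e-9)
  }
  # antiparallel frame normal is rejected
  flip <- posture_from_rotation(erp$right, c(0, 0, 0))
  flip$frame$b_vec <- c(0, -1, 0)
  expect_error(decompose_posture(flip, erp$right), "antiparallel")
})

test_that("torsional disparity subtracts the eye torsions", {
  expect_equal(torsional_disparity(3.15, 4.14), -0.99)
  expect_equal(torsional_disparity(1.26, 1.74), -0.48, tolerance = 1e-12)
  expect_equal(torsional_disparity(2, 2), 0)
  expect_equal(disparity_transfer(-0.99, -0.52), 0.47)
  expect_equal(disparity_transfer(0.3, 0.3), 0)
  expect_equal(disparity_transfer(-0.52, -0.99), -disparity_transfer(-0.99, -0.52))
})

test_that("transfer composition matches the printed worked values", {
  d1 <- make_dec(ref_rr1(), 3.147)
  d2 <- make_dec(ref_rr2(), 1.26)
  tr <- transfer_rvs(d1, d2)
  expect_vec_equal(tr$r12, ref_rr12(), 5e-4)
  expect_equal(sqrt(sum(tr$r12^2)), 0.12004, tolerance = 2e-3)
  expect_equal(tr$phi12_deg, 13.690, tolerance = 0.02)
  expect_equal(tr$tau12_deg, 1.26 - 3.147)
  # left-eye angle from the printed transfer components
  expect_equal(2 * atan(sqrt(sum(ref_rl12()^2))) * 180 / pi,
               16.534, tolerance = 1e-3)

  # swap antisymmetry
  tr_back <- transfer_rvs(d2, d1)
  expect_vec_equal(tr_back$r12, -tr$r12, 1e-12)
  expect_vec_equal(tr_back$q12, -tr$q12, 1e-12)
  expect_equal(tr_back$tau12_deg, -tr$tau12_deg)

  # identity
  tr0 <- transfer_rvs(d1, d1)
  expect_vec_equal(tr0$r12, c(0, 0, 0), 1e-12)
  expect_vec_equal(tr0$q12, c(0, 0, 0), 1e-12)
})

test_that("transfer parts reconstruct the end state: r12 o r1 = r2 and q12 o q1 = q2", {
  erp <- build_erp()
  set.seed(13)
  for (i in 1:50) {
    p1 <- posture_from_rotation(erp$right, random_rv(70))
    p2 <- posture_from_rotation(erp$right, random_rv(70))
    d1 <- decompose_posture(p1, erp$right)
    d2 <- decompose_posture(p2, erp$right)
    tr <- transfer_rvs(d1, d2)
    expect_vec_equal(rv_compose(tr$r12, d1$r), d2$r, 1e-10)
    expect_vec_equal(rv_compose(tr$q12, d1$q), d2$q, 1e-10)
  }
})

test_that("torsion structure across targets: none on the resting ray, mirror on the midline, degrees when oblique", {
  erp <- build_erp()
  conv <- "gimbal_vertical_first"

  # target on the eye's own resting fixation axis: the fixation-based
  # conventions are exactly the identity; the visual geodesic (anchored at
  # the offset optical center) acquires only a sub-millidegree rotation
  C <- erp$right$rotation_center
  along <- C + 0.5 * (erp$fixation - C)
  for (tag in gaze_convention_tags()) {
    p <- rotate_eye_to_target(erp$right, along, tag, erp$fixation)
    tau <- abs(decompose_posture(p, erp$right)$tau_deg)
    expect_lt(tau, if (tag == "visual_geodesic") 1e-3 else 1e-10)
  }

  # midline targets: right and left torsions mirror
  for (tgt in list(c(0, 60, 12), c(0, 40, -9))) {
    pair <- binocular_fixate(erp, tgt, conv)
    tr <- decompose_posture(pair$right, erp$right)$tau_deg
    tl <- decompose_posture(pair$left, erp$left)$tau_deg
    expect_equal(abs(tr), abs(tl), tolerance = 1e-9)
  }

  # vertical shift from the resting fixation: torsion below 0.1 degrees;
  # oblique shift: torsion of order degrees
  p_vert <- rotate_eye_to_target(erp$right, c(0, 99.56, 30), conv, erp$fixation)
  p_obl <- rotate_eye_to_target(erp$right, c(25, 60, 20), conv, erp$fixation)
  tau_vert <- abs(decompose_posture(p_vert, erp$right)$tau_deg)
  tau_obl <- abs(decompose_posture(p_obl, erp$right)$tau_deg)
  expect_lt(tau_vert, 0.1)
  expect_gt(tau_obl, 1)
})
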