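test_that("axis-aligned landmarks give the identity femoral frame", {
  lm <- landmark_set(
    femoral_head_center = c(0, 0, 400), knee_center_femur = c(0, 0, 0),
    medial_epicondyle = c(-45, 0, 0), lateral_epicondyle = c(45, 0, 0))
  fr <- femoral_frame(lm)
  expect_equal(fr$ml, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$ap, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$si, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$origin, c(0, 0, 0))
})

test_that("frame constructors are equivariant under rigid rotation", {
  base <- landmark_set(
    femoral_head_center = c(0, 0, 400), knee_center_femur = c(0, 0, 0),
    medial_epicondyle = c(-45, 0, 0), lateral_epicondyle = c(45, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    rot <- random_rotation3()
    shift <- runif(3, -100, 100)
    fr <- femoral_frame(rigid_apply(base, rot, shift))
    expect_equal(fr$ml, as.numeric(rot %*% c(1, 0, 0)), tolerance = 1e-9)
    expect_equal(fr$ap, as.numeric(rot %*% c(0, 1, 0)), tolerance = 1e-9)
    expect_equal(fr$si, as.numeric(rot %*% c(0, 0, 1)), tolerance = 1e-9)
  }
})

test_that("frames are right-handed orthonormal triads on random valid landmarks", {
  set.seed(12)
  for (i in 1:1000) {
    rot <- random_rotation3()
    shift <- runif(3, -200, 200)
    lm <- rigid_apply(template_landmarks(), rot, shift)
    for (fr in list(femoral_frame(lm), tibial_frame(lm))) {
      M <- cbind(fr$ml, fr$ap, fr$si)
      expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
      expect_gt(det(M), 0)
    }
  }
})

test_that("degenerate landmark configurations raise geometry errors", {
  expect_error(femoral_frame(landmark_set(
    femoral_head_center = c(0, 0, 400), knee_center_femur = c(0, 0, 0),
    medial_epicondyle = c(0, 0, 100), lateral_epicondyle = c(0, 0, 200))),
    "parallel")
  expect_error(femoral_frame(landmark_set(
    femoral_head_center = c(0, 0, 0), knee_center_femur = c(0, 0, 0),
    medial_epicondyle = c(-45, 0, 0), lateral_epicondyle = c(45, 0, 0))),
    "zero length")
  expect_error(tibial_frame(landmark_set(
    knee_center_tibia = c(0, 0, 0), ankle_center = c(0, 0, -380),
    tibia_posterior_condyle_medial = c(1, 2, 3),
    tibia_posterior_condyle_lateral = c(1, 2, 3))), "coincide")
  expect_error(component_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "parallel")
  expect_error(femoral_frame(landmark_set(knee_center_femur = c(0, 0, 0))),
               "missing landmark")
})

test_that("component frame equals a known rotation applied to the identity case", {
  expect_equal(component_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))$si,
               c(0, 0, 1), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:50) {
    rot <- random_rotation3()
    fr <- component_frame(c(0, 0, 0), rot %*% c(1, 0, 0), rot %*% c(0, 1, 0))
    expect_equal(cbind(fr$ml, fr$ap, fr$si), rot, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("projected_angle matches the frame-coordinate closed-form oracle", {
  fr0 <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(projected_angle(c(0, 0, 1), fr0, "coronal", "si"), 0)
  v30 <- cos(pi / 6) * fr0$ml + sin(pi / 6) * fr0$si
  expect_equal(projected_angle(v30, fr0, "coronal", "ml"), 30, tolerance = 1e-9)

  set.seed(14)
  cases <- expand.grid(plane = c("coronal", "sagittal", "axial"),
                       stringsAsFactors = FALSE)
  refs <- list(coronal = c("ml", "si"), sagittal = c("ap", "si"),
               axial = c("ml", "ap"))
  for (i in 1:2000) {
    fr <- random_frame()
    v <- rnorm(3)
    plane <- cases$plane[(i %% 3) + 1]
    reference <- refs[[plane]][(i %% 2) + 1]
    expect_equal(projected_angle(v, fr, plane, reference),
                 wrap_angle(oracle_projected_angle(v, fr, plane, reference)),
                 tolerance = 1e-9)
  }
})

test_that("projected_angle rejects vectors orthogonal to the plane", {
  fr0 <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(projected_angle(c(0, 1, 0), fr0, "coronal", "si"), "orthogonal")
})

test_that("single-axis component poses give one nonzero clinical angle", {
  lm <- template_landmarks()
  anat <- femoral_frame(lm)

  # pure coronal tilt: 7 degrees varus
  comp <- local({
    lmv <- generate_landmark_case(angle_report("femoral", 7, 0, 0),
                                  angle_report("tibial", 0, 0, 0), 0)
    component_frame(lmv$femoral_component_origin, lmv$femoral_component_ml,
                    lmv$femoral_component_ap)
  })
  rep <- femoral_component_angles(anat, comp)
  expect_equal(rep$varus_valgus, 7, tolerance = 1e-9)
  expect_equal(rep$sagittal_angle, 0, tolerance = 1e-9)
  expect_equal(rep$axial_rotation, 0, tolerance = 1e-9)

  # identical frames: all angles zero
  rep0 <- femoral_component_angles(anat, anat)
  expect_equal(c(rep0$varus_valgus, rep0$sagittal_angle, rep0$axial_rotation),
               c(0, 0, 0))

  # pure 5-degree sagittal pose on the tibia
  lmt <- generate_landmark_case(angle_report("femoral", 0, 0, 0),
                                angle_report("tibial", 0, -5, 0), 0)
  mt <- measure_angles(lmt)
  expect_equal(mt$tibial$sagittal_angle, -5, tolerance = 1e-9)
  expect_equal(mt$tibial$varus_valgus, 0, tolerance = 1e-9)
  expect_equal(mt$tibial$axial_rotation, 0, tolerance = 1e-9)
})

test_that("rotational mismatch is the wrapped signed difference", {
  mk <- function(rot, comp = "femoral")
    angle_report(comp, 0, 0, rot)
  expect_equal(rotational_mismatch(mk(3), mk(3, "tibial")), 0)
  expect_equal(rotational_mismatch(mk(5), mk(-5, "tibial")), 10)
  expect_equal(rotational_mismatch(mk(179), mk(-179, "tibial")), -2)
  expect_equal(rotational_mismatch(mk(-179), mk(179, "tibial")), 2)
})

test_that("tibiofemoral angle recovers constructed coronal angulation", {
  lm0 <- template_landmarks()
  expect_equal(tibiofemoral_angle(lm0), 0, tolerance = 1e-9)
  lm5 <- generate_landmark_case(angle_report("femoral", 0, 0, 0),
                                angle_report("tibial", 0, 0, 0), 5)
  expect_equal(tibiofemoral_angle(lm5), 5, tolerance = 1e-9)
  set.seed(15)
  for (i in 1:20) {
    lmr <- rigid_apply(lm5, random_rotation3(), runif(3, -100, 100))
    expect_equal(tibiofemoral_angle(lmr), 5, tolerance = 1e-9)
  }
})

test_that("sign conventions are centralized and flippable", {
  lm <- generate_landmark_case(angle_report("femoral", 4, 0, 0),
                               angle_report("tibial", 0, 0, 0), 0)
  default <- measure_angles(lm)
  flipped <- measure_angles(lm, conventions = angle_conventions(varus = -1))
  expect_equal(flipped$femoral$varus_valgus, -default$femoral$varus_valgus)
  expect_error(angle_conventions(varus = 2), "\\+1 or -1")
})

test_that("all angles lie in (-180, 180]", {
  expect_equal(wrap_angle(c(180, -180, 360, 540, -361)),
               c(180, 180, 0, 180, -1))
  expect_true(all(wrap_angle(runif(100, -1000, 1000)) > -180))
  expect_true(all(wrap_angle(runif(100, -1000, 1000)) <= 180))
})
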