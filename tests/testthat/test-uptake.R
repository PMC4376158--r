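test_that("box building yields 24 scored boxes plus background, disjoint per bone", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm)
  labels <- vapply(enumerate_scored_regions(), `[[`, "", "label")
  expect_setequal(names(boxes), c(labels, "femoral_shaft_background"))

  # membership disjointness: no voxel center may fall in two boxes of one bone
  vol <- intensity_volume(array(1, c(40, 40, 40)), spacing = c(3, 3, 3),
                          origin = c(-60, -60, -60))
  centers <- ukaspect:::.voxel_centers(vol)
  for (bone in c("F", "T", "P")) {
    bone_labels <- labels[substr(labels, 1, 1) == bone]
    counts <- rowSums(vapply(bone_labels, function(lab)
      ukaspect:::.in_box(centers, boxes[[lab]]), logical(nrow(centers))))
    expect_lte(max(counts), 1)
  }
})

test_that("zone-3 width and config dimensions pass through to the boxes", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm, box_config(zone3_ml_width_mm = 22))
  for (lab in c("T3sp", "T3sa", "T3ip", "T3ia"))
    expect_equal(boxes[[lab]]$half_extents[1], 11)
  expect_error(box_config(slab_mm = -1), "positive")
  expect_error(box_config(background_fraction = 1.2), "\\(0, 1\\)")
})

test_that("boxes transform rigidly with the landmarks", {
  lm <- template_landmarks()
  cfg <- box_config()
  boxes <- build_region_boxes(lm, cfg)
  set.seed(21)
  rot <- random_rotation3(); shift <- runif(3, -50, 50)
  boxes2 <- build_region_boxes(rigid_apply(lm, rot, shift), cfg)
  for (lab in names(boxes)) {
    expect_equal(boxes2[[lab]]$center,
                 as.numeric(rot %*% boxes[[lab]]$center + shift),
                 tolerance = 1e-9, info = lab)
    expect_equal(boxes2[[lab]]$half_extents, boxes[[lab]]$half_extents,
                 info = lab)
  }
})

test_that("quantify_region matches the brute-force voxel loop oracle", {
  # constant field: both statistics return the constant
  volc <- intensity_volume(array(7, c(8, 8, 8)), spacing = c(2, 2, 2))
  boxc <- ukaspect:::.region_box(
    "test", anatomical_frame(c(4, 4, 4), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    c(0, 0, 0), c(5, 5, 5))
  expect_equal(quantify_region(volc, boxc, "max"), 7)
  expect_equal(quantify_region(volc, boxc, "mean"), 7)

  # single hot voxel
  volh <- intensity_volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
  volh$voxels[4, 4, 4] <- 100
  expect_equal(quantify_region(volh, boxc, "max"), 100)

  set.seed(22)
  n_checked <- 0
  for (i in 1:50) {
    d <- sample(6:10, 3, replace = TRUE)
    vol <- intensity_volume(array(runif(prod(d), 0, 100), d),
                            spacing = runif(3, 1, 3),
                            origin = runif(3, -10, 10),
                            direction = random_rotation3())
    fr <- random_frame(origin = vol$origin + runif(3, 0, 10))
    box <- ukaspect:::.region_box("rand", fr, runif(3, -3, 3), runif(3, 4, 12))
    expected_max <- oracle_quantify(vol, box, "max")
    if (is.na(expected_max)) next
    n_checked <- n_checked + 1
    expect_identical(quantify_region(vol, box, "max"), expected_max)
    expect_equal(quantify_region(vol, box, "mean"),
                 oracle_quantify(vol, box, "mean"), tolerance = 1e-12)
  }
  expect_gte(n_checked, 25)
})

test_that("empty boxes raise a quantification error naming the region", {
  vol <- intensity_volume(array(1, c(5, 5, 5)))
  far <- ukaspect:::.region_box(
    "F2ip", anatomical_frame(c(500, 500, 500), c(1, 0, 0), c(0, 1, 0),
                             c(0, 0, 1)),
    c(0, 0, 0), c(1, 1, 1))
  expect_error(quantify_region(vol, far, "max"), "F2ip")
})

test_that("background reference sits at the configured mid-shaft fraction", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm, box_config(background_fraction = 0.5))
  bg_box <- boxes[["femoral_shaft_background"]]
  # head at z = 400, knee at z = 0 in the template: center z = 200
  expect_equal(bg_box$center, c(0, 0, 200), tolerance = 1e-9)

  vol <- generate_uptake_phantom(phantom_truth(background_level = 50),
                                 boxes, noise_sd = 0)
  expect_equal(background_reference(vol, lm), 50)

  zero <- intensity_volume(array(0, dim(vol$voxels)), vol$spacing, vol$origin)
  expect_error(background_reference(zero, lm), "not positive")
})

test_that("uptake report normalizes by background and keeps enumeration order", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm)
  truth <- phantom_truth(background_level = 50)
  vol <- generate_uptake_phantom(truth, boxes, noise_sd = 0)
  rep <- uptake_report(vol, boxes, background_reference(vol, lm))

  expect_identical(rep$region,
                   vapply(enumerate_scored_regions(), `[[`, "", "label"))
  expect_equal(rep$ratio, rep$absolute / attr(rep, "background"))
  expect_equal(rep$ratio,
               unname(truth$region_levels / truth$background_level))

  # uniform volume at background level: every ratio 1, both statistics
  uni <- intensity_volume(array(50, dim(vol$voxels)), vol$spacing, vol$origin)
  repu <- uptake_report(uni, boxes, background_reference(uni, lm))
  expect_true(all(repu$ratio == 1))
})

test_that("ratios are invariant to global volume rescaling", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm)
  truth <- phantom_truth(seed = 23)
  vol <- generate_uptake_phantom(truth, boxes, noise_sd = 4)
  rep1 <- uptake_report(vol, boxes, background_reference(vol, lm))
  k <- 3.7
  vol2 <- vol; vol2$voxels <- vol2$voxels * k
  rep2 <- uptake_report(vol2, boxes, background_reference(vol2, lm))
  expect_equal(rep2$absolute, k * rep1$absolute, tolerance = 1e-12)
  expect_equal(rep2$ratio, rep1$ratio, tolerance = 1e-12)
})

test_that("raising an in-box voxel never decreases the region max", {
  lm <- template_landmarks()
  boxes <- build_region_boxes(lm)
  vol <- generate_uptake_phantom(phantom_truth(seed = 24), boxes, noise_sd = 2)
  centers <- ukaspect:::.voxel_centers(vol)
  inside <- which(ukaspect:::.in_box(centers, boxes[["T1sa"]]))
  base <- quantify_region(vol, boxes[["T1sa"]], "max")
  set.seed(24)
  for (idx in sample(inside, 10)) {
    bumped <- vol
    bumped$voxels[idx] <- bumped$voxels[idx] + runif(1, 0, 50)
    expect_gte(quantify_region(bumped, boxes[["T1sa"]], "max"), base)
  }
})

test_that("records are unchanged when landmarks and volume translate together", {
  lm <- template_landmarks()
  cfg <- box_config()
  truth <- phantom_truth(seed = 25)
  boxes <- build_region_boxes(lm, cfg)
  vol <- generate_uptake_phantom(truth, boxes, noise_sd = 3)
  rep1 <- uptake_report(vol, boxes, background_reference(vol, lm, cfg))

  shift <- c(13, -7, 21)
  lm2 <- rigid_apply(lm, diag(3), shift)
  vol2 <- vol; vol2$origin <- vol2$origin + shift
  boxes2 <- build_region_boxes(lm2, cfg)
  rep2 <- uptake_report(vol2, boxes2, background_reference(vol2, lm2, cfg))
  expect_equal(rep2$absolute, rep1$absolute, tolerance = 1e-12)
  expect_equal(rep2$ratio, rep1$ratio, tolerance = 1e-12)
})
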