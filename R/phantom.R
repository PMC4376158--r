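# Digital phantom generators: synthetic uptake volumes, landmark cases that
# encode known component angles, and simulated rater tables with known
# variance components. All generators are pure functions of their
# parameters and seed (the session RNG state is saved and restored).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Phantom ground truth
#'
#' Bundles the known truth a phantom encodes: per-region uptake levels, the
#' background and base (off-region) levels, the component angle reports,
#' the tibiofemoral angle and the rater variance components. Default region
#' levels span background ratios from 0.6 to 5.2 so every region is
#' distinguishable.
#'
#' @param region_levels Named numeric vector over the 24 scored region
#'   labels (intensity units, >= 0); default spans 0.6-5.2 x background.
#' @param background_level Positive intensity at the femoral mid-shaft.
#' @param base_level Intensity outside all boxes.
#' @param fem_angles,tib_angles `uka_angles` reports (see
#'   [angle_report()]).
#' @param tibiofemoral True tibiofemoral angle (degrees).
#' @param rating_components List with `item_var`, `rater_var`,
#'   `residual_var` (>= 0).
#' @param seed Integer seed fixing all stochastic draws.
#' @return A list of class `uka_truth`.
#' @export
phantom_truth <- function(region_levels = NULL, background_level = 50,
                          base_level = 10,
                          fem_angles = angle_report("femoral", 2, 5, -3),
                          tib_angles = angle_report("tibial", 3, -6, -4),
                          tibiofemoral = -2,
                          rating_components = list(item_var = 9, rater_var = 0,
                                                   residual_var = 1),
                          seed = 1L) {
  labels <- .SCHEME_ORDER
  if (is.null(region_levels))
    region_levels <- stats::setNames(
      background_level * seq(0.6, 5.2, length.out = length(labels)), labels)
  if (is.null(names(region_levels)) ||
      !setequal(names(region_levels), labels))
    stop("region_levels must be named with the 24 scored region labels",
         call. = FALSE)
  if (any(region_levels < 0) || background_level <= 0 || base_level < 0)
    stop("uptake levels must be >= 0 and background > 0", call. = FALSE)
  vars <- unlist(rating_components[c("item_var", "rater_var", "residual_var")])
  if (length(vars) != 3L || any(!is.finite(vars)) || any(vars < 0))
    stop("rating_components must give item_var, rater_var, residual_var >= 0",
         call. = FALSE)
  structure(list(region_levels = region_levels[labels],
                 background_level = background_level, base_level = base_level,
                 fem_angles = fem_angles, tib_angles = tib_angles,
                 tibiofemoral = tibiofemoral,
                 rating_components = as.list(vars), seed = seed),
            class = "uka_truth")
}

#' Construct an angle report directly
#'
#' @param component `"femoral"` or `"tibial"`.
#' @param varus_valgus,sagittal_angle,axial_rotation Signed degrees under
#'   the package's sign conventions (see [angle_conventions()]).
#' @return A `uka_angles` object.
#' @export
angle_report <- function(component, varus_valgus, sagittal_angle,
                         axial_rotation) {
  component <- match.arg(component, c("femoral", "tibial"))
  .angle_report(component, varus_valgus, sagittal_angle, axial_rotation)
}

#' Template anatomy dimensions
#'
#' Package-default adult-knee dimensions (mm) used to lay out the phantom
#' landmark case.
#'
#' @param femur_length,tibia_length Mechanical axis lengths.
#' @param epicondylar_width Distance between the epicondyles.
#' @param condyle_halfwidth,condyle_posterior_offset Tibial posterior
#'   condyle placement relative to the tibial knee center.
#' @param joint_gap Distance from the femoral to the tibial knee center.
#' @return Named list of dimensions.
#' @export
template_anatomy <- function(femur_length = 400, epicondylar_width = 90,
                             tibia_length = 380, condyle_halfwidth = 40,
                             condyle_posterior_offset = 30, joint_gap = 12) {
  dims <- list(femur_length = femur_length,
               epicondylar_width = epicondylar_width,
               tibia_length = tibia_length,
               condyle_halfwidth = condyle_halfwidth,
               condyle_posterior_offset = condyle_posterior_offset,
               joint_gap = joint_gap)
  if (any(unlist(dims) <= 0)) stop("anatomy dimensions must be positive",
                                   call. = FALSE)
  dims
}

# Component triad (local anatomical-frame coordinates) whose projected
# angles equal the requested raw angles exactly. The superior axis is fixed
# by the coronal/sagittal projections, the ml axis by the axial projection
# plus orthogonality, and the ap axis closes the right-handed triad.
.component_axes_from_raw <- function(raw_cor, raw_sag, raw_ax) {
  a <- raw_cor * pi / 180; b <- raw_sag * pi / 180; g <- raw_ax * pi / 180
  # raw coronal angles run ml-toward-si (positive raw tilts the superior
  # axis medially), raw sagittal angles ap-toward-si (positive raw tilts it
  # posteriorly): the ml/ap components of the superior axis are -tan(a),
  # -tan(b)
  si <- c(-tan(a), -tan(b), 1)
  si <- si / sqrt(sum(si^2))
  w <- cos(g) * tan(a) + sin(g) * tan(b)
  ml <- c(cos(g), sin(g), w)
  ml <- ml / sqrt(sum(ml^2))
  ap <- .cross(si, ml)
  cbind(ml = ml, ap = ap, si = si)
}

#' Generate a landmark case encoding known component angles
#'
#' Builds a template knee in scanner space whose anatomical frames, when
#' measured with the geometry functions, return exactly the requested
#' femoral and tibial component angles and tibiofemoral angle. Component
#' fiducial triads are placed by inverting the projected-angle definition,
#' so the noiseless round-trip is exact to machine precision. A seed
#' applies a random rigid transform to the whole case (angles are invariant
#' under it).
#'
#' @param true_fem,true_tib `uka_angles` reports (each angle within
#'   (-60, 60) degrees).
#' @param true_tfa True tibiofemoral angle (degrees, within (-60, 60)).
#' @param template Output of [template_anatomy()].
#' @param seed `NULL` for the canonical (axis-aligned) pose, or an integer
#'   seed drawing a random rigid transform of all landmarks.
#' @param conventions Output of [angle_conventions()].
#' @return A `uka_landmarks` set with anatomical and component fiducials.
#' @export
generate_landmark_case <- function(true_fem, true_tib, true_tfa = 0,
                                   template = template_anatomy(),
                                   seed = NULL,
                                   conventions = angle_conventions()) {
  stopifnot(inherits(true_fem, "uka_angles"), inherits(true_tib, "uka_angles"))
  angles <- c(true_fem$varus_valgus, true_fem$sagittal_angle,
              true_fem$axial_rotation, true_tib$varus_valgus,
              true_tib$sagittal_angle, true_tib$axial_rotation, true_tfa)
  if (any(abs(angles) >= 60))
    stop("phantom angles must lie within (-60, 60) degrees", call. = FALSE)

  ew <- template$epicondylar_width / 2
  lm <- list(
    knee_center_femur = c(0, 0, 0),
    femoral_head_center = c(0, 0, template$femur_length),
    medial_epicondyle = c(-ew, 0, 0),
    lateral_epicondyle = c(ew, 0, 0),
    patella_center = c(0, 55, 5),
    knee_center_tibia = c(0, 0, -template$joint_gap)
  )

  # tibial mechanical axis tilted to encode the tibiofemoral angle
  raw_tfa <- (true_tfa / conventions$tfa) * pi / 180
  t_dir <- c(-tan(raw_tfa), 0, 1)
  t_dir <- t_dir / sqrt(sum(t_dir^2))
  lm$ankle_center <- lm$knee_center_tibia - template$tibia_length * t_dir

  ml_t <- .ortho(c(1, 0, 0), t_dir)
  ap_t <- .cross(t_dir, ml_t)
  ch <- template$condyle_halfwidth; po <- template$condyle_posterior_offset
  lm$tibia_posterior_condyle_medial <- lm$knee_center_tibia - ch * ml_t - po * ap_t
  lm$tibia_posterior_condyle_lateral <- lm$knee_center_tibia + ch * ml_t - po * ap_t

  fem_frame <- anatomical_frame(lm$knee_center_femur, c(1, 0, 0), c(0, 1, 0),
                                c(0, 0, 1))
  tib_frame <- anatomical_frame(lm$knee_center_tibia, ml_t, ap_t, t_dir)

  place_component <- function(anat, report, local_origin, prefix) {
    axes_local <- .component_axes_from_raw(
      report$varus_valgus / conventions$varus,
      report$sagittal_angle / conventions$sagittal,
      report$axial_rotation / conventions$axial)
    axes_world <- .frame_matrix(anat) %*% axes_local
    origin <- anat$origin + .frame_matrix(anat) %*% local_origin
    out <- list(origin, origin + 30 * axes_world[, "ml"],
                origin + 30 * axes_world[, "ap"])
    names(out) <- paste0(prefix, c("_origin", "_ml", "_ap"))
    out
  }
  lm <- c(lm,
          place_component(fem_frame, true_fem, c(-25, 0, 5), "femoral_component"),
          place_component(tib_frame, true_tib, c(-25, 0, -5), "tibial_component"))

  if (!is.null(seed)) {
    lm <- .with_seed(seed, {
      rot <- .random_rotation()
      shift <- stats::runif(3, -50, 50)
      lapply(lm, function(p) as.numeric(rot %*% p + shift))
    })
  }
  landmark_set(lm)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic uptake volume from known region levels
#'
#' Voxels whose centers fall inside a scored region box take that region's
#' true level; background-box voxels the background level; all other
#' voxels the base level. Optional additive Gaussian noise (sd in intensity
#' units) is clipped at zero. Boxes are required to claim disjoint voxel
#' sets.
#'
#' @param truth A [phantom_truth()].
#' @param boxes Output of [build_region_boxes()] for the same landmarks.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param shape Integer length-3 grid size, or `NULL` to fit the grid to
#'   the boxes (with a one-voxel margin).
#' @param spacing,origin,direction Volume geometry (see
#'   [intensity_volume()]); `origin = NULL` is fitted together with
#'   `shape`.
#' @return A `uka_volume`, deterministic given `truth$seed`.
#' @export
generate_uptake_phantom <- function(truth, boxes, noise_sd = 0,
                                    shape = NULL, spacing = c(4, 4, 4),
                                    origin = NULL, direction = diag(3)) {
  stopifnot(inherits(truth, "uka_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(shape) || is.null(origin)) {
    corners <- do.call(rbind, lapply(boxes, function(b) {
      signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      t(b$center + b$axes %*% (t(signs) * b$half_extents))
    }))
    qc <- corners %*% direction   # grid-axis coordinates
    lo <- apply(qc, 2, min) - spacing
    hi <- apply(qc, 2, max) + spacing
    origin <- as.numeric(direction %*% lo)
    shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  }
  vol <- intensity_volume(array(truth$base_level, shape), spacing, origin,
                          direction)
  centers <- .voxel_centers(vol)
  vals <- rep(truth$base_level, nrow(centers))
  claimed <- rep(FALSE, nrow(centers))
  assign_level <- function(box, level) {
    inside <- .in_box(centers, box)
    if (any(inside & claimed))
      stop("overlapping truth assignments: a voxel falls in two boxes",
           call. = FALSE)
    claimed[inside] <<- TRUE
    vals[inside] <<- level
  }
  for (lab in names(truth$region_levels))
    assign_level(boxes[[lab]], truth$region_levels[[lab]])
  assign_level(boxes[["femoral_shaft_background"]], truth$background_level)
  if (noise_sd > 0)
    vals <- .with_seed(truth$seed,
                       pmax(0, vals + stats::rnorm(length(vals), 0, noise_sd)))
  vol$voxels <- array(vals, shape)
  vol
}

#' Simulate an observer ratings table with known variance components
#'
#' Draws `value(i, r, s) = mu + b_i + c_r + e_irs` with independent
#' zero-mean Gaussian item, rater and residual effects of the stated
#' variances. The analytic one-way ICC
#' `item_var / (item_var + rater_var + residual_var)` is attached as
#' attribute `analytic_icc`.
#'
#' @param n_items Number of items (>= 2).
#' @param n_raters Number of raters.
#' @param sessions Sessions per rater.
#' @param components List with `item_var`, `rater_var`, `residual_var`
#'   (>= 0).
#' @param mu Grand mean.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Numeric matrix, items x `rater:session` columns.
#' @export
simulate_ratings <- function(n_items, n_raters = 2, sessions = 2,
                             components = list(item_var = 9, rater_var = 0,
                                               residual_var = 1),
                             mu = 0, seed = 1L) {
  if (n_items < 2L) stop("need at least 2 items", call. = FALSE)
  vars <- unlist(components[c("item_var", "rater_var", "residual_var")])
  if (length(vars) != 3L || any(!is.finite(vars)) || any(vars < 0))
    stop("components must give item_var, rater_var, residual_var >= 0",
         call. = FALSE)
  tab <- .with_seed(seed, {
    b <- stats::rnorm(n_items, 0, sqrt(vars[["item_var"]]))
    cr <- stats::rnorm(n_raters, 0, sqrt(vars[["rater_var"]]))
    cols <- list()
    for (r in seq_len(n_raters))
      for (s in seq_len(sessions))
        cols[[paste0("U", r, ":", s)]] <-
          mu + b + cr[r] + stats::rnorm(n_items, 0, sqrt(vars[["residual_var"]]))
    do.call(cbind, cols)
  })
  rownames(tab) <- paste0("case", seq_len(n_items))
  attr(tab, "analytic_icc") <-
    if (sum(vars) > 0) vars[["item_var"]] / sum(vars) else NA_real_
  tab
}
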