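# Volumetric tracer-uptake quantification: anatomically anchored oriented
# voxel boxes per scheme region, per-region max/mean statistics, and
# background normalization against the proximal femoral mid-shaft.

#' Create an intensity volume
#'
#' A 3D scalar uptake grid (counts, arbitrary units) with the geometry
#' needed to map voxel indices to scanner-space millimetres.
#'
#' @param voxels 3D numeric array, at least 2 voxels per axis.
#' @param spacing Numeric length-3 voxel size in mm (> 0).
#' @param origin Numeric length-3 scanner-space position of the first voxel
#'   center (mm).
#' @param direction 3x3 orthonormal matrix mapping index axes to scanner
#'   axes (columns are the index-axis directions).
#' @return An object of class `uka_volume`.
#' @export
intensity_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 2L))
    stop("volume needs at least 2 voxels per axis", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 point (mm)", call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "uka_volume")
}

#' @export
print.uka_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<intensity volume %dx%dx%d, spacing %.2fx%.2fx%.2f mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# N x 3 matrix of voxel-center scanner coordinates, voxels in array order
.voxel_centers <- function(volume) {
  d <- dim(volume$voxels)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  sweep(idx %*% t(volume$direction %*% diag(volume$spacing)), 2,
        volume$origin, `+`)
}

#' Box-placement configuration
#'
#' Dimensions (mm) of the oriented voxel boxes anchoring the localization
#' scheme to a landmark set. Defaults are plausible for adult knees; every
#' dimension is overridable.
#'
#' @param slab_mm Femoral/tibial axial slab thickness per level (inferior,
#'   superior).
#' @param zone_ml_width_mm Medial-lateral width of peripheral zones 1 and 2
#'   on femur and tibia.
#' @param zone3_ml_width_mm Medial-lateral width of the central tibial zone
#'   straddling the stem axis.
#' @param ap_depth_mm Anterior (and posterior) extent of femoral/tibial
#'   boxes from the AP origin plane.
#' @param femoral_distal_offset_mm Start of the femoral inferior slab above
#'   the knee center along the mechanical axis.
#' @param patella_ml_width_mm,patella_slab_mm,patella_ap_depth_mm Patellar
#'   box half-grid dimensions (zone width, axial slab, full AP half-depth).
#' @param background_dims_mm Background box edge lengths (ml, ap, si).
#' @param background_fraction Position of the background box center along
#'   the femoral mechanical axis as a fraction of the knee-to-head distance,
#'   in (0, 1); 0.5 is the mid-shaft.
#' @param statistic_override `NULL` for the scheme's per-region defaults,
#'   or `"max"`/`"mean"` to force one statistic for every region.
#' @return A list of class `uka_box_config`.
#' @export
box_config <- function(slab_mm = 10, zone_ml_width_mm = 40,
                       zone3_ml_width_mm = 15, ap_depth_mm = 40,
                       femoral_distal_offset_mm = 0,
                       patella_ml_width_mm = 22, patella_slab_mm = 12,
                       patella_ap_depth_mm = 12,
                       background_dims_mm = c(20, 20, 30),
                       background_fraction = 0.5,
                       statistic_override = NULL) {
  cfg <- list(slab_mm = slab_mm, zone_ml_width_mm = zone_ml_width_mm,
              zone3_ml_width_mm = zone3_ml_width_mm, ap_depth_mm = ap_depth_mm,
              femoral_distal_offset_mm = femoral_distal_offset_mm,
              patella_ml_width_mm = patella_ml_width_mm,
              patella_slab_mm = patella_slab_mm,
              patella_ap_depth_mm = patella_ap_depth_mm,
              background_dims_mm = as.numeric(background_dims_mm),
              background_fraction = background_fraction,
              statistic_override = statistic_override)
  lens <- c(cfg$slab_mm, cfg$zone_ml_width_mm, cfg$zone3_ml_width_mm,
            cfg$ap_depth_mm, cfg$patella_ml_width_mm, cfg$patella_slab_mm,
            cfg$patella_ap_depth_mm, cfg$background_dims_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all box dimensions must be positive (mm)", call. = FALSE)
  if (length(cfg$background_dims_mm) != 3L)
    stop("background_dims_mm must have length 3 (ml, ap, si)", call. = FALSE)
  if (!is.finite(cfg$femoral_distal_offset_mm) || cfg$femoral_distal_offset_mm < 0)
    stop("femoral_distal_offset_mm must be >= 0", call. = FALSE)
  if (!is.finite(cfg$background_fraction) ||
      cfg$background_fraction <= 0 || cfg$background_fraction >= 1)
    stop("background_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(cfg$statistic_override) &&
      !cfg$statistic_override %in% c("max", "mean"))
    stop("statistic_override must be NULL, 'max' or 'mean'", call. = FALSE)
  class(cfg) <- "uka_box_config"
  cfg
}

# Oriented box: frame-axis-aligned, half-open membership [-h, h) per axis.
.region_box <- function(region, frame, local_center, half_extents) {
  center <- frame$origin + .frame_matrix(frame) %*% local_center
  structure(list(region = region, axes = .frame_matrix(frame),
                 center = as.numeric(center),
                 half_extents = as.numeric(half_extents)),
            class = "uka_box")
}

#' Build the scheme's region boxes from landmarks
#'
#' Places one oriented box per scored region plus the femoral mid-shaft
#' background box. Femoral boxes tile the distal femur (medial/lateral split
#' at the frame origin, anterior/posterior at the AP origin plane, two axial
#' slabs above a configurable distal offset); tibial boxes tile the proximal
#' tibia with a central zone-3 column straddling the stem axis flanked by
#' the medial and lateral zones, two axial slabs below the tibial plateau;
#' patellar boxes split the patella medial/lateral and superior/inferior.
#' Within one bone the boxes partition their tile (half-open faces), so no
#' voxel center is counted twice.
#'
#' @param landmarks A `uka_landmarks` set with femoral and tibial frame
#'   landmarks and `patella_center`.
#' @param config A [box_config()].
#' @return Named list of `uka_box` objects: the 24 scored labels plus
#'   `femoral_shaft_background`.
#' @export
build_region_boxes <- function(landmarks, config = box_config()) {
  stopifnot(inherits(config, "uka_box_config"))
  .require_landmarks(landmarks, "patella_center")
  fem <- femoral_frame(landmarks)
  tib <- tibial_frame(landmarks)
  pat <- anatomical_frame(landmarks$patella_center, fem$ml, fem$ap, fem$si)

  slab <- config$slab_mm; zw <- config$zone_ml_width_mm
  w3 <- config$zone3_ml_width_mm; ad <- config$ap_depth_mm
  off <- config$femoral_distal_offset_mm

  boxes <- list()
  for (r in enumerate_scored_regions()) {
    ml_int <- NULL; ap_int <- NULL; si_int <- NULL; frame <- NULL
    if (r$bone == "F") {
      frame <- fem
      ml_int <- if (r$zone == 1L) c(-zw, 0) else c(0, zw)
      ap_int <- if (r$sagittal == "p") c(-ad, 0) else c(0, ad)
      si_int <- if (r$axial == "i") c(off, off + slab) else
        c(off + slab, off + 2 * slab)
    } else if (r$bone == "T") {
      frame <- tib
      ml_int <- switch(as.character(r$zone),
                       "1" = c(-w3 / 2 - zw, -w3 / 2),
                       "2" = c(w3 / 2, w3 / 2 + zw),
                       "3" = c(-w3 / 2, w3 / 2))
      ap_int <- if (r$sagittal == "p") c(-ad, 0) else c(0, ad)
      si_int <- if (r$axial == "s") c(-slab, 0) else c(-2 * slab, -slab)
    } else {
      frame <- pat
      pw <- config$patella_ml_width_mm
      ml_int <- if (r$zone == 1L) c(-pw, 0) else c(0, pw)
      ap_int <- c(-config$patella_ap_depth_mm, config$patella_ap_depth_mm)
      si_int <- if (r$axial == "i") c(-config$patella_slab_mm, 0) else
        c(0, config$patella_slab_mm)
    }
    lc <- c(mean(ml_int), mean(ap_int), mean(si_int))
    he <- c(diff(ml_int), diff(ap_int), diff(si_int)) / 2
    boxes[[r$label]] <- .region_box(r$label, frame, lc, he)
  }

  shaft_len <- sqrt(sum((landmarks$femoral_head_center -
                           landmarks$knee_center_femur)^2))
  bg_center <- c(0, 0, config$background_fraction * shaft_len)
  boxes[["femoral_shaft_background"]] <-
    .region_box("femoral_shaft_background", fem, bg_center,
                config$background_dims_mm / 2)
  boxes
}

# logical membership of all voxel centers in a box
.in_box <- function(centers, box) {
  q <- sweep(centers, 2, box$center) %*% box$axes
  (q[, 1] >= -box$half_extents[1] & q[, 1] < box$half_extents[1] &
   q[, 2] >= -box$half_extents[2] & q[, 2] < box$half_extents[2] &
   q[, 3] >= -box$half_extents[3] & q[, 3] < box$half_extents[3])
}

#' Quantify tracer uptake in one region box
#'
#' Collects every voxel whose center lies inside the oriented box
#' (inclusive on the minimum face, exclusive on the maximum face — no
#' interpolation, no partial-volume weighting) and returns the max or mean
#' of their intensities.
#'
#' @param volume A `uka_volume`.
#' @param box A `uka_box`.
#' @param statistic `"max"` or `"mean"`.
#' @return Scalar intensity.
#' @export
quantify_region <- function(volume, box, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(volume, "uka_volume"), inherits(box, "uka_box"))
  inside <- .in_box(.voxel_centers(volume), box)
  if (!any(inside))
    stop(sprintf("region '%s': no voxel center falls inside the box", box$region),
         call. = FALSE)
  vals <- as.vector(volume$voxels)[inside]
  if (statistic == "max") max(vals) else mean(vals)
}

#' Background reference uptake at the femoral mid-shaft
#'
#' Mean intensity over a box centered on the femoral mechanical axis at a
#' configurable fraction (default 0.5) of the knee-to-head distance. The
#' returned value must be positive to serve as a ratio denominator.
#'
#' @param volume A `uka_volume`.
#' @param landmarks A `uka_landmarks` set with the femoral frame landmarks.
#' @param config A [box_config()].
#' @return Positive scalar intensity.
#' @export
background_reference <- function(volume, landmarks, config = box_config()) {
  fem <- femoral_frame(landmarks)
  shaft_len <- sqrt(sum((landmarks$femoral_head_center -
                           landmarks$knee_center_femur)^2))
  box <- .region_box("femoral_shaft_background", fem,
                     c(0, 0, config$background_fraction * shaft_len),
                     config$background_dims_mm / 2)
  bg <- quantify_region(volume, box, "mean")
  if (!is.finite(bg) || bg <= 0)
    stop("background reference is not positive; cannot form uptake ratios",
         call. = FALSE)
  bg
}

#' Per-region uptake report with background-normalized ratios
#'
#' One record per scored region in the scheme's canonical order: the
#' region's absolute uptake (its configured statistic over in-box voxels)
#' and the ratio of that value to the femoral mid-shaft background.
#'
#' @param volume A `uka_volume`.
#' @param boxes Output of [build_region_boxes()].
#' @param background Positive background intensity (see
#'   [background_reference()]).
#' @param statistics Optional named character vector mapping region labels
#'   to `"max"`/`"mean"`; defaults to the scheme's per-region statistics.
#' @return A data.frame with columns `region`, `statistic`, `absolute`,
#'   `ratio`, carrying the background value as attribute `background`.
#' @export
uptake_report <- function(volume, boxes, background, statistics = NULL) {
  if (!is.finite(background) || background <= 0)
    stop("background must be a positive intensity", call. = FALSE)
  labels <- .SCHEME_ORDER
  missing <- setdiff(labels, names(boxes))
  if (length(missing))
    stop(sprintf("boxes missing for region(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (is.null(statistics))
    statistics <- vapply(labels, default_statistic, "")
  centers <- .voxel_centers(volume)
  vals <- as.vector(volume$voxels)
  absolute <- vapply(labels, function(lab) {
    inside <- .in_box(centers, boxes[[lab]])
    if (!any(inside))
      stop(sprintf("region '%s': no voxel center falls inside the box", lab),
           call. = FALSE)
    if (statistics[[lab]] == "max") max(vals[inside]) else mean(vals[inside])
  }, 0)
  out <- data.frame(region = labels,
                    statistic = unname(statistics[labels]),
                    absolute = unname(absolute),
                    ratio = unname(absolute) / background,
                    stringsAsFactors = FALSE)
  attr(out, "background") <- background
  out
}
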