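# Anatomical coordinate frames from landmarks, and component orientation as
# signed projected angles. All coordinates are scanner-space millimetres;
# angles are degrees externally, radians internally, wrapped to (-180, 180].

.EPS_DEGENERATE <- 1e-6   # mm / rad threshold for coincident points, parallel axes
.EPS_FRAME <- 1e-9        # orthonormality tolerance for a finished frame

.unit <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < .EPS_DEGENERATE)
    stop(sprintf("degenerate geometry: %s has (near-)zero length", what), call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# component of v orthogonal to unit vector u
.ortho <- function(v, u, what = "axis") {
  w <- v - sum(v * u) * u
  n <- sqrt(sum(w^2))
  if (n < .EPS_DEGENERATE * max(1, sqrt(sum(v^2))))
    stop(sprintf("degenerate geometry: %s is (near-)parallel to the reference axis",
                 what), call. = FALSE)
  w / n
}

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Construct an anatomical coordinate frame
#'
#' A frame is an origin plus a right-handed orthonormal triad: `ml`
#' (medial to lateral), `ap` (posterior to anterior) and `si` (inferior to
#' superior), satisfying `ml x ap = si`.
#'
#' @param origin Numeric length-3 point (mm).
#' @param ml,ap,si Numeric length-3 unit axis vectors.
#' @return An object of class `uka_frame`.
#' @export
anatomical_frame <- function(origin, ml, ap, si) {
  stopifnot(length(origin) == 3L, length(ml) == 3L, length(ap) == 3L,
            length(si) == 3L, all(is.finite(c(origin, ml, ap, si))))
  M <- cbind(ml, ap, si)
  G <- crossprod(M)
  if (max(abs(G - diag(3))) > 1e-7)
    stop("frame axes are not an orthonormal triad", call. = FALSE)
  if (det(M) < 0)
    stop("frame axes are not right-handed (ml x ap must equal si)", call. = FALSE)
  structure(list(origin = as.numeric(origin), ml = as.numeric(ml),
                 ap = as.numeric(ap), si = as.numeric(si)),
            class = "uka_frame")
}

#' @export
print.uka_frame <- function(x, ...) {
  cat("<anatomical frame>\n")
  cat(sprintf("  origin: [%7.2f %7.2f %7.2f] mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("ml", "ap", "si"))
    cat(sprintf("  %s: [%8.5f %8.5f %8.5f]\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

# 3x3 matrix with columns ml, ap, si
.frame_matrix <- function(frame) cbind(frame$ml, frame$ap, frame$si)

#' Create a landmark set
#'
#' Named 3D fiducial points in scanner space (mm). Anatomical names used by
#' the frame constructors: `femoral_head_center`, `knee_center_femur`,
#' `medial_epicondyle`, `lateral_epicondyle`, `knee_center_tibia`,
#' `ankle_center`, `tibia_posterior_condyle_medial`,
#' `tibia_posterior_condyle_lateral`, optionally `patella_center`; component
#' fiducials `femoral_component_origin`/`_ml`/`_ap` and the tibial
#' equivalents.
#'
#' @param ... Named numeric length-3 vectors, or a single named list of them.
#' @param space Coordinate-space tag recorded with the set.
#' @return An object of class `uka_landmarks` (a named list of points).
#' @export
landmark_set <- function(..., space = "scanner") {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1]))
    pts <- pts[[1]]
  if (length(pts) == 0L || is.null(names(pts)) || any(!nzchar(names(pts))))
    stop("all landmarks must be named", call. = FALSE)
  if (anyDuplicated(names(pts)))
    stop("duplicate landmark names", call. = FALSE)
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p)))
      stop("each landmark must be a finite numeric length-3 point", call. = FALSE)
    p
  })
  structure(pts, space = space, class = "uka_landmarks")
}

.require_landmarks <- function(landmarks, names) {
  missing <- setdiff(names, names(landmarks))
  if (length(missing))
    stop(sprintf("missing landmark(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  invisible(landmarks)
}

#' Femoral anatomical frame
#'
#' The superior axis is the mechanical femoral axis (knee center to femoral
#' head center); the medial-lateral axis is the transepicondylar axis
#' orthogonalized against it; the anterior axis completes the right-handed
#' triad. Origin at the femoral knee center.
#'
#' @param landmarks A `uka_landmarks` set containing `femoral_head_center`,
#'   `knee_center_femur`, `medial_epicondyle`, `lateral_epicondyle`.
#' @return A `uka_frame`.
#' @export
femoral_frame <- function(landmarks) {
  .require_landmarks(landmarks, c("femoral_head_center", "knee_center_femur",
                                  "medial_epicondyle", "lateral_epicondyle"))
  si <- .unit(landmarks$femoral_head_center - landmarks$knee_center_femur,
              "mechanical femoral axis")
  tea <- landmarks$lateral_epicondyle - landmarks$medial_epicondyle
  if (sqrt(sum(tea^2)) < .EPS_DEGENERATE)
    stop("degenerate geometry: epicondyles coincide", call. = FALSE)
  ml <- .ortho(tea, si, "transepicondylar axis")
  ap <- .cross(si, ml)
  anatomical_frame(landmarks$knee_center_femur, ml, ap, si)
}

#' Tibial anatomical frame
#'
#' The superior axis is the tibial mechanical axis (ankle center to tibial
#' knee center); the medial-lateral axis is the tibial posterior condylar
#' axis orthogonalized against it. Origin at the tibial knee center.
#'
#' @param landmarks A `uka_landmarks` set containing `knee_center_tibia`,
#'   `ankle_center`, `tibia_posterior_condyle_medial`,
#'   `tibia_posterior_condyle_lateral`.
#' @return A `uka_frame`.
#' @export
tibial_frame <- function(landmarks) {
  .require_landmarks(landmarks, c("knee_center_tibia", "ankle_center",
                                  "tibia_posterior_condyle_medial",
                                  "tibia_posterior_condyle_lateral"))
  si <- .unit(landmarks$knee_center_tibia - landmarks$ankle_center,
              "mechanical tibial axis")
  pca <- landmarks$tibia_posterior_condyle_lateral -
    landmarks$tibia_posterior_condyle_medial
  if (sqrt(sum(pca^2)) < .EPS_DEGENERATE)
    stop("degenerate geometry: posterior condyle points coincide", call. = FALSE)
  ml <- .ortho(pca, si, "posterior condylar axis")
  ap <- .cross(si, ml)
  anatomical_frame(landmarks$knee_center_tibia, ml, ap, si)
}

#' Component frame from three fiducials
#'
#' The medial-lateral axis points from the origin fiducial to the ml
#' fiducial; the anterior axis is the origin-to-ap direction orthogonalized
#' against it; the superior axis completes the right-handed triad.
#'
#' @param origin,ml_point,ap_point Numeric length-3 points (mm),
#'   non-collinear.
#' @return A `uka_frame`.
#' @export
component_frame <- function(origin, ml_point, ap_point) {
  ml <- .unit(ml_point - origin, "component ml fiducial direction")
  ap <- .ortho(ap_point - origin, ml, "component ap fiducial direction")
  si <- .cross(ml, ap)
  anatomical_frame(origin, ml, ap, si)
}

#' Signed projected angle of a vector in a frame plane
#'
#' The vector is projected onto the named plane of the frame (coronal =
#' ml-si, sagittal = ap-si, axial = ml-ap) and the signed angle from the
#' reference axis is returned, measured counterclockwise about the plane
#' normal taken as the cross product of the plane's ordered axes (so
#' rotation from the first axis toward the second is positive), in degrees
#' within (-180, 180].
#'
#' @param v Numeric length-3 vector.
#' @param frame A `uka_frame`.
#' @param plane `"coronal"`, `"sagittal"` or `"axial"`.
#' @param reference Name of a frame axis lying in the plane (`"ml"`, `"ap"`
#'   or `"si"`).
#' @return Signed angle in degrees.
#' @export
projected_angle <- function(v, frame, plane = c("coronal", "sagittal", "axial"),
                            reference) {
  plane <- match.arg(plane)
  axes <- switch(plane,
                 coronal  = c("ml", "si"),
                 sagittal = c("ap", "si"),
                 axial    = c("ml", "ap"))
  if (!reference %in% axes)
    stop(sprintf("reference axis '%s' does not lie in the %s plane", reference, plane),
         call. = FALSE)
  u1 <- sum(v * frame[[axes[1]]])
  u2 <- sum(v * frame[[axes[2]]])
  if (sqrt(u1^2 + u2^2) < 1e-9 * max(1, sqrt(sum(v^2))))
    stop(sprintf("vector is (near-)orthogonal to the %s plane", plane), call. = FALSE)
  proj <- u1 * frame[[axes[1]]] + u2 * frame[[axes[2]]]
  r <- frame[[reference]]
  n <- .cross(frame[[axes[1]]], frame[[axes[2]]])
  theta <- atan2(sum(.cross(r, proj) * n), sum(proj * r))
  wrap_angle(theta * 180 / pi)
}

#' Angle sign conventions
#'
#' Multipliers (+1 or -1) mapping raw counterclockwise projected angles onto
#' clinical signs. Defaults: component varus positive (superior axis tilted
#' medially), femoral flexion positive / tibial posterior slope negative
#' (superior axis tilted anteriorly is positive), external rotation positive
#' hence internal rotation negative (medial-lateral axis swung anteriorly is
#' positive), and tibiofemoral varus positive (tibial mechanical axis
#' deviated laterally from the femoral one). Flip any multiplier to adopt
#' the opposite convention.
#'
#' @param varus,sagittal,axial,tfa Sign multipliers, each `+1` or `-1`.
#' @return A named list of multipliers.
#' @export
angle_conventions <- function(varus = 1, sagittal = -1, axial = 1, tfa = -1) {
  conv <- list(varus = varus, sagittal = sagittal, axial = axial, tfa = tfa)
  if (!all(vapply(conv, function(s) identical(abs(s), 1), TRUE)))
    stop("sign conventions must be +1 or -1", call. = FALSE)
  conv
}

.angle_report <- function(component, varus_valgus, sagittal_angle, axial_rotation) {
  structure(list(component = component,
                 varus_valgus = wrap_angle(varus_valgus),
                 sagittal_angle = wrap_angle(sagittal_angle),
                 axial_rotation = wrap_angle(axial_rotation)),
            class = "uka_angles")
}

#' @export
print.uka_angles <- function(x, ...) {
  sag_label <- if (identical(x$component, "tibial")) "slope (post. neg.)" else
    "flexion-extension"
  cat(sprintf("<%s component angles>\n", x$component))
  cat(sprintf("  varus-valgus:       %+7.2f deg (varus positive)\n", x$varus_valgus))
  cat(sprintf("  %-19s %+7.2f deg\n", paste0(sag_label, ":"), x$sagittal_angle))
  cat(sprintf("  axial rotation:     %+7.2f deg (internal negative)\n", x$axial_rotation))
  invisible(x)
}

.component_angles <- function(anat, comp, component, conventions) {
  vv  <- conventions$varus    * projected_angle(comp$si, anat, "coronal",  "si")
  sag <- conventions$sagittal * projected_angle(comp$si, anat, "sagittal", "si")
  rot <- conventions$axial    * projected_angle(comp$ml, anat, "axial",    "ml")
  .angle_report(component, vv, sag, rot)
}

#' Femoral component orientation angles
#'
#' Varus-valgus and flexion-extension are coronal- and sagittal-plane
#' projections of the component superior axis measured in the femoral
#' anatomical frame (transepicondylar + mechanical femoral axes); axial
#' rotation is the axial-plane projection of the component medial-lateral
#' axis against the transepicondylar axis.
#'
#' @param anat Femoral anatomical `uka_frame`.
#' @param comp Femoral component `uka_frame`.
#' @param conventions Output of [angle_conventions()].
#' @return A `uka_angles` report with fields `varus_valgus`,
#'   `sagittal_angle` (flexion positive) and `axial_rotation` (internal
#'   negative), in degrees.
#' @export
femoral_component_angles <- function(anat, comp, conventions = angle_conventions()) {
  .component_angles(anat, comp, "femoral", conventions)
}

#' Tibial component orientation angles
#'
#' As [femoral_component_angles()] but measured in the tibial frame
#' (posterior condylar + tibial mechanical axes); `sagittal_angle` is the
#' tibial slope (posterior slope negative).
#'
#' @inheritParams femoral_component_angles
#' @return A `uka_angles` report.
#' @export
tibial_component_angles <- function(anat, comp, conventions = angle_conventions()) {
  .component_angles(anat, comp, "tibial", conventions)
}

#' Femoral-tibial rotational mismatch
#'
#' The difference between the femoral and tibial component axial rotations
#' (femoral minus tibial), wrapped into (-180, 180].
#'
#' @param fem,tib `uka_angles` reports for the femoral and tibial components
#'   of the same case.
#' @return Signed mismatch in degrees.
#' @export
rotational_mismatch <- function(fem, tib) {
  stopifnot(inherits(fem, "uka_angles"), inherits(tib, "uka_angles"))
  wrap_angle(fem$axial_rotation - tib$axial_rotation)
}

#' Tibiofemoral mechanical angle
#'
#' Coronal-plane signed angle between the tibial mechanical axis (ankle
#' center to tibial knee center) and the femoral mechanical axis, measured
#' in the femoral anatomical frame; varus positive under the default
#' conventions.
#'
#' @param landmarks A `uka_landmarks` set with femoral frame landmarks plus
#'   `knee_center_tibia` and `ankle_center`.
#' @param conventions Output of [angle_conventions()].
#' @return Signed angle in degrees.
#' @export
tibiofemoral_angle <- function(landmarks, conventions = angle_conventions()) {
  .require_landmarks(landmarks, c("knee_center_tibia", "ankle_center"))
  fem <- femoral_frame(landmarks)
  t_axis <- .unit(landmarks$knee_center_tibia - landmarks$ankle_center,
                  "mechanical tibial axis")
  conventions$tfa * projected_angle(t_axis, fem, "coronal", "si")
}
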