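# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own code paths: closed forms in frame
# coordinates, explicit voxel loops, and aov()-based mean squares.

# closed-form projected angle: express v in frame coordinates and apply the
# per-plane atan2 form derived from the counterclockwise convention
oracle_projected_angle <- function(v, frame, plane, reference) {
  M <- cbind(frame$ml, frame$ap, frame$si)
  q <- as.numeric(t(M) %*% v)   # (ml, ap, si) components
  deg <- function(x) x * 180 / pi
  if (plane == "coronal") {       # normal ml x si = -ap; ccw takes ml -> si
    ang <- atan2(-q[1], q[3])     # from si
    if (reference == "ml") ang <- atan2(q[3], q[1])
  } else if (plane == "sagittal") { # normal ap x si = ml; ccw takes ap -> si
    ang <- atan2(-q[2], q[3])     # from si
    if (reference == "ap") ang <- atan2(q[3], q[2])
  } else {                        # axial, normal si; ccw takes ml -> ap
    ang <- atan2(q[2], q[1])      # from ml
    if (reference == "ap") ang <- atan2(-q[1], q[2])
  }
  deg(ang)
}

# brute-force voxel loop: walks every index triple, maps it to scanner
# space and tests half-open box membership coordinate by coordinate
oracle_quantify <- function(volume, box, statistic) {
  d <- dim(volume$voxels)
  A <- volume$direction %*% diag(volume$spacing)
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- volume$origin + A %*% c(i - 1, j - 1, k - 1)
    q <- t(box$axes) %*% (p - box$center)
    if (all(q >= -box$half_extents) && all(q < box$half_extents))
      vals <- c(vals, volume$voxels[i, j, k])
  }
  if (!length(vals)) return(NA_real_)
  if (statistic == "max") max(vals) else mean(vals)
}

# ANOVA mean squares via aov(), then the single-measure ICC formulas
oracle_icc <- function(x, model) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   item = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  if (model == "oneway") {
    tab <- summary(stats::aov(y ~ item, data = df))[[1]]
    msb <- tab["item", "Mean Sq"]; msw <- tab["Residuals", "Mean Sq"]
    return((msb - msw) / (msb + (k - 1) * msw))
  }
  tab <- summary(stats::aov(y ~ item + rater, data = df))[[1]]
  msr <- tab["item", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (model == "twoway_mixed_consistency")
    (msr - mse) / (msr + (k - 1) * mse)
  else
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random orthonormal right-handed frame via QR
random_frame <- function(origin = rnorm(3, sd = 50)) {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  anatomical_frame(origin, q[, 1], q[, 2], q[, 3])
}

random_rotation3 <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# canonical axis-aligned template landmarks (no component pose)
template_landmarks <- function() {
  generate_landmark_case(angle_report("femoral", 0, 0, 0),
                         angle_report("tibial", 0, 0, 0), 0)
}

rigid_apply <- function(landmarks, rot, shift) {
  landmark_set(lapply(unclass(landmarks), function(p) as.numeric(rot %*% p + shift)))
}

angles_vector <- function(m) {
  c(m$femoral$varus_valgus, m$femoral$sagittal_angle, m$femoral$axial_rotation,
    m$tibial$varus_valgus, m$tibial$sagittal_angle, m$tibial$axial_rotation,
    m$tibiofemoral)
}
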