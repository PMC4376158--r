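# Readers and writers: NIfTI-1 volumes, JSON landmark files, YAML box
# configuration, CSV reports. All interfaces speak scanner-space
# millimetres; voxel indices are never exposed.

.KNOWN_LANDMARKS <- c(
  "femoral_head_center", "knee_center_femur", "medial_epicondyle",
  "lateral_epicondyle", "knee_center_tibia", "ankle_center",
  "tibia_posterior_condyle_medial", "tibia_posterior_condyle_lateral",
  "patella_center",
  "femoral_component_origin", "femoral_component_ml", "femoral_component_ap",
  "tibial_component_origin", "tibial_component_ml", "tibial_component_ap")

#' Read a NIfTI-1 volume as an intensity volume
#'
#' Decomposes the file's affine into spacing, origin and an orthonormal
#' direction matrix. Files whose direction matrix deviates from
#' orthonormality by more than 1e-3, and non-3D images, are rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `uka_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop nifti bookkeeping attrs
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D volume, got %dD: %s", length(dim(arr)), path),
         call. = FALSE)
  affine <- RNifti::xform(img)
  lin <- unclass(affine)[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0))
    stop("affine has a zero-length axis", call. = FALSE)
  direction <- sweep(lin, 2, spacing, `/`)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-3)
    stop("volume direction matrix is not orthonormal (oblique/sheared affine)",
         call. = FALSE)
  # re-orthonormalize residual rounding before the strict constructor check
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  intensity_volume(arr, spacing, unclass(affine)[1:3, 4], direction)
}

#' Write an intensity volume to NIfTI-1
#'
#' @param volume A `uka_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "uka_volume"))
  img <- RNifti::asNifti(volume$voxels)
  affine <- rbind(cbind(volume$direction %*% diag(volume$spacing),
                        volume$origin),
                  c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' Expected schema: an object with a `space` string and a `landmarks`
#' object mapping names to `[x, y, z]` mm triplets. Names outside the
#' documented vocabulary are kept but recorded in attribute
#' `unknown_names`.
#'
#' @param path Path to a JSON file.
#' @return A `uka_landmarks` set.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- if (!is.null(obj$landmarks)) obj$landmarks else obj
  if (!is.list(pts) || length(pts) == 0L)
    stop(sprintf("no landmarks found in %s", path), call. = FALSE)
  lm <- landmark_set(pts, space = if (is.null(obj$space)) "scanner" else obj$space)
  unknown <- setdiff(names(lm), .KNOWN_LANDMARKS)
  if (length(unknown)) attr(lm, "unknown_names") <- unknown
  lm
}

#' Write a landmark set to JSON
#'
#' @param landmarks A `uka_landmarks` set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "uka_landmarks"))
  obj <- list(space = attr(landmarks, "space"),
              landmarks = lapply(unclass(landmarks), as.numeric))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read box configuration from YAML
#'
#' Keys mirror the arguments of [box_config()]; unknown keys are an error
#' (a silently ignored typo in a box dimension would corrupt the analysis).
#'
#' @param path Path to a YAML file.
#' @return A `uka_box_config`.
#' @export
read_box_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(box_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(box_config, vals)
}

# stable hash of a configuration (canonical JSON -> md5)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}

.file_hash <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}
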