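# Full-case evaluation: anatomical frames -> region boxes -> background ->
# uptake report, plus both component angle measurements, bundled into a
# single auditable case report.

#' Measure all component angles of a case
#'
#' Builds the femoral and tibial anatomical frames and the component frames
#' from their fiducial triples, then reports femoral and tibial component
#' angles, their rotational mismatch and the tibiofemoral angle.
#'
#' @param landmarks A `uka_landmarks` set with anatomical landmarks and the
#'   `femoral_component_*` / `tibial_component_*` fiducials.
#' @param conventions Output of [angle_conventions()].
#' @return List with `femoral` and `tibial` (`uka_angles`),
#'   `rotational_mismatch` and `tibiofemoral` (degrees).
#' @export
measure_angles <- function(landmarks, conventions = angle_conventions()) {
  .require_landmarks(landmarks,
                     c("femoral_component_origin", "femoral_component_ml",
                       "femoral_component_ap", "tibial_component_origin",
                       "tibial_component_ml", "tibial_component_ap"))
  fem_anat <- femoral_frame(landmarks)
  tib_anat <- tibial_frame(landmarks)
  fem_comp <- component_frame(landmarks$femoral_component_origin,
                              landmarks$femoral_component_ml,
                              landmarks$femoral_component_ap)
  tib_comp <- component_frame(landmarks$tibial_component_origin,
                              landmarks$tibial_component_ml,
                              landmarks$tibial_component_ap)
  fem <- femoral_component_angles(fem_anat, fem_comp, conventions)
  tib <- tibial_component_angles(tib_anat, tib_comp, conventions)
  list(femoral = fem, tibial = tib,
       rotational_mismatch = rotational_mismatch(fem, tib),
       tibiofemoral = tibiofemoral_angle(landmarks, conventions))
}

#' Run the full evaluation for one case
#'
#' Executes the whole pipeline on one volume + landmark set: frames, region
#' boxes, femoral mid-shaft background, per-region uptake report with
#' background ratios, and all component angle measurements. Deterministic
#' for fixed inputs; any stage failure aborts with a stage-labeled message.
#'
#' @param volume A `uka_volume` or path to a NIfTI file.
#' @param landmarks A `uka_landmarks` set or path to a landmark JSON file.
#' @param config A [box_config()] or path to a YAML config file.
#' @param case_id Identifier recorded in the report.
#' @param conventions Output of [angle_conventions()].
#' @return An object of class `uka_case_report`: `case_id`, `uptake`
#'   (data.frame), `background`, `angles`, `provenance`.
#' @export
run_case <- function(volume, landmarks, config = box_config(),
                     case_id = "case", conventions = angle_conventions()) {
  volume_path <- if (is.character(volume)) volume else NULL
  landmarks_path <- if (is.character(landmarks)) landmarks else NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s' failed: %s", case_id, name,
                   conditionMessage(e)), call. = FALSE))
  }
  volume <- stage("read_volume",
                  if (is.character(volume)) read_volume(volume) else volume)
  landmarks <- stage("read_landmarks",
                     if (is.character(landmarks)) read_landmarks(landmarks)
                     else landmarks)
  if (is.character(config)) config <- stage("read_config", read_box_config(config))
  stopifnot(inherits(volume, "uka_volume"), inherits(landmarks, "uka_landmarks"),
            inherits(config, "uka_box_config"))

  boxes <- stage("build_region_boxes", build_region_boxes(landmarks, config))
  background <- stage("background_reference",
                      background_reference(volume, landmarks, config))
  stats_map <- vapply(.SCHEME_ORDER, default_statistic, "",
                      override = config$statistic_override)
  uptake <- stage("uptake_report",
                  uptake_report(volume, boxes, background, stats_map))
  angles <- stage("measure_angles", measure_angles(landmarks, conventions))

  structure(list(
    case_id = case_id,
    uptake = uptake,
    background = background,
    angles = angles,
    provenance = list(
      volume_md5 = .file_hash(volume_path),
      landmarks_md5 = .file_hash(landmarks_path),
      config_hash = .config_hash(config),
      package_version = as.character(utils::packageVersion("ukaspect")))),
    class = "uka_case_report")
}

#' @export
print.uka_case_report <- function(x, ...) {
  cat(sprintf("<case report '%s'>\n", x$case_id))
  cat(sprintf("  background: %.3f\n", x$background))
  cat(sprintf("  uptake ratios: %d regions, range %.2f-%.2f\n",
              nrow(x$uptake), min(x$uptake$ratio), max(x$uptake$ratio)))
  cat(sprintf("  femoral vv/flex/rot: %+.1f / %+.1f / %+.1f deg\n",
              x$angles$femoral$varus_valgus, x$angles$femoral$sagittal_angle,
              x$angles$femoral$axial_rotation))
  cat(sprintf("  tibial  vv/slope/rot: %+.1f / %+.1f / %+.1f deg\n",
              x$angles$tibial$varus_valgus, x$angles$tibial$sagittal_angle,
              x$angles$tibial$axial_rotation))
  cat(sprintf("  rotational mismatch: %+.1f deg, tibiofemoral: %+.1f deg\n",
              x$angles$rotational_mismatch, x$angles$tibiofemoral))
  invisible(x)
}

#' Serialize a case report
#'
#' Writes the uptake table as CSV (with the background value and config
#' hash recorded in comment header lines) and, alongside it, a full JSON
#' sidecar carrying the angles and provenance at full precision.
#'
#' @param report A `uka_case_report`.
#' @param path Output CSV path; the JSON sidecar replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  stopifnot(inherits(report, "uka_case_report"))
  con <- file(path, "w")
  writeLines(c(sprintf("# case_id: %s", report$case_id),
               sprintf("# background: %.12g", report$background),
               sprintf("# config_hash: %s", report$provenance$config_hash)), con)
  utils::write.csv(report$uptake, con, row.names = FALSE)
  close(con)
  side <- sub("\\.[^.]*$", ".json", path)
  angles <- report$angles
  jsonlite::write_json(list(
    case_id = report$case_id,
    background = report$background,
    angles = list(
      femoral = unclass(angles$femoral), tibial = unclass(angles$tibial),
      rotational_mismatch = angles$rotational_mismatch,
      tibiofemoral = angles$tibiofemoral),
    provenance = report$provenance),
    side, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read back a case report written by [write_case_report()]
#'
#' @param path The CSV path passed to [write_case_report()].
#' @return A list with `uptake`, `background`, `case_id`, plus the JSON
#'   sidecar contents when present.
#' @export
read_case_report <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  uptake <- utils::read.csv(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), header, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA_character_
  }
  out <- list(case_id = get_field("case_id"),
              background = as.numeric(get_field("background")),
              uptake = uptake)
  side <- sub("\\.[^.]*$", ".json", path)
  if (file.exists(side))
    out$sidecar <- jsonlite::read_json(side, simplifyVector = TRUE)
  out
}
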