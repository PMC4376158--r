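# Periprosthetic localization scheme: 24 scored regions on femur, tibia and
# patella, coded as bone letter + zone digit + axial letter (+ sagittal letter).

# Scored regions in the canonical report order, with the per-region default
# summary statistic. Four femoral regions use the mean; all others the max.
.SCHEME_ORDER <- c(
  "F2ip", "F1ip", "F2ia", "F1ia", "F2sa", "F1sa", "F1sp", "F2sp",
  "P2s",  "P2i",  "P1i",  "P1s",
  "T2sp", "T3sp", "T1sp", "T2sa", "T3sa", "T1sa",
  "T2ia", "T3ia", "T1ia", "T2ip", "T3ip", "T1ip"
)
.SCHEME_MEAN_REGIONS <- c("F2ip", "F1ip", "F2ia", "F1sp")

.AUX_REGIONS <- c("femoral_shaft_background", "stem_tip", "tibial_tubercle")

#' Construct a localization-scheme region code
#'
#' A region code identifies one cell of the periprosthetic localization grid:
#' bone (`F` femur, `T` tibia, `P` patella), zone (`1` medial, `2` lateral,
#' `3` central around the tibial stem), axial level (`i` inferior, `s`
#' superior) and, for femur and tibia only, sagittal half (`a` anterior,
#' `p` posterior). Zone 3 exists only on the tibia; patellar regions carry no
#' sagittal letter.
#'
#' @param bone `"F"`, `"T"` or `"P"`.
#' @param zone Integer 1, 2 or 3 (3 only with `bone = "T"`).
#' @param axial `"i"` or `"s"`.
#' @param sagittal `"a"` or `"p"`, or `NULL` for patellar regions.
#' @return An object of class `uka_region` with fields `bone`, `zone`,
#'   `axial`, `sagittal` and canonical `label`.
#' @examples
#' region_code("F", 2, "i", "p")$label
#' @export
region_code <- function(bone, zone, axial, sagittal = NULL) {
  if (!is.character(bone) || length(bone) != 1L || !bone %in% c("F", "T", "P"))
    stop("region bone must be one of 'F', 'T', 'P'", call. = FALSE)
  zone <- as.integer(zone)
  if (length(zone) != 1L || is.na(zone) || !zone %in% 1:3)
    stop("region zone must be 1 (medial), 2 (lateral) or 3 (central)", call. = FALSE)
  if (zone == 3L && bone != "T")
    stop("region zone 3 (central around stem) occurs only on the tibia", call. = FALSE)
  if (!is.character(axial) || length(axial) != 1L || !axial %in% c("i", "s"))
    stop("region axial level must be 'i' or 's'", call. = FALSE)
  if (bone == "P") {
    if (!is.null(sagittal))
      stop("patellar regions carry no sagittal letter", call. = FALSE)
  } else {
    if (is.null(sagittal) || length(sagittal) != 1L || !sagittal %in% c("a", "p"))
      stop("femoral/tibial regions require sagittal 'a' or 'p'", call. = FALSE)
  }
  structure(
    list(bone = bone, zone = zone, axial = axial, sagittal = sagittal,
         label = paste0(bone, zone, axial, if (is.null(sagittal)) "" else sagittal)),
    class = "uka_region"
  )
}

#' @export
format.uka_region <- function(x, ...) x$label

#' @export
print.uka_region <- function(x, ...) {
  zone_name <- c("medial", "lateral", "central around stem")[x$zone]
  cat(sprintf("<region %s: %s, %s, %s%s>\n", x$label,
              c(F = "femur", T = "tibia", P = "patella")[x$bone], zone_name,
              c(i = "inferior", s = "superior")[x$axial],
              if (is.null(x$sagittal)) "" else
                paste0(", ", c(a = "anterior", p = "posterior")[x$sagittal])))
  invisible(x)
}

#' Parse a region label into a region code
#'
#' Labels are case-sensitive: uppercase bone letter, lowercase modifiers
#' (e.g. `"F2ip"`, `"P1s"`, `"T3sp"`). Labels outside the scored grammar
#' (femoral zone 3, patellar sagittal letters, unknown characters) are
#' rejected with an error naming the offending field.
#'
#' @param label A single non-empty string.
#' @return A `uka_region`; `parse_region_label(r$label)` reproduces `r` for
#'   every scored region.
#' @examples
#' parse_region_label("T3sp")
#' @export
parse_region_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label))
    stop("region label must be a single non-empty string", call. = FALSE)
  chars <- strsplit(label, "")[[1]]
  if (!chars[1] %in% c("F", "T", "P"))
    stop(sprintf("region label '%s': bone letter must be F, T or P (uppercase)", label),
         call. = FALSE)
  bone <- chars[1]
  expected_len <- if (bone == "P") 3L else 4L
  if (length(chars) != expected_len)
    stop(sprintf("region label '%s': expected %d characters for bone %s",
                 label, expected_len, bone), call. = FALSE)
  if (!chars[2] %in% c("1", "2", "3"))
    stop(sprintf("region label '%s': zone must be 1, 2 or 3", label), call. = FALSE)
  zone <- as.integer(chars[2])
  if (zone == 3L && bone != "T")
    stop(sprintf("region label '%s': zone 3 occurs only on the tibia", label),
         call. = FALSE)
  if (!chars[3] %in% c("i", "s"))
    stop(sprintf("region label '%s': axial letter must be 'i' or 's'", label),
         call. = FALSE)
  sagittal <- NULL
  if (bone != "P") {
    if (!chars[4] %in% c("a", "p"))
      stop(sprintf("region label '%s': sagittal letter must be 'a' or 'p'", label),
           call. = FALSE)
    sagittal <- chars[4]
  }
  region_code(bone, zone, chars[3], sagittal)
}

#' Enumerate the scored regions of the localization scheme
#'
#' Returns the 24 scored regions in the canonical report order: 8 femoral,
#' 4 patellar and 12 tibial regions. Auxiliary regions (femoral shaft
#' background, stem tip, tibial tubercle) are never part of this enumeration.
#'
#' @return A list of `uka_region` objects with unique labels.
#' @examples
#' length(enumerate_scored_regions())
#' @export
enumerate_scored_regions <- function() {
  lapply(.SCHEME_ORDER, parse_region_label)
}

#' Auxiliary (non-scored) regions
#'
#' The femoral mid-shaft background (the only permitted denominator for
#' uptake ratios), the stem tip and the tibial tubercle. These support the
#' scored scheme but are never scored themselves.
#'
#' @return Character vector of auxiliary region kinds.
#' @export
auxiliary_regions <- function() .AUX_REGIONS

#' Default summary statistic for a scored region
#'
#' Per-region defaults: the mean for regions `F2ip`, `F1ip`, `F2ia` and
#' `F1sp`, the max for all other scored regions. A global override forces a
#' single statistic for every region.
#'
#' @param region A `uka_region` or a region label string.
#' @param override `NULL` (per-region default), `"max"` or `"mean"`.
#' @return `"max"` or `"mean"`.
#' @examples
#' default_statistic("F2ip")
#' default_statistic("T3sp")
#' @export
default_statistic <- function(region, override = NULL) {
  if (is.character(region)) region <- parse_region_label(region)
  if (!inherits(region, "uka_region"))
    stop("region must be a uka_region or label string", call. = FALSE)
  if (!region$label %in% .SCHEME_ORDER)
    stop(sprintf("'%s' is not a scored region; no statistic defined", region$label),
         call. = FALSE)
  if (!is.null(override)) {
    if (!override %in% c("max", "mean"))
      stop("statistic override must be 'max' or 'mean'", call. = FALSE)
    return(override)
  }
  if (region$label %in% .SCHEME_MEAN_REGIONS) "mean" else "max"
}

#' Tabulate the localization scheme
#'
#' One row per scored region in canonical order with its decomposition and
#' default statistic; suitable for serialization and for the command-line
#' `scheme list` subcommand.
#'
#' @param statistic_override `NULL`, `"max"` or `"mean"` (applied to all rows).
#' @return A data.frame with columns `label`, `bone`, `zone`, `axial`,
#'   `sagittal` (`NA` for patella) and `statistic`.
#' @export
scheme_table <- function(statistic_override = NULL) {
  regions <- enumerate_scored_regions()
  data.frame(
    label = vapply(regions, `[[`, "", "label"),
    bone = vapply(regions, `[[`, "", "bone"),
    zone = vapply(regions, `[[`, 0L, "zone"),
    axial = vapply(regions, `[[`, "", "axial"),
    sagittal = vapply(regions, function(r)
      if (is.null(r$sagittal)) NA_character_ else r$sagittal, ""),
    statistic = vapply(regions, default_statistic, "",
                       override = statistic_override),
    stringsAsFactors = FALSE
  )
}
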