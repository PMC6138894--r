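#' Clinical measures from segmentations
#'
#' Chamber volumes are voxel counts times the volume per voxel; LV mass is
#' the myocardial volume times the density 1.05 g/mL; stroke volume,
#' ejection fraction and cardiac output derive from the end-diastolic (ED)
#' and end-systolic (ES) volumes, with ED/ES located at the extrema of the
#' cavity volume curve.
#'
#' @name clinical-measures
NULL

.myocardium_density <- 1.05   # g/mL

#' Volume of one structure at one frame
#'
#' Voxel count times the volume per voxel (in-plane spacing product times
#' slice separation), in mL.
#'
#' @param seg a [segmentation_map()].
#' @param structure structure name from the scheme (e.g. `"LV cavity"`).
#' @param frame 1-based frame index.
#' @return volume in mL.
#' @export
chamber_volume <- function(seg, structure, frame) {
  stopifnot(inherits(seg, "segmentation_map"))
  idx <- structure_index(seg$scheme, structure)
  if (is.na(idx)) stop("unknown structure: ", structure)
  d <- dim(seg$labels)
  if (frame < 1L || frame > d[4]) stop("frame out of range")
  vox_ml <- prod(seg$spacing_mm) / 1000
  sum(seg$labels[, , , frame] == idx) * vox_ml
}

#' LV myocardial mass at one frame
#'
#' Myocardial volume times the density 1.05 g/mL.
#'
#' @param seg a [segmentation_map()] whose scheme contains
#'   `"LV myocardium"`.
#' @param frame 1-based frame index.
#' @return mass in grams.
#' @export
lv_mass <- function(seg, frame) {
  if (is.na(structure_index(seg$scheme, "LV myocardium"))) {
    stop("scheme has no LV myocardium class")
  }
  chamber_volume(seg, "LV myocardium", frame) * .myocardium_density
}

#' Locate the ED and ES frames
#'
#' ED is the argmax and ES the argmin of the cavity volume curve (LV cavity
#' for ventricular schemes, LA cavity for atrial views); ties resolve to the
#' earliest frame.
#'
#' @param seg a [segmentation_map()] covering >= 2 frames.
#' @param structure cavity structure to track; default picks `"LV cavity"`
#'   if present, else the first non-background structure.
#' @return list with `ed`, `es` (1-based frame indices) and `volume_ml`
#'   (per-frame curve).
#' @export
ed_es_frames <- function(seg, structure = NULL) {
  d <- dim(seg$labels)
  if (d[4] < 2L) stop("need at least 2 frames")
  structure <- structure %||%
    (if (!is.na(structure_index(seg$scheme, "LV cavity"))) "LV cavity"
     else structures(seg$scheme)[1])
  vol <- vapply(seq_len(d[4]), function(f) chamber_volume(seg, structure, f), 0)
  if (all(vol == 0)) stop("cavity volume curve is identically zero")
  list(ed = which.max(vol), es = which.min(vol), volume_ml = vol)
}

#' Full clinical measures report for one subject
#'
#' Computes LVEDV/LVESV/LVM (and RVEDV/RVESV when the scheme has an RV
#' class) plus the derived stroke volume `SV = EDV - ESV`, ejection fraction
#' `EF = 100 * SV / EDV` (%), and cardiac output
#' `CO = SV * (60 / cycle_s) / 1000` (L/min) where the cycle length is
#' `frames * frame_interval_ms / 1000` seconds. LV mass is evaluated at ED.
#'
#' @param seg a [segmentation_map()] segmented over the cardiac cycle.
#' @param frame_interval_ms overrides the map's frame interval if given.
#' @param heart_rate_bpm optional explicit heart rate, used for CO when no
#'   temporal metadata is available.
#' @return object of class `clinical_measures` (a named list); see
#'   [as.data.frame.clinical_measures()] for the flat CSV layout.
#' @export
measures_report <- function(seg, frame_interval_ms = NULL,
                            heart_rate_bpm = NULL) {
  stopifnot(inherits(seg, "segmentation_map"))
  d <- dim(seg$labels)
  fi <- frame_interval_ms %||% seg$frame_interval_ms
  ee <- ed_es_frames(seg)
  has_lv <- !is.na(structure_index(seg$scheme, "LV cavity"))
  cavity <- if (has_lv) "LV cavity" else structures(seg$scheme)[1]
  edv <- chamber_volume(seg, cavity, ee$ed)
  esv <- chamber_volume(seg, cavity, ee$es)
  sv <- edv - esv
  ef <- if (edv > 0) 100 * sv / edv else NA_real_
  hr <- if (!is.null(heart_rate_bpm)) heart_rate_bpm
        else if (!is.na(fi)) 60 / (d[4] * fi / 1000) else NA_real_
  co <- if (!is.na(hr)) sv * hr / 1000 else NA_real_
  m <- list(LVEDV_mL = edv, LVESV_mL = esv, LVSV_mL = sv, LVEF_pct = ef,
            LVCO_Lmin = co, ed_frame = ee$ed, es_frame = ee$es,
            heart_rate_bpm = hr)
  if (!is.na(structure_index(seg$scheme, "LV myocardium"))) {
    m$LVM_g <- lv_mass(seg, ee$ed)
  }
  if (!is.na(structure_index(seg$scheme, "RV cavity"))) {
    rvedv <- chamber_volume(seg, "RV cavity", ee$ed)
    rvesv <- chamber_volume(seg, "RV cavity", ee$es)
    m$RVEDV_mL <- rvedv; m$RVESV_mL <- rvesv
    m$RVSV_mL <- rvedv - rvesv
    m$RVEF_pct <- if (rvedv > 0) 100 * m$RVSV_mL / rvedv else NA_real_
    m$RVCO_Lmin <- if (!is.na(hr)) m$RVSV_mL * hr / 1000 else NA_real_
  }
  structure(m, class = "clinical_measures")
}

#' @export
print.clinical_measures <- function(x, ...) {
  cat("<clinical_measures>\n")
  for (nm in names(x)) {
    if (is.na(x[[nm]])) next
    cat(sprintf("  %-14s %.2f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Flatten clinical measures to a one-row data frame
#'
#' Columns (where defined): `LVEDV_mL, LVESV_mL, LVM_g, RVEDV_mL, RVESV_mL,
#' LVSV_mL, LVEF_pct, LVCO_Lmin, RVSV_mL, RVEF_pct, RVCO_Lmin`.
#'
#' @param x a `clinical_measures` object.
#' @param ... unused.
#' @export
as.data.frame.clinical_measures <- function(x, ...) {
  cols <- c("LVEDV_mL", "LVESV_mL", "LVM_g", "RVEDV_mL", "RVESV_mL",
            "LVSV_mL", "LVEF_pct", "LVCO_Lmin", "RVSV_mL", "RVEF_pct",
            "RVCO_Lmin")
  vals <- lapply(cols, function(nm) if (is.null(x[[nm]])) NA_real_ else x[[nm]])
  names(vals) <- cols
  as.data.frame(vals)
}
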