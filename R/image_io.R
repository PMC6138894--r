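#' Label schemes for cardiac views
#'
#' Integer label coding used throughout the package. Index 0 is always
#' background; the remaining indices follow anatomical order. The short-axis
#' scheme has 4 classes (background, LV cavity, LV myocardium, RV cavity),
#' the long-axis 2-chamber scheme 2 (background, LA cavity) and the
#' long-axis 4-chamber scheme 3 (background, LA cavity, RA cavity). A reduced
#' LV-only short-axis scheme (`"sa_lv"`) is provided for fine-tuning to
#' datasets that annotate only the left ventricle.
#'
#' @param view one of `"short_axis"`/`"sa"`, `"long_axis_2ch"`/`"2ch"`,
#'   `"long_axis_4ch"`/`"4ch"`, or `"sa_lv"`.
#' @return an object of class `label_scheme` with fields `view` and `labels`
#'   (character vector; `labels[i]` names integer label `i - 1`).
#' @export
#' @examples
#' label_scheme("sa")
label_scheme <- function(view) {
  view <- switch(view,
    sa = , short_axis = "short_axis",
    "2ch" = , long_axis_2ch = "long_axis_2ch",
    "4ch" = , long_axis_4ch = "long_axis_4ch",
    sa_lv = "sa_lv",
    stop("unknown view: ", view))
  labels <- switch(view,
    short_axis    = c("background", "LV cavity", "LV myocardium", "RV cavity"),
    long_axis_2ch = c("background", "LA cavity"),
    long_axis_4ch = c("background", "LA cavity", "RA cavity"),
    sa_lv         = c("background", "LV cavity", "LV myocardium"))
  structure(list(view = view, labels = labels), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme>", x$view, "\n")
  for (i in seq_along(x$labels)) cat(sprintf("  %d: %s\n", i - 1L, x$labels[i]))
  invisible(x)
}

#' Number of label classes in a scheme
#' @param scheme a `label_scheme`.
#' @export
n_classes <- function(scheme) length(scheme$labels)

#' Non-background structure names of a scheme
#' @param scheme a `label_scheme`.
#' @export
structures <- function(scheme) scheme$labels[-1]

#' Integer label index of a structure name (0-based), or NA if absent
#' @keywords internal
structure_index <- function(scheme, name) {
  i <- match(name, scheme$labels)
  if (is.na(i)) NA_integer_ else i - 1L
}

#' Construct a cine CMR stack
#'
#' The unit of analysis: a real-valued 4D intensity array indexed
#' (row, col, slice, frame) with physical voxel spacing in mm, the frame
#' interval in ms and a view tag. 2D/3D input arrays are promoted to 4D.
#'
#' @param voxels numeric array, 2D (row, col), 3D (row, col, slice) or 4D
#'   (row, col, slice, frame).
#' @param spacing_mm length-3 positive numeric: in-plane row and column pixel
#'   spacing and the slice separation (slice thickness plus gap), all in mm.
#' @param frame_interval_ms time between frames in ms, or `NA` if unknown.
#' @param view view tag as accepted by [label_scheme()].
#' @return object of class `cine_stack`.
#' @export
cine_stack <- function(voxels, spacing_mm = c(1.8, 1.8, 10),
                       frame_interval_ms = NA_real_, view = "short_axis") {
  view <- label_scheme(view)$view
  d <- dim(voxels)
  if (is.null(d)) stop("voxels must be an array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("voxels must be 2D, 3D or 4D")
  voxels <- array(as.double(voxels), dim = d)
  if (!all(is.finite(voxels))) stop("intensities must be finite")
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive values")
  }
  if (startsWith(view, "long_axis") && d[3] != 1L) {
    stop("long-axis views must have exactly 1 slice")
  }
  if (!is.na(frame_interval_ms) && frame_interval_ms <= 0) {
    stop("frame_interval_ms must be positive")
  }
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 frame_interval_ms = as.double(frame_interval_ms), view = view),
            class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cine_stack> %s  %dx%d, %d slice(s), %d frame(s)\n",
              x$view, d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.2f x %.2f x %.2f mm, frame interval %s ms\n",
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              format(x$frame_interval_ms)))
  invisible(x)
}

#' Construct a segmentation map
#'
#' Integer label map on a cine-stack grid under a view-specific label scheme.
#'
#' @param labels integer array (promoted to 4D like [cine_stack()]); every
#'   value must be a valid 0-based index into `scheme`.
#' @param scheme a [label_scheme()].
#' @param spacing_mm,frame_interval_ms geometry copied from the parent stack.
#' @return object of class `segmentation_map`.
#' @export
segmentation_map <- function(labels, scheme, spacing_mm = c(1.8, 1.8, 10),
                             frame_interval_ms = NA_real_) {
  stopifnot(inherits(scheme, "label_scheme"))
  d <- dim(labels)
  if (is.null(d)) stop("labels must be an array")
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("labels must be 2D, 3D or 4D")
  labels <- array(as.integer(labels), dim = d)
  K <- n_classes(scheme)
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] >= K) {
    stop("labels contain values outside the scheme (0..", K - 1L, ")")
  }
  structure(list(labels = labels, scheme = scheme,
                 spacing_mm = as.double(spacing_mm),
                 frame_interval_ms = as.double(frame_interval_ms)),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<segmentation_map> %s scheme, %dx%d, %d slice(s), %d frame(s)\n",
              x$scheme$view, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Load a cine stack from NIfTI
#'
#' Voxel spacing is read from `pixdim[1:3]` and the frame interval from the
#' temporal `pixdim` (converted to ms). A missing temporal spacing yields
#' `frame_interval_ms = NA` with a warning.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param view view tag (not stored in NIfTI); default `"short_axis"`.
#' @return a [cine_stack()].
#' @export
load_cine <- function(path, view = "short_axis") {
  nii <- read_nifti(path)
  d <- dim(nii$data)
  sp <- nii$pixdim[1:min(3, length(d))]
  if (length(sp) < 3) sp <- c(sp, rep(1, 3 - length(sp)))
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  if (length(d) >= 4L && is.na(nii$time_ms)) {
    warning("no temporal spacing in NIfTI header; frame_interval_ms unset")
  }
  cine_stack(nii$data, spacing_mm = sp, frame_interval_ms = nii$time_ms,
             view = view)
}

#' Save a cine stack to NIfTI
#' @param stack a [cine_stack()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
save_cine <- function(stack, path) {
  write_nifti(stack$voxels, path,
              pixdim = c(stack$spacing_mm,
                         if (!is.na(stack$frame_interval_ms)) stack$frame_interval_ms),
              datatype = "float64")
}

#' Save / load a segmentation map (NIfTI + JSON sidecar)
#'
#' Labels are stored as an unsigned 8-bit NIfTI volume; the label scheme is
#' recorded in a sidecar `<path>.json` so the map is self-describing.
#'
#' @param seg a [segmentation_map()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
save_segmentation <- function(seg, path) {
  write_nifti(seg$labels, path,
              pixdim = c(seg$spacing_mm,
                         if (!is.na(seg$frame_interval_ms)) seg$frame_interval_ms),
              datatype = "uint8")
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".scheme.json")
  jsonlite::write_json(list(view = seg$scheme$view, labels = seg$scheme$labels),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_segmentation
#' @param scheme optional [label_scheme()]; if `NULL`, read from the sidecar.
#' @export
load_segmentation <- function(path, scheme = NULL) {
  if (is.null(scheme)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".scheme.json")
    if (!file.exists(sidecar)) stop("no scheme given and no sidecar found: ", sidecar)
    scheme <- label_scheme(jsonlite::read_json(sidecar)$view)
  }
  nii <- read_nifti(path)
  sp <- nii$pixdim[1:3]
  segmentation_map(nii$data, scheme, spacing_mm = sp,
                   frame_interval_ms = nii$time_ms)
}

# Per-dimension crop/pad bookkeeping: source window in the original image and
# destination window in the fixed-size output.
.crop_plan <- function(orig, size, offset = 0L) {
  if (orig >= size) {
    src0 <- (orig - size) %/% 2L + 1L + offset
    src0 <- max(1L, min(src0, orig - size + 1L))
    list(src = c(src0, src0 + size - 1L), dst = c(1L, size))
  } else {
    dst0 <- (size - orig) %/% 2L + 1L
    list(src = c(1L, orig), dst = c(dst0, dst0 + orig - 1L))
  }
}

#' Preprocess a cine stack for the network
#'
#' Each 2D slice/frame plane is centre-cropped (when larger) or symmetrically
#' zero-padded (when smaller) to `size` x `size`, then min-max normalised to
#' the range \[0, 1\] per plane; constant planes map to all zeros. The
#' geometric step is exactly invertible via the returned `crop_record`.
#'
#' @param stack a [cine_stack()].
#' @param size output side length in pixels (default 192).
#' @param offset optional (row, col) crop-centre offset in pixels.
#' @return list with `x` (array `size` x `size` x slices x frames) and
#'   `record` (a `crop_record`).
#' @export
preprocess <- function(stack, size = 192L, offset = c(0L, 0L)) {
  v <- stack$voxels
  d <- dim(v)
  pr <- .crop_plan(d[1], size, as.integer(offset[1]))
  pc <- .crop_plan(d[2], size, as.integer(offset[2]))
  out <- array(0, dim = c(size, size, d[3], d[4]))
  # normalise the cropped window before zero-padding, so constant content
  # maps to zeros and non-constant content attains exactly 0 and 1
  for (f in seq_len(d[4])) {
    for (s in seq_len(d[3])) {
      win <- v[pr$src[1]:pr$src[2], pc$src[1]:pc$src[2], s, f]
      lo <- min(win); hi <- max(win)
      out[pr$dst[1]:pr$dst[2], pc$dst[1]:pc$dst[2], s, f] <-
        if (hi > lo) (win - lo) / (hi - lo) else 0
    }
  }
  record <- structure(list(orig_shape = d, size = as.integer(size),
                           src_row = pr$src, src_col = pc$src,
                           dst_row = pr$dst, dst_col = pc$dst),
                      class = "crop_record")
  list(x = out, record = record)
}

#' Restore a 192-grid label map to the original geometry
#'
#' Inverts the crop/pad of [preprocess()]: labels inside the window are copied
#' back to their original position, everything outside is background (0).
#'
#' @param labels integer array on the preprocessed grid
#'   (`size` x `size` x slices x frames), or a [segmentation_map()] on it.
#' @param record the `crop_record` returned by [preprocess()].
#' @return object of the same kind as `labels`, on the original grid.
#' @export
restore_geometry <- function(labels, record) {
  is_seg <- inherits(labels, "segmentation_map")
  lab <- if (is_seg) labels$labels else labels
  d <- dim(lab)
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  lab <- array(lab, dim = d)
  if (d[1] != record$size || d[2] != record$size) {
    stop("label grid does not match the crop record (expected ",
         record$size, "x", record$size, ")")
  }
  od <- record$orig_shape
  if (d[3] != od[3] || d[4] != od[4]) stop("slice/frame count does not match the crop record")
  out <- array(0L, dim = od)
  out[record$src_row[1]:record$src_row[2], record$src_col[1]:record$src_col[2], , ] <-
    lab[record$dst_row[1]:record$dst_row[2], record$dst_col[1]:record$dst_col[2], , , drop = FALSE]
  if (is_seg) {
    segmentation_map(out, labels$scheme, spacing_mm = labels$spacing_mm,
                     frame_interval_ms = labels$frame_interval_ms)
  } else out
}
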