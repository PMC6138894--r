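#' Parameters of the synthetic cine phantom
#'
#' The phantom emulates a UK-Biobank-like short-axis acquisition: ~10 slices
#' of 1.8 x 1.8 mm in-plane resolution with 10 mm slice separation
#' (8 mm thickness + 2 mm gap) and 50 frames per cardiac cycle, with a bright
#' blood pool and mid-grey myocardium. The left ventricle is a cylinder of
#' contracting endocardial radius r(t) surrounded by a fixed-thickness
#' myocardial annulus; the right ventricle is a crescent adjacent to the LV.
#' r(t) follows a cosine between its end-diastolic (frame 1) and end-systolic
#' (frame frames/2 + 1) values, the latter chosen so the analytic
#' cavity-volume curve attains the requested ejection fraction. Long-axis
#' views are single-slice elliptical atrium variants.
#'
#' Defaults are the package's stated world: r_endo 21 mm at ED (analytic
#' LVEDV ~139 mL, within the normal range), 8 mm wall, EF target 0.60,
#' 20 ms frame interval (1 s cycle), intensity levels 0.2/0.5/0.9 for
#' background/myocardium/blood.
#'
#' @param rows,cols,slices,frames grid shape; `frames >= 2`.
#' @param spacing_mm (row, col, slice-separation) spacing in mm.
#' @param frame_interval_ms time between frames in ms.
#' @param view phantom view; `"short_axis"`, `"long_axis_2ch"` or
#'   `"long_axis_4ch"` (long-axis views force `slices = 1`).
#' @param r_endo_mm LV endocardial radius at ED, mm.
#' @param wall_thickness_mm myocardial thickness, mm.
#' @param ef_target generative ejection fraction in (0, 1).
#' @param rv_offset_mm,rv_radius_mm RV crescent: centre offset from the LV
#'   centre (along -col) and disk radius, mm.
#' @param la_axes_mm,ra_axes_mm atrial ellipse semi-axes for long-axis views.
#' @param intensity named levels for `background`, `myocardium`, `blood`.
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param noise_sd additive Gaussian noise sd (0 disables).
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(rows = 192L, cols = 192L, slices = 10L, frames = 50L,
                           spacing_mm = c(1.8, 1.8, 10), frame_interval_ms = 20,
                           view = "short_axis",
                           r_endo_mm = 21, wall_thickness_mm = 8,
                           ef_target = 0.6,
                           rv_offset_mm = 33, rv_radius_mm = 30,
                           la_axes_mm = c(28, 20), ra_axes_mm = c(25, 18),
                           intensity = c(background = 0.2, myocardium = 0.5,
                                         blood = 0.9),
                           blur_sigma_px = 0.8, noise_sd = 0.05, seed = 1L) {
  view <- label_scheme(view)$view
  if (startsWith(view, "long_axis")) slices <- 1L
  p <- list(rows = as.integer(rows), cols = as.integer(cols),
            slices = as.integer(slices), frames = as.integer(frames),
            spacing_mm = as.double(spacing_mm),
            frame_interval_ms = as.double(frame_interval_ms), view = view,
            r_endo_mm = r_endo_mm, wall_thickness_mm = wall_thickness_mm,
            ef_target = ef_target, rv_offset_mm = rv_offset_mm,
            rv_radius_mm = rv_radius_mm, la_axes_mm = la_axes_mm,
            ra_axes_mm = ra_axes_mm, intensity = intensity,
            blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
            seed = as.integer(seed))
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$frames < 2L) stop("frames must be >= 2")
  if (p$r_endo_mm <= 0 || p$wall_thickness_mm <= 0) stop("radii and thickness must be positive")
  if (p$ef_target <= 0 || p$ef_target >= 1) stop("ef_target must be in (0, 1)")
  half_r <- p$rows / 2 * p$spacing_mm[1]
  half_c <- p$cols / 2 * p$spacing_mm[2]
  if (p$view == "short_axis") {
    r_epi <- p$r_endo_mm + p$wall_thickness_mm
    if (r_epi >= min(half_r, half_c)) stop("LV exceeds the grid")
    if (p$rv_offset_mm + p$rv_radius_mm >= 2 * half_c * 0.95) stop("RV exceeds the grid")
  } else {
    if (max(p$la_axes_mm) >= min(half_r, half_c)) stop("atrium exceeds the grid")
  }
  invisible(p)
}

# Cosine radial scale: 1 at frame 1 (ED), s_es at frame frames/2 + 1 (ES).
.radial_scale <- function(p, frame) {
  s_es <- sqrt(1 - p$ef_target)
  phase <- 2 * pi * (frame - 1) / p$frames
  s_es + (1 - s_es) * (1 + cos(phase)) / 2
}

#' Analytic LV cavity volume of the continuous phantom
#'
#' Closed-form volume of the generative geometry at one frame: disk (or
#' ellipse) area times slice count times slice separation, in mL. This is the
#' oracle against which voxel-counted volumes are checked.
#'
#' @param params a [phantom_params()].
#' @param frame 1-based frame index.
#' @return volume in mL.
#' @export
analytic_lv_volume <- function(params, frame) {
  if (any(frame < 1L | frame > params$frames)) stop("frame out of range")
  s <- .radial_scale(params, frame)
  area_mm2 <- if (params$view == "short_axis") {
    pi * (params$r_endo_mm * s)^2
  } else {
    pi * (params$la_axes_mm[1] * s) * (params$la_axes_mm[2] * s)
  }
  area_mm2 * params$slices * params$spacing_mm[3] / 1000
}

# Separable Gaussian blur with replicated edges; sigma in pixels.
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(x) {   # along rows
    n <- nrow(x)
    out <- 0
    for (s in -r:r) {
      idx <- pmin(pmax(seq_len(n) + s, 1L), n)
      out <- out + k[s + r + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

# One frame's 2D truth label plane for the given parameters.
.phantom_plane <- function(p, frame) {
  s <- .radial_scale(p, frame)
  y <- (seq_len(p$rows) - (p$rows + 1) / 2) * p$spacing_mm[1]
  x <- (seq_len(p$cols) - (p$cols + 1) / 2) * p$spacing_mm[2]
  Y <- matrix(y, p$rows, p$cols)
  X <- matrix(x, p$rows, p$cols, byrow = TRUE)
  lab <- matrix(0L, p$rows, p$cols)
  if (p$view == "short_axis") {
    d_lv <- sqrt(Y^2 + X^2)
    r_en <- p$r_endo_mm * s
    r_ep <- r_en + p$wall_thickness_mm
    d_rv <- sqrt(Y^2 + (X + p$rv_offset_mm)^2)
    lab[d_rv < p$rv_radius_mm * s & d_lv >= r_ep] <- 3L
    lab[d_lv < r_ep] <- 2L
    lab[d_lv < r_en] <- 1L
  } else {
    # Atrial ellipse(s); 4Ch adds a second (right atrial) ellipse.
    in_ell <- function(cy, cx, a, b) ((Y - cy) / (a * s))^2 + ((X - cx) / (b * s))^2 < 1
    lab[in_ell(0, if (p$view == "long_axis_4ch") -p$la_axes_mm[2] * 0.8 else 0,
               p$la_axes_mm[1], p$la_axes_mm[2])] <- 1L
    if (p$view == "long_axis_4ch") {
      lab[in_ell(0, p$ra_axes_mm[2] * 1.1, p$ra_axes_mm[1], p$ra_axes_mm[2]) &
            lab == 0L] <- 2L
    }
  }
  lab
}

#' Generate a synthetic cine phantom case
#'
#' Builds the image stack, its exact ground-truth segmentation, the analytic
#' LV (or LA) cavity volume curve, and the analytic ED/ES frame indices.
#' Intensities are assigned per tissue level, blurred, then corrupted with
#' additive Gaussian noise; with both sigmas zero the image is
#' piecewise-constant and its level sets equal the truth regions. Identical
#' seeds give bit-identical cases.
#'
#' @param params a [phantom_params()].
#' @return object of class `phantom_case`: list with `stack` ([cine_stack()]),
#'   `truth` ([segmentation_map()]), `analytic_volume_ml` (per-frame),
#'   `ed_frame`, `es_frame` and `params`.
#' @export
generate_phantom <- function(params) {
  p <- validate_phantom_params(params)
  scheme <- label_scheme(p$view)
  set.seed(p$seed)
  lab <- array(0L, dim = c(p$rows, p$cols, p$slices, p$frames))
  img <- array(0, dim = c(p$rows, p$cols, p$slices, p$frames))
  lv_levels <- c(p$intensity[["background"]], p$intensity[["blood"]],
                 p$intensity[["myocardium"]], p$intensity[["blood"]])
  for (f in seq_len(p$frames)) {
    plane <- .phantom_plane(p, f)
    base <- matrix(lv_levels[plane + 1L], p$rows, p$cols)
    base <- .gauss_blur(base, p$blur_sigma_px)
    for (z in seq_len(p$slices)) {
      lab[, , z, f] <- plane
      img[, , z, f] <- base
    }
  }
  if (p$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = p$noise_sd), dim = dim(img))
  }
  vol <- analytic_lv_volume(p, seq_len(p$frames))
  structure(list(
    stack = cine_stack(img, spacing_mm = p$spacing_mm,
                       frame_interval_ms = p$frame_interval_ms, view = p$view),
    truth = segmentation_map(lab, scheme, spacing_mm = p$spacing_mm,
                             frame_interval_ms = p$frame_interval_ms),
    analytic_volume_ml = vol,
    ed_frame = which.max(vol), es_frame = which.min(vol),
    params = p), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s, EF target %.2f, ED frame %d (%.1f mL), ES frame %d (%.1f mL)\n",
              x$params$view, x$params$ef_target,
              x$ed_frame, x$analytic_volume_ml[x$ed_frame],
              x$es_frame, x$analytic_volume_ml[x$es_frame]))
  invisible(x)
}

#' Simulate a human observer's segmentation
#'
#' Perturbs structure boundaries with a smooth random displacement field of
#' root-mean-square amplitude `jitter_mm`: a coarse grid of i.i.d. Gaussian
#' displacements is bilinearly upsampled to the image grid, scaled to the
#' requested RMS, and the label map is warped by nearest-neighbour sampling.
#' Small smooth fields preserve each structure's topology; `jitter_mm = 0`
#' returns the input unchanged.
#'
#' @param truth a [segmentation_map()].
#' @param jitter_mm RMS boundary displacement in mm (>= 0).
#' @param seed RNG seed.
#' @param knots coarse-grid side for the displacement field.
#' @return a [segmentation_map()] on the same grid and scheme.
#' @export
simulate_observer <- function(truth, jitter_mm, seed = 1L, knots = 6L) {
  stopifnot(inherits(truth, "segmentation_map"), jitter_mm >= 0)
  if (jitter_mm == 0) return(truth)
  d <- dim(truth$labels)
  set.seed(seed)
  upsample <- function(coarse, n1, n2) {
    # bilinear interpolation of a knots x knots grid onto an n1 x n2 grid
    pos <- seq(1, nrow(coarse), length.out = n1)
    i0 <- pmin(floor(pos), nrow(coarse) - 1L); w <- pos - i0
    rowi <- coarse[i0, , drop = FALSE] * (1 - w) + coarse[i0 + 1L, , drop = FALSE] * w
    pos2 <- seq(1, ncol(coarse), length.out = n2)
    j0 <- pmin(floor(pos2), ncol(coarse) - 1L); w2 <- pos2 - j0
    t(t(rowi[, j0, drop = FALSE]) * (1 - w2) + t(rowi[, j0 + 1L, drop = FALSE]) * w2)
  }
  dy <- upsample(matrix(stats::rnorm(knots^2), knots, knots), d[1], d[2])
  dx <- upsample(matrix(stats::rnorm(knots^2), knots, knots), d[1], d[2])
  rms <- sqrt(mean(dy^2 + dx^2))
  dy <- dy / rms * jitter_mm / truth$spacing_mm[1]   # mm -> pixels
  dx <- dx / rms * jitter_mm / truth$spacing_mm[2]
  I <- matrix(seq_len(d[1]), d[1], d[2])
  J <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  si <- pmin(pmax(round(I + dy), 1L), d[1])
  sj <- pmin(pmax(round(J + dx), 1L), d[2])
  flat <- cbind(as.vector(si), as.vector(sj))
  out <- truth$labels
  for (f in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pl <- truth$labels[, , z, f]
      out[, , z, f] <- matrix(pl[flat], d[1], d[2])
    }
  }
  segmentation_map(out, truth$scheme, spacing_mm = truth$spacing_mm,
                   frame_interval_ms = truth$frame_interval_ms)
}
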