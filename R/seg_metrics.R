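#' Segmentation agreement metrics
#'
#' The three metrics used to compare an automated segmentation A against a
#' manual segmentation B: the Dice overlap `2|A n B| / (|A| + |B|)`, the
#' symmetric mean contour distance, and the Hausdorff distance, the latter
#' two computed between the segmentation contours in physical units (mm).
#'
#' @name seg-metrics
NULL

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`: 1 denotes perfect agreement, 0 no overlap.
#' When both masks are empty the metric is undefined and `NA` is returned
#' (callers exclude such cases from aggregates).
#'
#' @param A,B logical/0-1 arrays on the same grid.
#' @return numeric in \[0, 1\], or `NA` if both masks are empty.
#' @export
dice <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("masks must be on the same grid")
  a <- sum(A != 0); b <- sum(B != 0)
  if (a + b == 0) return(NA_real_)
  2 * sum(A != 0 & B != 0) / (a + b)
}

#' Extract the contour of a 2D binary mask
#'
#' Boundary pixels under 4-connectivity: mask pixels with at least one
#' 4-neighbour outside the mask (pixels beyond the grid count as outside).
#' Pixel centres are scaled to mm by the in-plane spacing.
#'
#' @param mask logical/0-1 matrix.
#' @param spacing_mm length-2 in-plane (row, col) spacing in mm.
#' @return object of class `contour`: list with `points` (n x 2 matrix of mm
#'   coordinates) and `n`.
#' @export
extract_contour <- function(mask, spacing_mm = c(1, 1)) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  boundary <- mask & !inner
  idx <- which(boundary, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * spacing_mm[1], idx[, 2] * spacing_mm[2])
  structure(list(points = pts, n = nrow(pts)), class = "contour")
}

# all-pairs squared distances between two mm point sets
.pair_dists <- function(P, Q) {
  d2 <- outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2
  sqrt(d2)
}

#' Mean contour distance in mm
#'
#' Symmetric mean of point-to-contour distances:
#' `1/(2|dA|) sum_{p in dA} d(p, dB) + 1/(2|dB|) sum_{q in dB} d(q, dA)`
#' with Euclidean point-to-set distances.
#'
#' @param cA,cB [extract_contour()] results (both nonempty).
#' @return distance in mm, or `NA` if either contour is empty.
#' @export
mean_contour_distance <- function(cA, cB) {
  if (cA$n == 0L || cB$n == 0L) return(NA_real_)
  D <- .pair_dists(cA$points, cB$points)
  mean(apply(D, 1L, min)) / 2 + mean(apply(D, 2L, min)) / 2
}

#' Hausdorff distance in mm
#'
#' `max(max_{p in dA} d(p, dB), max_{q in dB} d(q, dA))`.
#'
#' @param cA,cB [extract_contour()] results (both nonempty).
#' @return distance in mm, or `NA` if either contour is empty.
#' @export
hausdorff_distance <- function(cA, cB) {
  if (cA$n == 0L || cB$n == 0L) return(NA_real_)
  D <- .pair_dists(cA$points, cB$points)
  max(max(apply(D, 1L, min)), max(apply(D, 2L, min)))
}

#' Per-structure agreement metrics for one case
#'
#' For every non-background structure of the shared scheme: the Dice metric
#' on the pooled 3D voxel sets of all annotated frames (frames where the
#' manual map has any non-background label), and the contour distances
#' computed in-plane per 2D slice where the structure is present in both
#' maps — the mean contour distance averaged and the Hausdorff distance
#' maximised over contributing slices. Planes where the structure is missing
#' from either map are excluded; `n_slices` counts the contributing planes.
#'
#' @param auto,manual [segmentation_map()]s on the same grid and scheme.
#' @param dice_mode `"3d"` (pooled voxels, default) or `"2d"` (per-slice
#'   average).
#' @return a `data.frame` with columns `structure`, `dice`, `mcd_mm`,
#'   `hd_mm`, `n_slices`.
#' @export
evaluate_case <- function(auto, manual, dice_mode = c("3d", "2d")) {
  dice_mode <- match.arg(dice_mode)
  stopifnot(inherits(auto, "segmentation_map"), inherits(manual, "segmentation_map"))
  if (!identical(dim(auto$labels), dim(manual$labels))) {
    stop("segmentations must be on the same grid")
  }
  if (!identical(auto$scheme$labels, manual$scheme$labels)) {
    stop("segmentations must share a label scheme")
  }
  d <- dim(auto$labels)
  annotated <- which(vapply(seq_len(d[4]),
                            function(f) any(manual$labels[, , , f] > 0L), TRUE))
  if (!length(annotated)) stop("no annotated frames in the manual segmentation")
  sp <- auto$spacing_mm[1:2]
  scheme <- auto$scheme
  res <- lapply(seq_along(structures(scheme)), function(s) {
    A <- auto$labels[, , , annotated, drop = FALSE] == s
    B <- manual$labels[, , , annotated, drop = FALSE] == s
    mcds <- c(); hds <- c(); dices2d <- c()
    n_sl <- 0L
    for (fi in seq_along(annotated)) for (z in seq_len(d[3])) {
      a2 <- A[, , z, fi]; b2 <- B[, , z, fi]
      if (dice_mode == "2d" && (any(a2) || any(b2))) {
        dices2d <- c(dices2d, dice(a2, b2))
      }
      if (!any(a2) || !any(b2)) next
      ca <- extract_contour(a2, sp); cb <- extract_contour(b2, sp)
      mcds <- c(mcds, mean_contour_distance(ca, cb))
      hds <- c(hds, hausdorff_distance(ca, cb))
      n_sl <- n_sl + 1L
    }
    dval <- if (dice_mode == "3d") dice(A, B)
            else if (length(dices2d)) mean(dices2d) else NA_real_
    data.frame(structure = structures(scheme)[s],
               dice = dval,
               mcd_mm = if (n_sl) mean(mcds) else NA_real_,
               hd_mm = if (n_sl) max(hds) else NA_real_,
               n_slices = n_sl, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
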