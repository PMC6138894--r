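#' Segment a full cine stack
#'
#' Each requested frame's slices are preprocessed to the network input size,
#' forwarded, assigned per pixel to the class with the highest softmax
#' probability (ties broken toward the lowest label index), and restored to
#' the original geometry. Frames not requested are filled with background.
#'
#' @param net a trained `fcn_network` whose `K` matches the view's scheme.
#' @param stack a [cine_stack()].
#' @param scheme the [label_scheme()] of the view; defaults to the stack's
#'   view tag.
#' @param frames `"all"` or an integer vector of 1-based frame indices.
#' @param keep_largest if `TRUE`, keep only the largest 4-connected component
#'   of each structure per 2D plane (off by default; the method applies no
#'   post-processing).
#' @return a [segmentation_map()] on the stack's grid.
#' @export
segment_stack <- function(net, stack, scheme = NULL, frames = "all",
                          keep_largest = FALSE) {
  stopifnot(inherits(net, "fcn_network"), inherits(stack, "cine_stack"))
  scheme <- scheme %||% label_scheme(stack$view)
  if (n_classes(scheme) != net$spec$K) {
    stop("network K (", net$spec$K, ") does not match scheme (",
         n_classes(scheme), " classes)")
  }
  d <- dim(stack$voxels)
  frame_idx <- if (identical(frames, "all")) seq_len(d[4]) else as.integer(frames)
  if (any(frame_idx < 1L | frame_idx > d[4])) stop("frame index out of range")
  pp <- preprocess(stack, size = net$spec$input_size)
  size <- net$spec$input_size
  lab192 <- array(0L, c(size, size, d[3], d[4]))
  for (f in frame_idx) {
    batch <- array(pp$x[, , , f], c(size, size, d[3]))
    r <- .fcn_forward(net, batch, train = FALSE)
    # ties.method = "first" resolves equal probabilities to the lowest index
    cls <- max.col(r$probs, ties.method = "first") - 1L
    lab192[, , , f] <- array(cls, c(size, size, d[3]))
  }
  if (keep_largest) {
    for (f in frame_idx) for (z in seq_len(d[3])) {
      lab192[, , z, f] <- .keep_largest_components(lab192[, , z, f],
                                                   n_classes(scheme) - 1L)
    }
  }
  out <- restore_geometry(lab192, pp$record)
  segmentation_map(out, scheme, spacing_mm = stack$spacing_mm,
                   frame_interval_ms = stack$frame_interval_ms)
}

# Largest 4-connected component per structure, via two-pass label flooding.
.keep_largest_components <- function(plane, n_struct) {
  for (s in seq_len(n_struct)) {
    mask <- plane == s
    if (!any(mask)) next
    comp <- .connected_components(mask)
    sizes <- tabulate(comp[comp > 0L])
    if (length(sizes) > 1L) {
      keep <- which.max(sizes)
      plane[mask & comp != keep] <- 0L
    }
  }
  plane
}

.connected_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  comp <- matrix(0L, H, W)
  cur <- 0L
  todo <- which(mask & comp == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    frontier <- todo[1]
    while (length(frontier)) {
      comp[frontier] <- cur
      i <- (frontier - 1L) %% H + 1L
      j <- (frontier - 1L) %/% H + 1L
      nb <- c(frontier[i > 1L] - 1L, frontier[i < H] + 1L,
              frontier[j > 1L] - H, frontier[j < W] + H)
      nb <- unique(nb)
      frontier <- nb[mask[nb] & comp[nb] == 0L]
    }
    todo <- which(mask & comp == 0L)
  }
  comp
}
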