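#' Training configuration
#'
#' Defaults follow the published training procedure: Adam with learning rate
#' 0.001 for 50,000 iterations on mini-batches of 20 image slices, with
#' on-the-fly random translation, rotation, scaling and intensity variation,
#' and 10,000 iterations for fine-tuning. Augmentation ranges are symmetric
#' about the identity transform.
#'
#' @param learning_rate Adam learning rate.
#' @param iterations number of optimisation steps.
#' @param batch_size slices per mini-batch.
#' @param translation_px maximum absolute translation, pixels.
#' @param rotation_deg maximum absolute rotation, degrees.
#' @param scale_range multiplicative spatial scale interval.
#' @param intensity_scale multiplicative intensity interval.
#' @param intensity_offset maximum absolute additive intensity offset.
#' @param augment enable augmentation.
#' @param fine_tune_iterations steps used by [fine_tune()].
#' @param beta1,beta2,epsilon Adam moment parameters (conventional defaults).
#' @param seed RNG seed for sampling, augmentation and any head re-init.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, iterations = 50000L,
                         batch_size = 20L, translation_px = 15,
                         rotation_deg = 15, scale_range = c(0.9, 1.1),
                         intensity_scale = c(0.9, 1.1),
                         intensity_offset = 0.05, augment = TRUE,
                         fine_tune_iterations = 10000L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = NULL) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  stopifnot(diff(scale_range) >= 0, diff(intensity_scale) >= 0)
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 translation_px = translation_px,
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 intensity_scale = intensity_scale,
                 intensity_offset = intensity_offset, augment = augment,
                 fine_tune_iterations = as.integer(fine_tune_iterations),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = seed), class = "train_config")
}

#' Mean cross-entropy loss
#'
#' Mean over contributing pixels of `-log p(true class)`, the training loss.
#' Pixels whose true structure is listed in `ignore` are excluded from the
#' mean (used when fine-tuning to datasets that do not annotate all
#' structures). Probabilities are clipped below at 1e-12 before the log.
#'
#' @param pred probability array `H x W x K x B` (or a `(N x K)` matrix).
#' @param truth integer label array `H x W x B` (or vector), 0-based indices.
#' @param scheme optional [label_scheme()]; required when `ignore` is given.
#' @param ignore character vector of structure names to exclude.
#' @return object of class `loss_value`: list with `loss` and `n_pixels`.
#' @export
cross_entropy_loss <- function(pred, truth, scheme = NULL, ignore = NULL) {
  if (is.array(pred) && length(dim(pred)) == 4L) {
    d <- dim(pred)
    K <- d[3]
    pm <- matrix(0, d[1] * d[2] * d[4], K)
    for (b in seq_len(d[4])) {
      pm[((b - 1L) * d[1] * d[2] + 1L):(b * d[1] * d[2]), ] <-
        array(pred[, , , b], c(d[1] * d[2], K))
    }
    pred <- pm
  }
  K <- ncol(pred)
  lab <- as.integer(as.vector(if (inherits(truth, "segmentation_map")) truth$labels else truth))
  if (length(lab) != nrow(pred)) stop("prediction and truth shapes do not match")
  if (any(lab < 0L | lab >= K)) stop("truth labels outside 0..K-1")
  keep <- rep(TRUE, length(lab))
  if (!is.null(ignore) && length(ignore)) {
    if (is.null(scheme)) stop("ignore requires a label scheme")
    idx <- vapply(ignore, function(nm) structure_index(scheme, nm), 0L)
    idx <- idx[!is.na(idx)]
    keep <- !(lab %in% idx)
  }
  if (!any(keep)) stop("no contributing pixels (all ignored)")
  p_true <- pred[cbind(which(keep), lab[keep] + 1L)]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  structure(list(loss = loss, n_pixels = sum(keep)), class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> %.6f over %d pixels\n", x$loss, x$n_pixels))
  invisible(x)
}

# Affine resampling of one plane. Bilinear for intensities, nearest-neighbour
# for labels; coordinates outside the source map to `fill`.
.affine_resample <- function(plane, theta, scale, t_r, t_c, nearest, fill = 0) {
  H <- nrow(plane); W <- ncol(plane)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  i <- matrix(seq_len(H), H, W) - cy
  j <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  ct <- cos(theta); st <- sin(theta)
  # inverse map: output pixel -> source pixel
  src_i <- cy + ( ct * (i - t_r) + st * (j - t_c)) / scale
  src_j <- cx + (-st * (i - t_r) + ct * (j - t_c)) / scale
  if (nearest) {
    si <- round(src_i); sj <- round(src_j)
    ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
    out <- matrix(fill, H, W)
    if (is.integer(plane)) storage.mode(out) <- "integer"
    out[ok] <- plane[cbind(si[ok], sj[ok])]
    return(out)
  }
  i0 <- floor(src_i); j0 <- floor(src_j)
  wi <- src_i - i0; wj <- src_j - j0
  out <- matrix(fill, H, W)
  gv <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- matrix(0, H, W)
    v[ok] <- plane[cbind(ii[ok], jj[ok])]
    v
  }
  out <- gv(i0, j0) * (1 - wi) * (1 - wj) + gv(i0 + 1, j0) * wi * (1 - wj) +
    gv(i0, j0 + 1) * (1 - wi) * wj + gv(i0 + 1, j0 + 1) * wi * wj
  out
}

#' On-the-fly mini-batch augmentation
#'
#' Applies an identical random translation/rotation/scaling to each image
#' slice and its label map (bilinear vs nearest-neighbour interpolation) and
#' a random multiplicative/additive intensity change to the image only;
#' images are re-clipped to \[0, 1\]. Draws come from the current RNG state.
#' With all ranges zero the batch is returned unchanged.
#'
#' @param images array `H x W x B` in \[0, 1\].
#' @param labels integer array `H x W x B`.
#' @param cfg a [train_config()] providing the ranges.
#' @return list with augmented `images` and `labels`.
#' @export
augment_batch <- function(images, labels, cfg = train_config()) {
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, c(d, 1L)); labels <- array(labels, c(d, 1L)); d <- dim(images) }
  identity_cfg <- cfg$translation_px == 0 && cfg$rotation_deg == 0 &&
    all(cfg$scale_range == 1) && all(cfg$intensity_scale == 1) &&
    cfg$intensity_offset == 0
  if (identity_cfg) return(list(images = images, labels = labels))
  for (b in seq_len(d[3])) {
    t_r <- stats::runif(1, -cfg$translation_px, cfg$translation_px)
    t_c <- stats::runif(1, -cfg$translation_px, cfg$translation_px)
    theta <- stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
    sc <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    a <- stats::runif(1, cfg$intensity_scale[1], cfg$intensity_scale[2])
    off <- stats::runif(1, -cfg$intensity_offset, cfg$intensity_offset)
    img <- .affine_resample(images[, , b], theta, sc, t_r, t_c, nearest = FALSE)
    images[, , b] <- pmin(pmax(img * a + off, 0), 1)
    labels[, , b] <- .affine_resample(labels[, , b], theta, sc, t_r, t_c,
                                      nearest = TRUE)
  }
  list(images = images, labels = labels)
}

#' Collect annotated 2D training slices from cases
#'
#' A case is a `phantom_case` or a list with elements `stack`
#' ([cine_stack()]) and `truth` ([segmentation_map()]). Images are
#' preprocessed to the network input size; every (slice, frame) plane of an
#' annotated frame (any non-background label) becomes one training slice.
#'
#' @param cases list of cases.
#' @param size network input side.
#' @return list with arrays `images` and `labels` (`size x size x n`) and the
#'   `scheme` shared by the cases.
#' @export
training_slices <- function(cases, size = 192L) {
  if (inherits(cases, "phantom_case")) cases <- list(cases)
  imgs <- list(); labs <- list(); scheme <- NULL
  for (case in cases) {
    stack <- case$stack; seg <- case$truth
    if (is.null(stack) || is.null(seg)) stop("case must provide stack and truth")
    scheme <- scheme %||% seg$scheme
    pp <- preprocess(stack, size = size)
    d <- dim(seg$labels)
    lab192 <- array(0L, c(size, size, d[3], d[4]))
    pr <- pp$record
    lab192[pr$dst_row[1]:pr$dst_row[2], pr$dst_col[1]:pr$dst_col[2], , ] <-
      seg$labels[pr$src_row[1]:pr$src_row[2], pr$src_col[1]:pr$src_col[2], , , drop = FALSE]
    for (f in seq_len(d[4])) {
      if (!any(seg$labels[, , , f] > 0L)) next
      for (z in seq_len(d[3])) {
        imgs[[length(imgs) + 1L]] <- pp$x[, , z, f]
        labs[[length(labs) + 1L]] <- lab192[, , z, f]
      }
    }
  }
  if (!length(imgs)) stop("no annotated slices in the supplied cases")
  n <- length(imgs)
  images <- array(0, c(size, size, n)); labels <- array(0L, c(size, size, n))
  for (i in seq_len(n)) { images[, , i] <- imgs[[i]]; labels[, , i] <- labs[[i]] }
  list(images = images, labels = labels, scheme = scheme)
}

.adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(par, grads, st, cfg) {
  st$t <- st$t + 1L
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^st$t) / (1 - cfg$beta1^st$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * g
    st$v[[nm]] <- cfg$beta2 * st$v[[nm]] + (1 - cfg$beta2) * g * g
    par[[nm]] <- par[[nm]] - lr_t * st$m[[nm]] / (sqrt(st$v[[nm]]) + cfg$epsilon)
  }
  list(par = par, st = st)
}

# One optimisation step shared by train() and fine_tune().
.train_loop <- function(net, pool, cfg, iterations, ignore = NULL,
                        log_file = NULL) {
  n_slices <- dim(pool$images)[3]
  K <- net$spec$K
  opt <- .adam_init(net$par)
  history <- numeric(iterations)
  scheme <- pool$scheme
  ignore_idx <- integer(0)
  if (!is.null(ignore) && length(ignore)) {
    ignore_idx <- vapply(ignore, function(nm) structure_index(scheme, nm), 0L)
    ignore_idx <- ignore_idx[!is.na(ignore_idx)]
  }
  for (it in seq_len(iterations)) {
    idx <- sample.int(n_slices, cfg$batch_size, replace = TRUE)
    imgs <- pool$images[, , idx, drop = FALSE]
    labs <- pool$labels[, , idx, drop = FALSE]
    if (cfg$augment) {
      aug <- augment_batch(imgs, labs, cfg)
      imgs <- aug$images; labs <- aug$labels
    }
    fwd <- .fcn_forward(net, imgs, train = TRUE, want_cache = TRUE)
    net$state <- fwd$state
    lab_vec <- as.integer(as.vector(labs))
    keep <- !(lab_vec %in% ignore_idx) & lab_vec < K
    if (!any(keep)) stop("no contributing pixels in mini-batch")
    n_keep <- sum(keep)
    # clamp labels for indexing; non-keep rows are zeroed out below anyway
    lab_idx <- pmin(lab_vec, K - 1L)
    p_true <- fwd$probs[cbind(seq_along(lab_vec), lab_idx + 1L)]
    loss <- -sum(log(pmax(p_true[keep], 1e-12))) / n_keep
    if (!is.finite(loss)) {
      stop(sprintf("training aborted: non-finite loss at iteration %d", it))
    }
    history[it] <- loss
    dlogits <- fwd$probs
    dlogits[cbind(seq_along(lab_vec), lab_idx + 1L)] <-
      dlogits[cbind(seq_along(lab_vec), lab_idx + 1L)] - 1
    dlogits[!keep, ] <- 0
    dlogits <- dlogits / n_keep
    grads <- .fcn_backward(net, fwd, dlogits)
    upd <- .adam_step(net$par, grads, opt, cfg)
    net$par <- upd$par; opt <- upd$st
    if (!is.null(log_file)) {
      cat(sprintf("%d,%.6f\n", it, loss), file = log_file, append = it > 1L)
    }
  }
  list(net = net, history = history)
}

#' Train the network
#'
#' Runs `cfg$iterations` Adam steps on augmented mini-batches assembled by
#' sampling annotated slices uniformly with replacement. With
#' `cfg$learning_rate = 0` or `cfg$iterations = 0` parameters are unchanged.
#' Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param net an `fcn_network` whose `K` matches the cases' label scheme.
#' @param cases list of cases as for [training_slices()], or the result of
#'   [training_slices()] itself.
#' @param cfg a [train_config()].
#' @param ignore structure names excluded from the loss.
#' @param log_file optional CSV path receiving `iteration,loss` rows.
#' @return list with `net` (trained network) and `history` (per-iteration
#'   loss).
#' @export
train <- function(net, cases, cfg = train_config(), ignore = NULL,
                  log_file = NULL) {
  stopifnot(inherits(net, "fcn_network"))
  pool <- if (is.list(cases) && !is.null(cases$images)) cases
          else training_slices(cases, size = net$spec$input_size)
  if (n_classes(pool$scheme) != net$spec$K && is.null(ignore)) {
    stop("network K (", net$spec$K, ") does not match the label scheme (",
         n_classes(pool$scheme), " classes)")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$iterations == 0L) return(list(net = net, history = numeric(0)))
  .train_loop(net, pool, cfg, cfg$iterations, ignore = ignore,
              log_file = log_file)
}

#' Fine-tune a trained network on a new label scheme
#'
#' Transfer learning to a new dataset: when the new scheme's class count
#' differs, the final 1x1 prediction layer is re-initialised to emit the new
#' K while all other parameters start from the input network. Labels are
#' remapped from each case's scheme to `new_scheme` by structure name;
#' structures absent from `new_scheme` are excluded from the loss. Training
#' then runs for `cfg$fine_tune_iterations` steps.
#'
#' @param net a trained `fcn_network`.
#' @param cases training cases (their truth may use the old, richer scheme).
#' @param new_scheme the target [label_scheme()].
#' @param cfg a [train_config()]; `fine_tune_iterations` sets the schedule.
#' @return list with `net` and `history` as for [train()].
#' @export
fine_tune <- function(net, cases, new_scheme, cfg = train_config()) {
  stopifnot(inherits(net, "fcn_network"), inherits(new_scheme, "label_scheme"))
  K_new <- n_classes(new_scheme)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (K_new != net$spec$K) {
    cin <- net$spec$head_widths[2]
    net$spec$K <- K_new
    net$arch <- .fcn_arch(net$spec)
    net$par[["h3_W"]] <- matrix(stats::rnorm(cin * K_new, sd = sqrt(2 / cin)),
                                cin, K_new)
    net$par[["h3_bias"]] <- rep(0, K_new)
  }
  pool <- training_slices(cases, size = net$spec$input_size)
  old_scheme <- pool$scheme
  # remap labels by structure name; unmappable structures -> ignored
  map <- vapply(old_scheme$labels,
                function(nm) structure_index(new_scheme, nm), 0L)
  ignore <- old_scheme$labels[-1][is.na(map[-1])]
  sentinel <- K_new                 # temporary class for unmappable pixels
  map[is.na(map)] <- sentinel
  pool$labels <- array(map[pool$labels + 1L], dim = dim(pool$labels))
  ext_scheme <- new_scheme
  if (length(ignore)) {
    ext_scheme$labels <- c(new_scheme$labels, "(ignored)")
    pool$scheme <- ext_scheme
    ignore <- "(ignored)"
  } else {
    pool$scheme <- new_scheme
    ignore <- NULL
  }
  if (cfg$fine_tune_iterations == 0L) return(list(net = net, history = numeric(0)))
  r <- .train_loop(net, pool, cfg, cfg$fine_tune_iterations, ignore = ignore)
  r
}
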