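#' Multi-scale fully convolutional segmentation network
#'
#' The architecture learns features at five resolution scales (sides
#' 192/96/48/24/12 for a 192 input) with 3x3 convolutions, each followed by
#' batch normalisation and ReLU, downsampling by a factor of 2 after every
#' two or three convolutions. Every scale's feature map is upsampled back to
#' the finest resolution in a single transposed convolution (scale 1 passes
#' through), all scales are concatenated, and a three-layer 1x1 convolutional
#' head ending in a softmax predicts per-pixel class probabilities over K
#' label classes. The `vgg` variant has 16 convolutional layers excluding the
#' transposed convolutions; the `residual` variant replaces scales 3-5 with
#' identity-skip residual blocks of two 3x3 convolutions for a total of 33.
#'
#' Everything — convolution, batch norm, pooling, transposed convolution,
#' and their gradients — is implemented in this package on top of small
#' im2col/col2im kernels; no external deep-learning runtime is used.
#'
#' @name fcn-network
NULL

.bn_eps <- 1e-5
.bn_momentum <- 0.9

# ---- architecture description -------------------------------------------

.fcn_arch <- function(spec) {
  S <- spec$scales
  body <- vector("list", S)
  for (s in seq_len(S)) {
    cin_scale <- if (s == 1L) 1L else spec$widths[s - 1L]
    if (spec$variant == "residual" && s >= 3L) {
      units <- vector("list", spec$blocks[s])
      for (u in seq_len(spec$blocks[s])) {
        cin <- if (u == 1L) cin_scale else spec$widths[s]
        units[[u]] <- list(kind = "res",
                           prefix = sprintf("b_s%d_u%d", s, u),
                           cin = cin, cout = spec$widths[s],
                           proj = cin != spec$widths[s])
      }
    } else {
      units <- vector("list", spec$conv_counts[s])
      for (u in seq_len(spec$conv_counts[s])) {
        cin <- if (u == 1L) cin_scale else spec$widths[s]
        units[[u]] <- list(kind = "conv",
                           prefix = sprintf("b_s%d_u%d", s, u),
                           kh = 3L, cin = cin, cout = spec$widths[s],
                           bn = TRUE, relu = TRUE)
      }
    }
    body[[s]] <- units
  }
  ups <- vector("list", S)
  if (S > 1L) {
    for (s in 2:S) {
      stride <- 2L^(s - 1L)
      ups[[s]] <- list(kind = "tconv", prefix = sprintf("up_s%d", s),
                       cin = spec$widths[s], cout = spec$up_width,
                       k = 2L * stride, stride = stride, pad = stride %/% 2L)
    }
  }
  concat_width <- spec$widths[1] + (S - 1L) * spec$up_width
  head <- list(
    list(kind = "conv", prefix = "h1", kh = 1L, cin = concat_width,
         cout = spec$head_widths[1], bn = TRUE, relu = TRUE),
    list(kind = "conv", prefix = "h2", kh = 1L, cin = spec$head_widths[1],
         cout = spec$head_widths[2], bn = TRUE, relu = TRUE),
    list(kind = "linear", prefix = "h3", kh = 1L, cin = spec$head_widths[2],
         cout = spec$K))
  list(body = body, ups = ups, head = head)
}

.init_conv <- function(par, state, prefix, kh, cin, cout, bn = TRUE) {
  fan_in <- kh * kh * cin
  par[[paste0(prefix, "_W")]] <-
    matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  if (bn) {
    par[[paste0(prefix, "_g")]] <- rep(1, cout)
    par[[paste0(prefix, "_b")]] <- rep(0, cout)
    state[[paste0(prefix, "_rm")]] <- rep(0, cout)
    state[[paste0(prefix, "_rv")]] <- rep(1, cout)
  }
  list(par = par, state = state)
}

.init_params <- function(arch, spec) {
  par <- list(); state <- list()
  for (units in arch$body) for (d in units) {
    if (d$kind == "conv") {
      r <- .init_conv(par, state, d$prefix, d$kh, d$cin, d$cout)
      par <- r$par; state <- r$state
    } else {                       # residual block
      r <- .init_conv(par, state, paste0(d$prefix, "_c1"), 3L, d$cin, d$cout)
      r <- .init_conv(r$par, r$state, paste0(d$prefix, "_c2"), 3L, d$cout, d$cout)
      par <- r$par; state <- r$state
      if (d$proj) {
        r <- .init_conv(par, state, paste0(d$prefix, "_p"), 1L, d$cin, d$cout)
        par <- r$par; state <- r$state
      }
    }
  }
  for (d in arch$ups) {
    if (is.null(d)) next
    fan <- d$k * d$k * d$cout
    par[[paste0(d$prefix, "_W")]] <-
      matrix(stats::rnorm(fan * d$cin, sd = sqrt(2 / fan)), fan, d$cin)
    par[[paste0(d$prefix, "_bias")]] <- rep(0, d$cout)
  }
  for (d in arch$head) {
    if (d$kind == "conv") {
      r <- .init_conv(par, state, d$prefix, d$kh, d$cin, d$cout)
      par <- r$par; state <- r$state
    } else {
      par[[paste0(d$prefix, "_W")]] <-
        matrix(stats::rnorm(d$cin * d$cout, sd = sqrt(2 / d$cin)), d$cin, d$cout)
      par[[paste0(d$prefix, "_bias")]] <- rep(0, d$cout)
    }
  }
  list(par = par, state = state)
}

#' Build the segmentation network
#'
#' @param K number of label classes (>= 2).
#' @param variant `"vgg"` (16 convolutional layers) or `"residual"` (33).
#' @param scales number of resolution scales (default 5; smaller values give
#'   the reduced networks used for quick experiments).
#' @param widths per-scale feature widths; default `c(16, 32, 64, 128, 256)`
#'   truncated to `scales`.
#' @param conv_counts per-scale convolution counts for the vgg variant;
#'   default `c(2, 2, 3, 3, 3)` truncated to `scales`.
#' @param blocks residual blocks per scale for scales >= 3 in the residual
#'   variant; default `c(0, 0, 4, 4, 5)` (totalling 33 layers with the head).
#' @param head_widths widths of the first two 1x1 head layers, default
#'   `c(64, 64)`; the third emits `K` features.
#' @param up_width channel width each upsampled scale is projected to.
#' @param input_size expected square input side; must be divisible by
#'   `2^(scales - 1)`.
#' @param seed RNG seed for the variance-scaled weight initialisation.
#' @return object of class `fcn_network`.
#' @export
#' @examples
#' net <- build_fcn(4, scales = 2, widths = c(4, 8), head_widths = c(8, 8),
#'                  input_size = 16, seed = 1)
#' count_conv_layers(net)
build_fcn <- function(K, variant = c("vgg", "residual"), scales = 5L,
                      widths = NULL, conv_counts = NULL, blocks = NULL,
                      head_widths = c(64L, 64L), up_width = 16L,
                      input_size = 192L, seed = NULL) {
  variant <- match.arg(variant)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  scales <- as.integer(scales)
  if (is.null(widths)) widths <- c(16L, 32L, 64L, 128L, 256L)[seq_len(scales)]
  if (is.null(conv_counts)) conv_counts <- c(2L, 2L, 3L, 3L, 3L)[seq_len(scales)]
  if (is.null(blocks)) blocks <- c(0L, 0L, 4L, 4L, 5L)[seq_len(scales)]
  if (length(widths) != scales || length(conv_counts) != scales) {
    stop("widths and conv_counts must have one entry per scale")
  }
  if (input_size %% 2L^(scales - 1L) != 0L) {
    stop("input_size must be divisible by 2^(scales - 1)")
  }
  spec <- list(K = K, variant = variant, scales = scales,
               widths = as.integer(widths),
               conv_counts = as.integer(conv_counts),
               blocks = as.integer(blocks),
               head_widths = as.integer(head_widths),
               up_width = as.integer(up_width),
               input_size = as.integer(input_size))
  arch <- .fcn_arch(spec)
  if (!is.null(seed)) set.seed(seed)
  ps <- .init_params(arch, spec)
  structure(list(spec = spec, arch = arch, par = ps$par, state = ps$state),
            class = "fcn_network")
}

#' @export
print.fcn_network <- function(x, ...) {
  cat(sprintf("<fcn_network> %s variant, K = %d, %d scale(s), input %dx%d\n",
              x$spec$variant, x$spec$K, x$spec$scales,
              x$spec$input_size, x$spec$input_size))
  cat(sprintf("  %d convolutional layers, %s parameters\n",
              count_conv_layers(x), format(num_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count convolutional layers
#'
#' Counts all convolutional layers of any kernel size on the main path,
#' excluding transposed convolutions and, in the residual variant, the 1x1
#' projection shortcuts (following the usual residual-network counting
#' convention). The default vgg variant counts 16, the residual variant 33,
#' and the head alone 3.
#'
#' @param net an `fcn_network`.
#' @param part `"all"`, `"body"` or `"head"`.
#' @return integer layer count.
#' @export
count_conv_layers <- function(net, part = c("all", "body", "head")) {
  part <- match.arg(part)
  n_body <- sum(vapply(unlist(net$arch$body, recursive = FALSE), function(d) {
    if (d$kind == "res") 2L else 1L
  }, 0L))
  n_head <- length(net$arch$head)
  switch(part, all = n_body + n_head, body = n_body, head = n_head)
}

#' Total number of learnable parameters
#' @param net an `fcn_network`.
#' @export
num_parameters <- function(net) sum(vapply(net$par, length, 0L))

# ---- forward / backward --------------------------------------------------

# Activations travel as a (B*H*W) x C matrix plus spatial dims; rows of
# sample b are ((b-1)*H*W + 1):(b*H*W), within a sample in R column-major
# plane order, matching matrix(cube, nrow = H*W).

.bn_fwd <- function(Z, g, bta, rm, rv, train) {
  if (train) {
    mu <- colMeans(Z)
    va <- pmax(colMeans(Z * Z) - mu^2, 0)
    new_rm <- .bn_momentum * rm + (1 - .bn_momentum) * mu
    new_rv <- .bn_momentum * rv + (1 - .bn_momentum) * va
  } else {
    mu <- rm; va <- rv; new_rm <- rm; new_rv <- rv
  }
  istd <- 1 / sqrt(va + .bn_eps)
  Zh <- Z; Y <- Z
  for (k in seq_along(mu)) {          # column loops avoid big temporaries
    Zh[, k] <- (Z[, k] - mu[k]) * istd[k]
    Y[, k] <- Zh[, k] * g[k] + bta[k]
  }
  list(Y = Y, Zh = Zh, istd = istd, rm = new_rm, rv = new_rv)
}

.bn_bwd <- function(dY, Zh, istd, g) {
  n <- nrow(dY)
  dg <- colSums(dY * Zh)
  db <- colSums(dY)
  dZ <- dY
  for (k in seq_along(g)) {
    dZ[, k] <- (g[k] * istd[k]) * (dY[, k] - db[k] / n - Zh[, k] * dg[k] / n)
  }
  list(dZ = dZ, dg = dg, db = db)
}

.conv_fwd <- function(d, prefix, net, a, train, state_env) {
  W <- net$par[[paste0(prefix, "_W")]]
  if (d$kh == 1L) {
    cols <- NULL
    Z <- a$mat %*% W
  } else {
    cols <- im2col_batch_cpp(a$mat, a$H, a$W, a$B, 3L, 3L, 1L, 1L)
    Z <- cols %*% W
  }
  bn_cache <- NULL
  if (isTRUE(d$bn)) {
    bn <- .bn_fwd(Z, net$par[[paste0(prefix, "_g")]],
                  net$par[[paste0(prefix, "_b")]],
                  net$state[[paste0(prefix, "_rm")]],
                  net$state[[paste0(prefix, "_rv")]], train)
    if (train) {
      state_env$state[[paste0(prefix, "_rm")]] <- bn$rm
      state_env$state[[paste0(prefix, "_rv")]] <- bn$rv
    }
    Y <- bn$Y
    bn_cache <- list(Zh = bn$Zh, istd = bn$istd)
  } else {
    bias <- net$par[[paste0(prefix, "_bias")]]
    Y <- Z + matrix(bias, nrow(Z), length(bias), byrow = TRUE)
  }
  mask <- NULL
  if (isTRUE(d$relu)) {
    mask <- Y > 0
    Y <- Y * mask
  }
  list(a = list(mat = Y, H = a$H, W = a$W, B = a$B),
       cache = list(prefix = prefix, kh = d$kh, cin = d$cin,
                    in_mat = if (d$kh == 1L) a$mat else NULL, cols = cols,
                    bn = bn_cache, mask = mask,
                    H = a$H, W = a$W, B = a$B))
}

.conv_bwd <- function(cache, dY, net, genv) {
  prefix <- cache$prefix
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  if (!is.null(cache$bn)) {
    g <- net$par[[paste0(prefix, "_g")]]
    bb <- .bn_bwd(dY, cache$bn$Zh, cache$bn$istd, g)
    dZ <- bb$dZ
    genv$g[[paste0(prefix, "_g")]] <- genv$g[[paste0(prefix, "_g")]] %||% 0
    genv$g[[paste0(prefix, "_g")]] <- genv$g[[paste0(prefix, "_g")]] + bb$dg
    genv$g[[paste0(prefix, "_b")]] <- (genv$g[[paste0(prefix, "_b")]] %||% 0) + bb$db
  } else {
    dZ <- dY
    genv$g[[paste0(prefix, "_bias")]] <- (genv$g[[paste0(prefix, "_bias")]] %||% 0) + colSums(dY)
  }
  W <- net$par[[paste0(prefix, "_W")]]
  if (cache$kh == 1L) {
    dW <- crossprod(cache$in_mat, dZ)
    dx <- dZ %*% t(W)
  } else {
    dW <- crossprod(cache$cols, dZ)
    dx <- col2im_batch_cpp(dZ %*% t(W), cache$H, cache$W, cache$cin, cache$B,
                           3L, 3L, 1L, 1L)
  }
  genv$g[[paste0(prefix, "_W")]] <- (genv$g[[paste0(prefix, "_W")]] %||% 0) + dW
  dx
}

.res_fwd <- function(d, net, a, train, state_env) {
  d1 <- list(kind = "conv", kh = 3L, cin = d$cin, cout = d$cout, bn = TRUE, relu = TRUE)
  d2 <- list(kind = "conv", kh = 3L, cin = d$cout, cout = d$cout, bn = TRUE, relu = FALSE)
  r1 <- .conv_fwd(d1, paste0(d$prefix, "_c1"), net, a, train, state_env)
  r2 <- .conv_fwd(d2, paste0(d$prefix, "_c2"), net, r1$a, train, state_env)
  if (d$proj) {
    dp <- list(kind = "conv", kh = 1L, cin = d$cin, cout = d$cout, bn = TRUE, relu = FALSE)
    rp <- .conv_fwd(dp, paste0(d$prefix, "_p"), net, a, train, state_env)
    skip <- rp$a$mat; proj_cache <- rp$cache
  } else {
    skip <- a$mat; proj_cache <- NULL
  }
  Y <- r2$a$mat + skip
  mask <- Y > 0
  Y <- Y * mask
  list(a = list(mat = Y, H = a$H, W = a$W, B = a$B),
       cache = list(kind = "res", c1 = r1$cache, c2 = r2$cache,
                    proj = proj_cache, mask = mask))
}

.res_bwd <- function(cache, dY, net, genv) {
  dY <- dY * cache$mask
  dmain <- .conv_bwd(cache$c2, dY, net, genv)
  dmain <- .conv_bwd(cache$c1, dmain, net, genv)
  dskip <- if (!is.null(cache$proj)) .conv_bwd(cache$proj, dY, net, genv) else dY
  dmain + dskip
}

.pool_fwd <- function(a, cin) {
  r <- maxpool_fwd_batch_cpp(a$mat, a$H, a$W, a$B, 2L)
  list(a = list(mat = r$out, H = a$H %/% 2L, W = a$W %/% 2L, B = a$B),
       cache = list(idx = r$idx, n_rows = nrow(a$mat)))
}

.pool_bwd <- function(cache, dY) {
  maxpool_bwd_batch_cpp(dY, cache$idx, cache$n_rows)
}

.tconv_fwd <- function(d, net, a) {
  W <- net$par[[paste0(d$prefix, "_W")]]
  bias <- net$par[[paste0(d$prefix, "_bias")]]
  Hf <- a$H * d$stride; Wf <- a$W * d$stride
  out <- col2im_batch_cpp(a$mat %*% t(W), Hf, Wf, d$cout, a$B,
                          d$k, d$k, d$pad, d$stride)
  for (k in seq_len(d$cout)) out[, k] <- out[, k] + bias[k]
  list(a = list(mat = out, H = Hf, W = Wf, B = a$B),
       cache = list(d = d, in_mat = a$mat, B = a$B, Hf = Hf, Wf = Wf))
}

.tconv_bwd <- function(cache, dY, net, genv) {
  d <- cache$d
  W <- net$par[[paste0(d$prefix, "_W")]]
  dcols <- im2col_batch_cpp(dY, cache$Hf, cache$Wf, cache$B,
                            d$k, d$k, d$pad, d$stride)
  dW <- crossprod(dcols, cache$in_mat)
  dx <- dcols %*% W
  genv$g[[paste0(d$prefix, "_W")]] <- (genv$g[[paste0(d$prefix, "_W")]] %||% 0) + dW
  genv$g[[paste0(d$prefix, "_bias")]] <-
    (genv$g[[paste0(d$prefix, "_bias")]] %||% 0) + colSums(dY)
  dx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.softmax_rows <- function(z) {
  m <- z[, 1]
  for (k in seq_len(ncol(z))[-1]) m <- pmax(m, z[, k])
  e <- exp(z - m)
  e / rowSums(e)
}

# Full forward pass. Returns probability matrix (B*N x K) and, when
# want_cache, everything backward needs. state_env$state collects batch-norm
# running-statistic updates in training mode.
.fcn_forward <- function(net, x, train = FALSE, want_cache = FALSE,
                         state_env = NULL) {
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  H <- d[1]; W <- d[2]; B <- d[3]
  if (H != net$spec$input_size || W != net$spec$input_size) {
    stop("input slices must be ", net$spec$input_size, "x", net$spec$input_size)
  }
  if (is.null(state_env)) state_env <- new.env(); state_env$state <- net$state
  S <- net$spec$scales
  a <- list(mat = matrix(as.vector(x), ncol = 1L), H = H, W = W, B = B)
  scale_out <- vector("list", S)
  body_caches <- vector("list", S)
  pool_caches <- vector("list", S)
  for (s in seq_len(S)) {
    if (s > 1L) {
      pr <- .pool_fwd(a, net$spec$widths[s - 1L])
      a <- pr$a; pool_caches[[s]] <- pr$cache
    }
    ucaches <- list()
    for (dsc in net$arch$body[[s]]) {
      r <- if (dsc$kind == "res") .res_fwd(dsc, net, a, train, state_env)
           else .conv_fwd(dsc, dsc$prefix, net, a, train, state_env)
      a <- r$a
      ucaches[[length(ucaches) + 1L]] <- r$cache
    }
    body_caches[[s]] <- ucaches
    scale_out[[s]] <- a
  }
  up_out <- vector("list", S)
  up_caches <- vector("list", S)
  up_out[[1]] <- scale_out[[1]]
  if (S > 1L) {
    for (s in 2:S) {
      r <- .tconv_fwd(net$arch$ups[[s]], net, scale_out[[s]])
      up_out[[s]] <- r$a; up_caches[[s]] <- r$cache
    }
  }
  cat_mat <- do.call(cbind, lapply(up_out, function(u) u$mat))
  a <- list(mat = cat_mat, H = H, W = W, B = B)
  head_caches <- list()
  for (dsc in net$arch$head) {
    r <- .conv_fwd(dsc, dsc$prefix, net, a, train, state_env)
    a <- r$a
    head_caches[[length(head_caches) + 1L]] <- r$cache
  }
  probs <- .softmax_rows(a$mat)
  out <- list(probs = probs, logits = a$mat, H = H, W = W, B = B,
              state = state_env$state)
  if (want_cache) {
    out$cache <- list(body = body_caches, pools = pool_caches,
                      ups = up_caches, head = head_caches,
                      widths = c(net$spec$widths[1],
                                 rep(net$spec$up_width, S - 1L)))
  }
  out
}

# Backward pass from d(logits); returns named gradient list.
.fcn_backward <- function(net, fwd, dlogits) {
  genv <- new.env(); genv$g <- list()
  ch <- fwd$cache
  dcur <- dlogits
  for (i in rev(seq_along(ch$head))) {
    dcur <- .conv_bwd(ch$head[[i]], dcur, net, genv)
  }
  S <- net$spec$scales
  w <- ch$widths
  splits <- split(seq_len(sum(w)), rep(seq_len(S), w))
  d_scale <- vector("list", S)      # gradient flowing into each scale output
  for (s in seq_len(S)) {
    dup <- dcur[, splits[[s]], drop = FALSE]
    d_scale[[s]] <- if (s == 1L) dup else .tconv_bwd(ch$ups[[s]], dup, net, genv)
  }
  dnext <- NULL                     # gradient from scale s+1 through its pool
  for (s in S:1) {
    dacc <- d_scale[[s]]
    if (!is.null(dnext)) dacc <- dacc + dnext
    for (i in rev(seq_along(ch$body[[s]]))) {
      cc <- ch$body[[s]][[i]]
      dacc <- if (identical(cc$kind, "res")) .res_bwd(cc, dacc, net, genv)
              else .conv_bwd(cc, dacc, net, genv)
    }
    dnext <- if (s > 1L) .pool_bwd(ch$pools[[s]], dacc) else NULL
  }
  genv$g
}

#' Forward pass: per-pixel class probabilities
#'
#' @param net an `fcn_network`.
#' @param batch numeric array of slices, `H x W` or `H x W x B`, preprocessed
#'   to \[0, 1\]; `H` and `W` must equal the network's `input_size`.
#' @param train logical; use batch statistics (TRUE) or running statistics
#'   (FALSE) in batch normalisation.
#' @return array `H x W x K x B` of probabilities summing to 1 per pixel.
#' @export
forward <- function(net, batch, train = FALSE) {
  stopifnot(inherits(net, "fcn_network"))
  r <- .fcn_forward(net, batch, train = train)
  K <- net$spec$K
  B <- r$B; N <- r$H * r$W
  out <- array(0, c(r$H, r$W, K, B))
  for (b in seq_len(B)) {
    out[, , , b] <- array(r$probs[((b - 1L) * N + 1L):(b * N), ], c(r$H, r$W, K))
  }
  out
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a network checkpoint
#'
#' Weights go into an `.rds` file; the architecture spec is additionally
#' serialized as JSON next to it, so the spec is readable without loading
#' the weights.
#'
#' @param net an `fcn_network`.
#' @param path checkpoint path (`.rds`).
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(net$spec, paste0(sub("\\.rds$", "", path), ".spec.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  net <- readRDS(path)
  stopifnot(inherits(net, "fcn_network"))
  net
}
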