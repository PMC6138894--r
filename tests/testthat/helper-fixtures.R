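# Shared fixtures: scaled-down phantoms and reduced networks keep the suite
# inside CPU budgets; generator defaults themselves are exercised in
# test-acceptance.R.

small_phantom_params <- function(...) {
  defaults <- list(rows = 64L, cols = 64L, slices = 2L, frames = 8L,
                   spacing_mm = c(3.6, 3.6, 10), blur_sigma_px = 0,
                   noise_sd = 0, seed = 1L)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

# 96 x 96 at the native 1.8 mm spacing (structures at true scale)
native_phantom_params <- function(...) {
  defaults <- list(rows = 96L, cols = 96L, slices = 2L, frames = 10L,
                   spacing_mm = c(1.8, 1.8, 10), seed = 1L)
  do.call(phantom_params, utils::modifyList(defaults, list(...)))
}

tiny_net <- function(K = 4L, input_size = 64L, seed = 1L, variant = "vgg") {
  build_fcn(K, variant, scales = 2L, widths = c(8L, 16L),
            conv_counts = c(2L, 2L), head_widths = c(16L, 16L),
            up_width = 8L, input_size = input_size, seed = seed)
}

# Independent brute-force metric oracles (double loops over voxels/points);
# deliberately naive and separate from the package implementation.
oracle_dice <- function(A, B) {
  a <- 0; b <- 0; ab <- 0
  for (i in seq_along(A)) {
    a <- a + (A[i] != 0); b <- b + (B[i] != 0)
    ab <- ab + (A[i] != 0 && B[i] != 0)
  }
  if (a + b == 0) NA_real_ else 2 * ab / (a + b)
}

oracle_boundary <- function(mask, spacing) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!mask[i, j]) next
    outside <- (i == 1 || !mask[i - 1, j]) || (i == H || !mask[i + 1, j]) ||
      (j == 1 || !mask[i, j - 1]) || (j == W || !mask[i, j + 1])
    if (outside) pts <- rbind(pts, c(i * spacing[1], j * spacing[2]))
  }
  pts
}

oracle_distances <- function(P, Q) {
  # directed min-distances both ways, all pairs
  dmin_pq <- apply(P, 1, function(p) min(sqrt((Q[, 1] - p[1])^2 + (Q[, 2] - p[2])^2)))
  dmin_qp <- apply(Q, 1, function(q) min(sqrt((P[, 1] - q[1])^2 + (P[, 2] - q[2])^2)))
  list(mcd = mean(dmin_pq) / 2 + mean(dmin_qp) / 2,
       hd = max(max(dmin_pq), max(dmin_qp)))
}

random_blob_mask <- function(n, seed) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  cy <- runif(1, n * 0.3, n * 0.7); cx <- runif(1, n * 0.3, n * 0.7)
  r <- runif(1, 2, n * 0.3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- (i - cy)^2 + (j - cx)^2 < r^2 * (1 + 0.3 * sin(3 * atan2(i - cy, j - cx)))
  }
  m
}
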