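test_that("Dice boundary values and hand-counted overlap", {
  m <- matrix(0, 20, 20)
  A <- m; A[5:12, 5:12] <- 1
  expect_equal(dice(A, A), 1)
  B <- m; B[15:18, 15:18] <- 1
  expect_equal(dice(A, B), 0)
  # |A| = 4, |B| = 4, |A n B| = 2 -> 0.5
  a2 <- m; a2[1, 1:4] <- 1
  b2 <- m; b2[1, 3:6] <- 1
  expect_equal(dice(a2, b2), 0.5)
  expect_true(is.na(dice(m, m)))
  expect_error(dice(A, matrix(0, 10, 10)), "same grid")
})

test_that("contour extraction counts boundary pixels correctly", {
  m <- matrix(FALSE, 20, 20)
  m[3, 7] <- TRUE
  expect_identical(extract_contour(m)$n, 1L)
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_identical(extract_contour(sq)$n, 36L)          # 4*10 - 4
  full <- matrix(TRUE, 12, 9)
  expect_identical(extract_contour(full)$n, 2L * 12L + 2L * 9L - 4L)
  expect_identical(extract_contour(matrix(FALSE, 5, 5))$n, 0L)
})

test_that("contour distances match their closed forms", {
  cA <- structure(list(points = cbind(0, 0), n = 1L), class = "contour")
  cB <- structure(list(points = cbind(c(0, 0), c(0, 5)), n = 2L), class = "contour")
  expect_equal(mean_contour_distance(cA, cB), 1.25)     # 0/2 + (0+5)/2/2
  expect_equal(hausdorff_distance(cA, cB), 5)
  expect_equal(mean_contour_distance(cA, cA), 0)
  expect_equal(hausdorff_distance(cA, cA), 0)
  # single-pixel contours 3 px apart at 1.8 mm spacing -> 5.4 mm
  m1 <- matrix(FALSE, 10, 10); m1[4, 2] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[4, 5] <- TRUE
  c1 <- extract_contour(m1, c(1.8, 1.8)); c2 <- extract_contour(m2, c(1.8, 1.8))
  expect_equal(mean_contour_distance(c1, c2), 5.4)
  expect_equal(hausdorff_distance(c1, c2), 5.4)
  empty <- extract_contour(matrix(FALSE, 5, 5))
  expect_true(is.na(mean_contour_distance(c1, empty)))
  expect_true(is.na(hausdorff_distance(empty, c1)))
})

test_that("metrics agree exactly with the brute-force oracle on random masks", {
  spacing <- c(1.8, 1.8)
  for (s in 1:100) {
    n <- sample(8:32, 1)
    A <- random_blob_mask(n, seed = 1000 + s)
    B <- random_blob_mask(n, seed = 2000 + s)
    expect_identical(dice(A, B), oracle_dice(A, B))
    pA <- oracle_boundary(A, spacing); pB <- oracle_boundary(B, spacing)
    if (is.null(pA) || is.null(pB)) next
    cA <- extract_contour(A, spacing); cB <- extract_contour(B, spacing)
    # same boundary sets
    expect_identical(cA$points[order(cA$points[, 1], cA$points[, 2]), , drop = FALSE],
                     pA[order(pA[, 1], pA[, 2]), , drop = FALSE])
    o <- oracle_distances(pA, pB)
    mcd <- mean_contour_distance(cA, cB)
    hd <- hausdorff_distance(cA, cB)
    expect_equal(mcd, o$mcd, tolerance = 1e-12)
    expect_equal(hd, o$hd, tolerance = 1e-12)
    expect_gte(hd, mcd)
    # symmetry
    expect_equal(mean_contour_distance(cB, cA), mcd, tolerance = 1e-12)
    expect_equal(hausdorff_distance(cB, cA), hd, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under identical rigid translation", {
  A <- random_blob_mask(24, seed = 5); B <- random_blob_mask(24, seed = 6)
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, 40, 40)
    out[(1:24) + dr, (1:24) + dc] <- m
    out
  }
  sp <- c(1.8, 1.8)
  d0 <- dice(pad(A, 0, 0), pad(B, 0, 0))
  m0 <- mean_contour_distance(extract_contour(pad(A, 0, 0), sp),
                              extract_contour(pad(B, 0, 0), sp))
  for (shift in list(c(5, 3), c(11, 14))) {
    At <- pad(A, shift[1], shift[2]); Bt <- pad(B, shift[1], shift[2])
    expect_identical(dice(At, Bt), d0)
    expect_equal(mean_contour_distance(extract_contour(At, sp),
                                       extract_contour(Bt, sp)), m0,
                 tolerance = 1e-12)
  }
})

test_that("Dice decreases monotonically under erosion of one mask", {
  ref <- matrix(FALSE, 30, 30); ref[5:25, 5:25] <- TRUE
  vals <- vapply(0:5, function(k) {
    shrunk <- matrix(FALSE, 30, 30)
    if (5 + k <= 25 - k) shrunk[(5 + k):(25 - k), (5 + k):(25 - k)] <- TRUE
    dice(shrunk, ref)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("evaluate_case aggregates per structure with undefined handling", {
  case <- generate_phantom(small_phantom_params(frames = 2L))
  truth <- case$truth
  m_id <- evaluate_case(truth, truth)
  expect_identical(m_id$structure, structures(truth$scheme))
  expect_equal(m_id$dice, rep(1, 3))
  expect_equal(m_id$mcd_mm, rep(0, 3))
  expect_equal(m_id$hd_mm, rep(0, 3))
  expect_identical(m_id$n_slices, rep(4L, 3))           # 2 slices x 2 frames
  # structure absent from both maps: excluded with a zero slice count
  lab_lv <- truth$labels; lab_lv[lab_lv == 3L] <- 0L
  seg_lv <- segmentation_map(lab_lv, truth$scheme, truth$spacing_mm)
  m_lv <- evaluate_case(seg_lv, seg_lv)
  expect_true(is.na(m_lv$dice[m_lv$structure == "RV cavity"]))
  expect_identical(m_lv$n_slices[m_lv$structure == "RV cavity"], 0L)
  expect_error(evaluate_case(truth,
                             segmentation_map(array(0L, c(4, 4, 1, 1)),
                                              truth$scheme)), "same grid")
})

test_that("observer jitter bounds the mean contour distance", {
  case <- generate_phantom(native_phantom_params(frames = 2L, noise_sd = 0,
                                                 blur_sigma_px = 0))
  truth <- case$truth
  mcds <- vapply(1:20, function(s) {
    obs <- simulate_observer(truth, 1.8, seed = s)
    m <- evaluate_case(obs, truth)
    m$mcd_mm[m$structure == "LV cavity"]
  }, 0)
  expect_true(all(mcds > 0 & mcds < 3.6))
})
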