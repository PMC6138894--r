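test_that("NIfTI round-trip preserves voxels, labels and spacing", {
  dir <- withr::local_tempdir()
  set.seed(1)
  v <- array(rnorm(20 * 18 * 3 * 4), c(20, 18, 3, 4))
  stack <- cine_stack(v, spacing_mm = c(1.8, 1.8, 10), frame_interval_ms = 20)
  for (ext in c(".nii", ".nii.gz")) {
    path <- file.path(dir, paste0("img", ext))
    save_cine(stack, path)
    back <- load_cine(path)
    expect_identical(back$voxels, stack$voxels)         # float64 is bit-exact
    expect_equal(back$spacing_mm, stack$spacing_mm, tolerance = 1e-6)
    expect_equal(back$frame_interval_ms, 20, tolerance = 1e-6)
  }
  # integer labels round-trip exactly, with the scheme sidecar
  lab <- array(sample(0:3, 20 * 18 * 3 * 4, TRUE), c(20, 18, 3, 4))
  seg <- segmentation_map(lab, label_scheme("sa"), spacing_mm = c(1.8, 1.8, 10))
  p <- file.path(dir, "seg.nii.gz")
  save_segmentation(seg, p)
  back <- load_segmentation(p)
  expect_identical(back$labels, seg$labels)
  expect_identical(back$scheme$labels, seg$scheme$labels)
})

test_that("load_cine handles degenerate dimensionality and bad input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "flat.nii")
  cineseg:::write_nifti(array(1:9 / 9, c(3, 3, 1)), p, pixdim = c(1.8, 1.8, 10))
  s <- load_cine(p)
  expect_equal(dim(s$voxels), c(3L, 3L, 1L, 1L))
  expect_error(load_cine(file.path(dir, "missing.nii")), "not found")
  writeBin(raw(100), file.path(dir, "junk.nii"))
  expect_error(load_cine(file.path(dir, "junk.nii")), "malformed")
})

test_that("missing temporal metadata warns and leaves the interval unset", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "notime.nii")
  cineseg:::write_nifti(array(runif(4 * 4 * 1 * 3), c(4, 4, 1, 3)), p,
                        pixdim = c(1.8, 1.8, 10, 0))
  expect_warning(s <- load_cine(p), "temporal")
  expect_true(is.na(s$frame_interval_ms))
})

test_that("preprocess crops, pads and normalises per slice", {
  set.seed(2)
  # larger than the window: centre crop
  big <- cine_stack(array(runif(210 * 180), c(210, 180, 1, 1)))
  pp <- preprocess(big, size = 192)
  expect_equal(dim(pp$x)[1:2], c(192L, 192L))
  expect_equal(range(pp$x[, , 1, 1]), c(0, 1))
  # constant slice maps to zeros
  const <- cine_stack(array(7, c(50, 50, 1, 1)))
  expect_true(all(preprocess(const, size = 192)$x == 0))
  # closed-form min-max rescaling
  v <- array(100, c(10, 10, 1, 1)); v[1] <- 500; v[2] <- 300
  pp2 <- preprocess(cine_stack(v), size = 10)
  expect_equal(max(pp2$x), 1)
  expect_equal(min(pp2$x), 0)
  expect_equal(pp2$x[2, 1, 1, 1], 0.5)
})

test_that("restore_geometry inverts the geometric step exactly", {
  set.seed(3)
  # pad-then-restore preserves every original label
  lab <- array(sample(0:3, 100 * 100, TRUE), c(100, 100, 1, 1))
  stack <- cine_stack(array(runif(1e4), c(100, 100, 1, 1)))
  pp <- preprocess(stack, size = 192)
  lab192 <- array(0L, c(192, 192, 1, 1))
  r <- pp$record
  lab192[r$dst_row[1]:r$dst_row[2], r$dst_col[1]:r$dst_col[2], , ] <- lab
  expect_identical(restore_geometry(lab192, pp$record), lab)
  # exactly 192 x 192 is the identity
  lab_id <- array(sample(0:1, 192 * 192, TRUE), c(192, 192, 1, 1))
  pp_id <- preprocess(cine_stack(array(runif(192^2), c(192, 192, 1, 1))), size = 192)
  expect_identical(restore_geometry(lab_id, pp_id$record), lab_id)
  # crop-then-restore: identity on the overlap, background outside
  lab_big <- array(sample(0:3, 210 * 200, TRUE), c(210, 200, 1, 1))
  stack_big <- cine_stack(array(runif(210 * 200), c(210, 200, 1, 1)))
  ppb <- preprocess(stack_big, size = 192)
  rb <- ppb$record
  crop <- lab_big[rb$src_row[1]:rb$src_row[2], rb$src_col[1]:rb$src_col[2], , , drop = FALSE]
  restored <- restore_geometry(array(crop, c(192, 192, 1, 1)), ppb$record)
  expect_identical(restored[rb$src_row[1]:rb$src_row[2],
                            rb$src_col[1]:rb$src_col[2], , , drop = FALSE],
                   unname(crop))
  outside <- restored
  outside[rb$src_row[1]:rb$src_row[2], rb$src_col[1]:rb$src_col[2], , ] <- 0L
  expect_true(all(outside == 0L))
  expect_error(restore_geometry(array(0L, c(100, 100, 1, 1)), ppb$record),
               "crop record")
})

test_that("preprocess/restore identity holds on random shapes", {
  set.seed(4)
  for (rep in 1:5) {
    h <- sample(40:250, 1); w <- sample(40:250, 1)
    lab <- array(sample(0:2, h * w, TRUE), c(h, w, 1, 1))
    pp <- preprocess(cine_stack(array(runif(h * w), c(h, w, 1, 1))), size = 192)
    r <- pp$record
    lab192 <- array(0L, c(192, 192, 1, 1))
    lab192[r$dst_row[1]:r$dst_row[2], r$dst_col[1]:r$dst_col[2], , ] <-
      lab[r$src_row[1]:r$src_row[2], r$src_col[1]:r$src_col[2], , , drop = FALSE]
    back <- restore_geometry(lab192, r)
    expect_identical(back[r$src_row[1]:r$src_row[2],
                          r$src_col[1]:r$src_col[2], , , drop = FALSE],
                     lab[r$src_row[1]:r$src_row[2],
                         r$src_col[1]:r$src_col[2], , , drop = FALSE])
  }
})

test_that("domain type validation catches bad input", {
  expect_error(cine_stack(array(1, c(4, 4)), spacing_mm = c(0, 1, 1)), "positive")
  expect_error(cine_stack(array(c(1, NA), c(2, 1))), "finite")
  expect_error(cine_stack(array(1, c(4, 4, 2, 1)), view = "2ch"), "1 slice")
  expect_error(segmentation_map(array(5L, c(4, 4)), label_scheme("sa")), "outside")
  expect_error(label_scheme("axial"), "unknown view")
  expect_identical(n_classes(label_scheme("sa")), 4L)
  expect_identical(structures(label_scheme("4ch")), c("LA cavity", "RA cavity"))
})
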