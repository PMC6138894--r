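# segmentation fixture with exact voxel counts per structure and frame:
# spacing (1, 1, 10) mm gives 10 mm^3 per voxel, so counts map to mL exactly
make_seg <- function(counts, grid = 200L, frames = length(counts[[1]]),
                     spacing = c(1, 1, 10), frame_interval_ms = NA_real_) {
  lab <- array(0L, c(grid, grid, 1L, frames))
  for (f in seq_len(frames)) {
    pos <- 1L
    for (s in seq_along(counts)) {
      n <- counts[[s]][f]
      if (n > 0) {
        plane <- lab[, , 1L, f]
        plane[pos:(pos + n - 1L)] <- s
        lab[, , 1L, f] <- plane
        pos <- pos + n
      }
    }
  }
  segmentation_map(lab, label_scheme("sa"), spacing_mm = spacing,
                   frame_interval_ms = frame_interval_ms)
}

test_that("chamber volume is voxel count times voxel volume", {
  # 1000 voxels at 1.8 x 1.8 x 10 mm -> 32.4 mL
  lab <- array(0L, c(40, 40, 1, 1))
  lab[seq_len(1000)] <- 1L
  seg <- segmentation_map(lab, label_scheme("sa"), spacing_mm = c(1.8, 1.8, 10))
  expect_equal(chamber_volume(seg, "LV cavity", 1), 32.4, tolerance = 1e-12)
  expect_equal(chamber_volume(seg, "RV cavity", 1), 0)
  expect_error(chamber_volume(seg, "aorta", 1), "unknown structure")
  expect_error(chamber_volume(seg, "LV cavity", 5), "out of range")
})

test_that("LV mass applies the 1.05 g/mL myocardial density", {
  # exactly 100 mL of myocardium -> 105 g
  seg <- make_seg(list(`1` = 0L, `2` = 10000L, `3` = 0L), frames = 1L)
  expect_equal(lv_mass(seg, 1), 105)
  expect_equal(lv_mass(seg, 1) / chamber_volume(seg, "LV myocardium", 1), 1.05)
  empty <- make_seg(list(`1` = 1L, `2` = 0L, `3` = 0L), frames = 1L)
  expect_equal(lv_mass(empty, 1), 0)
  seg2ch <- segmentation_map(array(0L, c(4, 4, 1, 1)), label_scheme("2ch"))
  expect_error(lv_mass(seg2ch, 1), "myocardium")
})

test_that("ED/ES frames are the volume-curve extrema with earliest-tie rule", {
  # monotone decreasing curve over 5 frames
  seg <- make_seg(list(c(500L, 400L, 300L, 200L, 100L),
                       rep(50L, 5), rep(0L, 5)))
  ee <- ed_es_frames(seg)
  expect_identical(ee$ed, 1L)
  expect_identical(ee$es, 5L)
  # two equal maxima -> earlier frame
  seg_tie <- make_seg(list(c(300L, 100L, 300L), rep(10L, 3), rep(0L, 3)))
  expect_identical(ed_es_frames(seg_tie)$ed, 1L)
  expect_error(ed_es_frames(make_seg(list(rep(0L, 3), rep(0L, 3), rep(0L, 3)))),
               "identically zero")
  expect_error(ed_es_frames(make_seg(list(1L, 1L, 0L), frames = 1L)), "2 frames")
})

test_that("derived measures follow their definitions", {
  # EDV 143 mL, ESV 60 mL -> SV 83 mL, EF 58.04 %
  seg <- make_seg(list(c(14300L, 6000L), c(8000L, 8000L), c(15000L, 7000L)),
                  frames = 2L, frame_interval_ms = 500)
  m <- measures_report(seg)
  expect_equal(m$LVEDV_mL, 143)
  expect_equal(m$LVESV_mL, 60)
  expect_equal(m$LVSV_mL, 83)
  expect_equal(m$LVEF_pct, 100 * 83 / 143, tolerance = 1e-12)
  expect_equal(round(m$LVEF_pct, 2), 58.04)
  expect_equal(m$LVM_g, 80 * 1.05)
  expect_equal(m$RVEDV_mL, 150); expect_equal(m$RVESV_mL, 70)
  # cycle = 2 frames x 500 ms = 1 s -> HR 60; SV 70 -> CO 4.2 L/min
  seg_co <- make_seg(list(c(10000L, 3000L), c(100L, 100L), c(0L, 0L)),
                     frames = 2L, frame_interval_ms = 500)
  expect_equal(measures_report(seg_co)$LVCO_Lmin, 4.2, tolerance = 1e-12)
  # EDV = ESV -> SV 0, EF 0
  seg_flat0 <- make_seg(list(c(500L, 500L), c(10L, 5L), c(0L, 0L)), frames = 2L)
  m0 <- measures_report(seg_flat0)
  expect_equal(m0$LVSV_mL, 0); expect_equal(m0$LVEF_pct, 0)
  # heart-rate override when temporal metadata is missing
  m_hr <- measures_report(seg_co, heart_rate_bpm = 60)
  expect_equal(m_hr$LVCO_Lmin, 4.2, tolerance = 1e-12)
  df <- as.data.frame(m)
  expect_named(df, c("LVEDV_mL", "LVESV_mL", "LVM_g", "RVEDV_mL", "RVESV_mL",
                     "LVSV_mL", "LVEF_pct", "LVCO_Lmin", "RVSV_mL", "RVEF_pct",
                     "RVCO_Lmin"))
})

test_that("volume additivity and invariances hold", {
  case <- generate_phantom(small_phantom_params(frames = 4L))
  seg <- case$truth
  vox_ml <- prod(seg$spacing_mm) / 1000
  grid_ml <- prod(dim(seg$labels)[1:3]) * vox_ml
  for (f in 1:4) {
    tot <- sum(vapply(structures(seg$scheme),
                      function(s) chamber_volume(seg, s, f), 0))
    bg <- sum(seg$labels[, , , f] == 0L) * vox_ml
    expect_equal(tot + bg, grid_ml, tolerance = 1e-9)
  }
  # in-plane translation leaves volumes unchanged
  shifted <- seg$labels[c(11:64, 1:10), , , , drop = FALSE]
  seg_sh <- segmentation_map(shifted, seg$scheme, seg$spacing_mm,
                             seg$frame_interval_ms)
  expect_equal(chamber_volume(seg_sh, "LV cavity", 1),
               chamber_volume(seg, "LV cavity", 1))
  # EF is dimensionless: uniform spacing rescale cancels
  seg_big <- segmentation_map(seg$labels, seg$scheme, seg$spacing_mm * 2,
                              seg$frame_interval_ms)
  expect_equal(measures_report(seg_big)$LVEF_pct, measures_report(seg)$LVEF_pct)
})

test_that("phantom EF target is recovered within 3 percentage points", {
  for (g in c(0.5, 0.6)) {
    case <- generate_phantom(native_phantom_params(ef_target = g, noise_sd = 0,
                                                   blur_sigma_px = 0))
    m <- measures_report(case$truth)
    expect_lt(abs(m$LVEF_pct - 100 * g), 3)
    expect_identical(m$ed_frame, case$ed_frame)
    expect_identical(m$es_frame, case$es_frame)
  }
})
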