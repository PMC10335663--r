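uniform_disk_image <- function(red, green, w = 60, h = 60) {
  img <- array(0, dim = c(h, w, 3))
  rois <- roi_layout("d1", center_x = 30, center_y = 30, radius = 10)
  px <- roptode:::roi_pixel_mask(rois[1, ], w, h)
  img[cbind(px$y + 1L, px$x + 1L, 1L)] <- red
  img[cbind(px$y + 1L, px$x + 1L, 2L)] <- green
  list(img = img, rois = rois)
}

test_that("constant-disk extraction reproduces channel arithmetic", {
  u <- uniform_disk_image(100, 50)
  s <- extract_roi_ratios(u$img, u$rois, time_min = 0)
  expect_equal(s$mean_red, 100)
  expect_equal(s$mean_green, 50)
  expect_equal(s$ratio_larsen, 1.0)
  expect_equal(s$ratio_simple, 2.0)
  expect_true(s$qc_pass)
  eq <- uniform_disk_image(70, 70)
  expect_equal(extract_roi_ratios(eq$img, eq$rois)$ratio_larsen, 0)
})

test_that("the two ratio definitions differ by exactly one", {
  layout <- roi_layout(c("a", "b"), c(20, 50), c(20, 40), c(8, 10))
  cals <- list(a = make_cal(id = "a"), b = make_cal(id = "b", Ksv = 0.009))
  img <- render_synthetic_frame(layout, list(a = 30, b = 80), cals,
                                width = 70, height = 60, green_level = 80,
                                noise_sd = 2, seed = 4)
  s <- extract_roi_ratios(img, layout)
  expect_equal(s$ratio_larsen, s$ratio_simple - 1)
})

test_that("noiseless render/extract/invert closes on the configured truth", {
  layout <- roi_layout("a", 30, 30, 12)
  cal <- calibration_curve("a", R0 = 1.9, Ksv = 0.011)
  for (C in c(0, 20, 40, 60, 80, 100)) {
    img <- render_synthetic_frame(layout, list(a = C), list(a = cal),
                                  width = 60, height = 60,
                                  green_level = 80, noise_sd = 0)
    s <- extract_roi_ratios(img, layout)
    C_hat <- invert_calibration(s$ratio_larsen, cal)
    expect_lt(abs(C_hat - C), 0.5)  # quantisation-only error budget
  }
})

test_that("rendering is deterministic under a fixed seed", {
  layout <- roi_layout("a", 30, 30, 12)
  cal <- list(a = make_cal(id = "a"))
  img1 <- render_synthetic_frame(layout, list(a = 50), cal, noise_sd = 1.5,
                                 seed = 99)
  img2 <- render_synthetic_frame(layout, list(a = 50), cal, noise_sd = 1.5,
                                 seed = 99)
  expect_identical(img1, img2)
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  write_frame(img1, p1); write_frame(img2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("extraction is invariant to a rigid translation of the layout", {
  cal <- list(a = make_cal(id = "a"))
  base <- roi_layout("a", 25, 25, 10)
  img <- render_synthetic_frame(base, list(a = 40), cal,
                                width = 100, height = 100,
                                green_level = 80, noise_sd = 0)
  shifted_layout <- roi_layout("a", 25 + 13, 25 + 7, 10)
  shifted_img <- array(0, dim = dim(img))
  shifted_img[(1:100) > 7, (1:100) > 13, ] <-
    img[1:(100 - 7), 1:(100 - 13), ]
  expect_equal(extract_roi_ratios(shifted_img, shifted_layout)$ratio_larsen,
               extract_roi_ratios(img, base)$ratio_larsen)
})

test_that("geometry and signal failures are reported per disk", {
  u <- uniform_disk_image(100, 50)
  bad <- roi_layout("edge", 2, 2, 5)
  expect_error(extract_roi_ratios(u$img, bad), "outside the image")
  dark <- uniform_disk_image(0, 0)
  expect_warning(s <- extract_roi_ratios(dark$img, dark$rois), "green")
  expect_false(s$qc_pass)
  expect_true(is.na(s$ratio_larsen))
  # a bright render that cannot be represented must refuse, not clip
  layout <- roi_layout("a", 30, 30, 10)
  expect_error(render_synthetic_frame(layout, list(a = 0),
                                      list(a = make_cal(id = "a")),
                                      green_level = 200),
               "full scale")
})

test_that("default disk geometry gives a well-populated ROI", {
  # at the working image scale a 10 px disk radius yields >= 300 pixels
  px <- roptode:::roi_pixel_mask(roi_layout("a", 30, 30, 10)[1, ], 60, 60)
  expect_gte(nrow(px), 300)
})

test_that("frames round-trip through PNG (8-bit) and TIFF (16-bit)", {
  layout <- roi_layout("a", 30, 30, 10)
  img <- render_synthetic_frame(layout, list(a = 50),
                                list(a = make_cal(id = "a")),
                                width = 60, height = 60, green_level = 80)
  p8 <- tempfile(fileext = ".png")
  write_frame(img, p8, bit_depth = 8)
  back8 <- read_frame(p8, bit_depth = 8)
  expect_lt(max(abs(back8 - img)), 0.5 + 1e-9)  # half-DN quantisation
  img16 <- img / 255 * 65535
  p16 <- tempfile(fileext = ".tiff")
  write_frame(img16, p16, bit_depth = 16)
  back16 <- read_frame(p16, bit_depth = 16)
  expect_lt(max(abs(back16 - img16)), 1 + 1e-9)  # 1-DN storage quantisation
  expect_error(write_frame(img16, tempfile(fileext = ".png"),
                           bit_depth = 16), "TIFF")
})

test_that("time-series assembly inverts per disk and honours QC", {
  cal <- calibration_curve("a", R0 = 1.9, Ksv = 0.011)
  reg <- list(a = cal)
  R <- stern_volmer_forward(60, cal)
  samples <- data.frame(disk_id = "a", time_min = c(0, 2, 4),
                        mean_red = NA, mean_green = NA, n_pixels = 300L,
                        ratio_larsen = R, ratio_simple = R + 1,
                        saturated_fraction = 0,
                        qc_pass = c(TRUE, TRUE, FALSE))
  ts <- build_timeseries(samples, reg)
  expect_equal(ts$conc_pct_sat[1:2], c(60, 60), tolerance = 1e-9)
  expect_true(is.na(ts$conc_pct_sat[3]))  # carried, not dropped
  expect_error(build_timeseries(transform(samples, disk_id = "zz"), reg),
               "zz")
  empty <- build_timeseries(samples[0, ], reg)
  expect_equal(nrow(empty), 0)
})

test_that("manifest reader resolves paths and enforces time order", {
  d <- tempfile(); dir.create(d)
  file.create(file.path(d, c("f1.png", "f2.png")))
  mpath <- file.path(d, "manifest.csv")
  write.csv(data.frame(time_min = c(0, 2), path = c("f1.png", "f2.png")),
            mpath, row.names = FALSE)
  m <- read_frame_manifest(mpath)
  expect_true(all(file.exists(m$path)))
  write.csv(data.frame(time_min = c(2, 0), path = c("f1.png", "f2.png")),
            mpath, row.names = FALSE)
  expect_error(read_frame_manifest(mpath), "increasing")
})
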