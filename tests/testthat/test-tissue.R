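# Tissue identification: darkest channel, mean filter, percentile
# thresholds, area cleanup, ROI selection.

test_that("darkest channel is the per-pixel minimum", {
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(10, 200, 200)
  rgb[1, 2, ] <- c(80, 80, 80)
  rgb[2, 1, ] <- c(255, 255, 255)
  rgb[2, 2, ] <- c(30, 20, 40)
  dk <- darkest_channel(rgb)
  expect_equal(dk, matrix(c(10, 255, 80, 20), 2, 2))
  expect_error(darkest_channel(array(0, c(2, 2, 2))), "3")
})

test_that("mean filter matches a brute-force windowed mean", {
  set.seed(1)
  x <- matrix(runif(15 * 12, 0, 255), 15, 12)
  for (w in c(1, 3, 5)) {
    expect_equal(mean_filter(x, w), oracle_box_mean(x, w), tolerance = 1e-12)
  }
  # window larger than the raster still works via mirrored extension
  small <- matrix(runif(9), 3, 3)
  expect_equal(mean_filter(small, 7), oracle_box_mean(small, 7),
               tolerance = 1e-12)
  expect_equal(mean_filter(x, 1), x)
  u <- matrix(7, 10, 10)
  expect_equal(mean_filter(u, 5), u)
  expect_error(mean_filter(x, 4), "odd")
})

test_that("initial threshold is the 99th centile minus the offset", {
  allwhite <- matrix(255, 20, 20)
  m <- initial_tissue_mask(allwhite)
  expect_equal(attr(m, "threshold"), 240)
  expect_false(any(m))

  half <- matrix(c(rep(50, 200), rep(255, 200)), 20, 20)
  m2 <- initial_tissue_mask(half)
  # 99th centile of {50 x200, 255 x200} is 255 -> T = 240
  expect_equal(attr(m2, "threshold"), 240)
  expect_identical(unclass(m2)[half == 50], rep(TRUE, 200))
  expect_identical(unclass(m2)[half == 255], rep(FALSE, 200))

  dark <- matrix(0, 5, 5)
  m3 <- initial_tissue_mask(dark)
  expect_equal(attr(m3, "threshold"), -15)
  expect_false(any(m3))
})

test_that("background refinement reclassifies bright tissue", {
  # background at 255, tissue at 50: T2 = 245, nothing reclassified
  x <- matrix(255, 10, 10); x[3:6, 3:6] <- 50
  mask <- x < 240
  out <- refine_background(x, mask)
  expect_equal(attr(out, "threshold"), 245)
  expect_equal(as.vector(out), as.vector(mask))

  # background at 100, tissue at {50, 95}: T2 = 90, the 95s flip
  y <- matrix(100, 10, 10)
  y[3:4, 3:4] <- 50
  y[7:8, 7:8] <- 95
  mask2 <- y < 100
  out2 <- refine_background(y, mask2)
  expect_equal(attr(out2, "threshold"), 90)
  expect_true(all(!out2[y == 95]))
  expect_true(all(out2[y == 50]))

  # empty background returned unchanged with a warning
  full <- matrix(TRUE, 4, 4)
  expect_warning(out3 <- refine_background(matrix(10, 4, 4), full),
                 "background")
  expect_identical(out3, full)
})

test_that("clean_mask applies the 50 um^2 floor then the 1% rule", {
  px <- 0.45  # 0.2025 um^2 per pixel
  mask <- matrix(FALSE, 120, 400)
  mask[10:109, 10:309] <- TRUE        # 30000 px main block
  mask[115:119, 330:369] <- TRUE      # 200 px island = 40.5 um^2 -> removed
  out <- clean_mask(mask, px)
  expect_false(any(out[115:119, 330:369]))
  expect_true(all(out[10:109, 10:309]))

  # a 300 px island (60.75 um^2) that is >= 1% of total tissue is kept
  mask2 <- matrix(FALSE, 150, 200)
  mask2[10:109, 10:109] <- TRUE       # 10000 px
  mask2[130:144, 150:169] <- TRUE     # 300 px ~ 2.9% of total
  out2 <- clean_mask(mask2, px)
  expect_true(all(out2[130:144, 150:169]))

  # the same island below 1% of a much larger block is removed
  mask3 <- matrix(FALSE, 400, 400)
  mask3[5:354, 5:354] <- TRUE         # 122500 px
  mask3[380:394, 360:379] <- TRUE     # 300 px ~ 0.24%
  out3 <- clean_mask(mask3, px)
  expect_false(any(out3[380:394, 360:379]))

  # small background holes are filled
  mask4 <- matrix(FALSE, 100, 100)
  mask4[10:89, 10:89] <- TRUE
  mask4[40:44, 40:44] <- FALSE        # 25 px hole = 5.06 um^2
  out4 <- clean_mask(mask4, px)
  expect_true(all(out4[40:44, 40:44]))

  # one giant component, no islands: unchanged
  expect_equal(clean_mask(mask4, px), out4)
})

test_that("after clean_mask no component violates either area rule", {
  px <- 0.45
  cfg <- tissue_config()
  set.seed(7)
  for (rep in 1:5) {
    noise <- matrix(runif(150 * 150) < 0.45, 150, 150)
    out <- clean_mask(noise, px, cfg)
    lab_t <- label_components(out)
    lab_b <- label_components(!out)
    if (max(lab_t) > 0) {
      areas_t <- tabulate(lab_t[lab_t > 0]) * px^2
      expect_true(all(areas_t >= cfg$min_area_um2))
      expect_true(all(areas_t >= cfg$min_tissue_fraction * sum(areas_t)))
    }
    if (max(lab_b) > 0) {
      # border-touching background is one large sea; all components obey
      areas_b <- tabulate(lab_b[lab_b > 0]) * px^2
      expect_true(all(areas_b >= cfg$min_area_um2))
    }
  }
})

test_that("raising the initial offset never grows the tissue mask", {
  set.seed(3)
  x <- matrix(runif(60 * 60, 0, 255), 60, 60)
  f <- mean_filter(x, 5)
  prev <- NULL
  for (off in c(0, 5, 15, 30)) {
    m <- initial_tissue_mask(f, tissue_config(init_offset = off))
    if (!is.null(prev)) expect_true(all(!unclass(m) | prev))
    prev <- unclass(m)
  }
})

test_that("ROI grid splits a square block into equal quadrants", {
  mask <- matrix(FALSE, 60, 60)
  mask[11:50, 11:50] <- TRUE
  rois <- select_rois(mask, 4)
  expect_length(rois, 4)
  expect_equal(unique(vapply(rois, sum, numeric(1))), 400)
  expect_equal(Reduce(`+`, lapply(rois, as.numeric)), as.numeric(mask),
               ignore_attr = TRUE)
})

test_that("user ROI labels pass through after tissue intersection", {
  mask <- matrix(TRUE, 20, 20)
  mask[, 1:2] <- FALSE
  labs <- matrix(0L, 20, 20)
  labs[1:10, ] <- 1L
  labs[11:20, ] <- 2L
  rois <- select_rois(mask, roi_labels = labs)
  expect_length(rois, 2)
  expect_equal(rois[[1]], labs == 1 & mask)
})

test_that("empty grid tiles are dropped with a warning", {
  # two blobs on one diagonal of the bounding box: the off-diagonal
  # tiles hold no tissue and are dropped
  mask <- matrix(FALSE, 40, 40)
  mask[2:9, 2:9] <- TRUE
  mask[32:39, 32:39] <- TRUE
  expect_warning(rois <- select_rois(mask, 4), "ROI")
  expect_lt(length(rois), 4)
  expect_true(all(vapply(rois, any, logical(1))))
})

test_that("tissue masks recover planted tissue on noiseless slides", {
  for (seed in 1:3) {
    sp <- slide_spec(width_px = 500, height_px = 400, n_positive = 8,
                     n_negative = 8, tissue_margin_px = 100)
    gen <- generate_ihc_slide(sp, optical_model(noise_sd = 0), seed = seed)
    res <- identify_tissue(gen$slide)
    iou <- sum(res$mask & gen$truth$tissue_mask) /
      sum(res$mask | gen$truth$tissue_mask)
    expect_gte(iou, 0.95)
  }
})
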