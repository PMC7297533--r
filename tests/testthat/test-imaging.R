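cfg96 <- sim_config(format = 96, seed = 1)
lay96 <- make_layout(96, "none")

test_that("segmentation finds every disk, matching a component-count oracle", {
  set.seed(5)
  for (k in c(1, 7, 30, 96)) {
    sizes <- matrix(0, 8, 12)
    sizes[sample(96, k)] <- 40
    img <- simulate_plate_image(cfg96, lay96, sizes, "grey")
    expect_equal(count_components(img), k)   # independent oracle
    mask <- segment_plate(img, c(8, 12))
    expect_equal(nrow(mask$position_map), k)
    # bijective position map onto the seeded positions
    seeded <- which(t(sizes) > 0) - 1L
    got <- sort(mask$position_map$row * 12 + mask$position_map$col)
    expect_equal(got, sort(seeded))
  }
})

test_that("blank images raise a no-objects error", {
  blank <- EBImage::Image(matrix(0.5, 128, 128))
  expect_error(segment_plate(blank, c(8, 12)), "no objects")
})

test_that("a single disk at the top-left lattice node maps to (0,0)", {
  sizes <- matrix(0, 8, 12); sizes[1, 1] <- 40
  img <- simulate_plate_image(cfg96, lay96, sizes, "grey")
  mask <- segment_plate(img, c(8, 12))
  expect_equal(mask$position_map[, c("row", "col")],
               data.frame(row = 0, col = 0))
})

test_that("measured disk areas are accurate and circular", {
  # radius 20 px disks: area within 5% of pi r^2, circularity >= 0.9
  cfg <- sim_config(format = 96, image_colony_radius = 20, image_pitch = 60)
  img <- simulate_plate_image(cfg, lay96, matrix(40, 8, 12), "grey")
  rec <- quantify_batch(list(img), c(8, 12))[[1]]$records
  expect_true(all(rec$found))
  expect_lt(max(abs(rec$area - pi * 400) / (pi * 400)), 0.05)
  expect_true(all(rec$circularity >= 0.9 & rec$circularity <= 1.2))
  # centroids sit on the lattice (pitch 60, first node at 30)
  expect_lt(max(abs(rec$centroid_x[rec$row == 0 & rec$col == 0] - 29.5)), 1.5)
})

test_that("empty positions are reported as not found with zero area", {
  sizes <- matrix(40, 8, 12); sizes[3, 4] <- 0
  img <- simulate_plate_image(cfg96, lay96, sizes, "grey")
  rec <- quantify_batch(list(img), c(8, 12))[[1]]$records
  miss <- rec[rec$row == 2 & rec$col == 3, ]
  expect_false(miss$found)
  expect_equal(miss$area, 0)
  expect_equal(sum(rec$found), 95)
})

test_that("elongated colonies score lower circularity than disks", {
  img <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey",
                              axis_ratio = 3)
  rec <- quantify_batch(list(img), c(8, 12))[[1]]$records
  expect_lt(median(rec$circularity, na.rm = TRUE), 0.85)
})

test_that("batch mode rejects RGB input and mixed sizes", {
  rgb <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "rgb")
  expect_error(quantify_batch(list(rgb), c(8, 12)), "greyscale")
  g1 <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey")
  cfg_small <- sim_config(format = 96, image_pitch = 20)
  g2 <- simulate_plate_image(cfg_small, lay96, matrix(40, 8, 12), "grey")
  expect_error(quantify_batch(list(g1, g2), c(8, 12)), "mixed image sizes")
})

test_that("inverted (dark-colony) transmission scans are auto-detected", {
  img <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey")
  inv <- EBImage::Image(1 - EBImage::imageData(img))
  rec <- quantify_batch(list(img), c(8, 12))[[1]]$records
  rec_inv <- quantify_batch(list(inv), c(8, 12))[[1]]$records
  expect_equal(rec_inv$area, rec$area)
  expect_equal(rec_inv$intensity, rec$intensity, tolerance = 1e-6)
})

test_that("downscaled segmentation recovers areas within 10%", {
  cfg <- sim_config(format = 96, image_colony_radius = 10, image_pitch = 30)
  img <- simulate_plate_image(cfg, lay96, matrix(40, 8, 12), "grey")
  full <- quantify_batch(list(img), c(8, 12), scale = 1)[[1]]$records
  half <- quantify_batch(list(img), c(8, 12), scale = 0.5)[[1]]$records
  expect_equal(sum(half$found), 96)
  # outputs are reported in original-image pixel units at any scale
  expect_lt(max(abs(half$area - full$area) / full$area), 0.1)
})

test_that("redness equals the chromaticity of a uniform colour", {
  px <- array(1, dim = c(120, 120, 3))
  px <- draw_disk(px, 60, 60, 20, c(0.9, 0.3, 0.3))
  img <- EBImage::Image(px, colormode = "Color")
  rec <- quantify_redness(img, c(1, 1), local_block = 41)
  expect_equal(sum(rec$found), 1)
  expect_equal(rec$redness[rec$found], 0.9 / 1.5, tolerance = 0.02)

  # grey disk: symmetric channels give exactly 1/3
  px2 <- array(1, dim = c(120, 120, 3))
  px2 <- draw_disk(px2, 60, 60, 20, c(0.5, 0.5, 0.5))
  rec2 <- quantify_redness(EBImage::Image(px2, colormode = "Color"),
                           c(1, 1), local_block = 41)
  expect_equal(rec2$redness[rec2$found], 1 / 3, tolerance = 0.02)
})

test_that("redder colonies score strictly higher redness", {
  px <- array(1, dim = c(200, 100, 3))
  px <- draw_disk(px, 50, 50, 18, c(0.9, 0.3, 0.3))   # red
  px <- draw_disk(px, 150, 50, 18, c(0.5, 0.5, 0.5))  # grey
  img <- EBImage::Image(px, colormode = "Color")
  rec <- quantify_redness(img, c(1, 2), local_block = 41)
  expect_equal(sum(rec$found), 2)
  expect_gt(rec$redness[rec$col == 0], rec$redness[rec$col == 1])
})

test_that("redness mode rejects greyscale input", {
  img <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey")
  expect_error(quantify_redness(img, c(8, 12)), "RGB")
})

test_that("timecourse uses the final-image mask for all frames", {
  sizes_t <- lapply(c(1, 4, 12, 25, 40), function(s) matrix(s, 8, 12))
  imgs <- lapply(sizes_t, function(s)
    simulate_plate_image(cfg96, lay96, s, "grey"))
  tc <- quantify_timecourse(imgs, c(8, 12), timestamps = 0:4)
  expect_equal(dim(tc), c(5L, 97L))
  mat <- as.matrix(tc[, -1])
  expect_true(all(apply(mat, 2, function(v) all(diff(v) >= 0))))
  # the mask attribute is the single segmentation reused across frames
  mask <- attr(tc, "mask")
  expect_equal(nrow(mask$position_map), 96)
})

test_that("a uniform background offset cancels in timecourse values", {
  sizes_t <- lapply(c(10, 20, 40), function(s) matrix(s, 8, 12))
  imgs <- lapply(sizes_t, function(s)
    simulate_plate_image(cfg96, lay96, s, "grey"))
  shifted <- imgs
  shifted[[2]] <- EBImage::Image(
    pmin(EBImage::imageData(imgs[[2]]) + 0.1, 1))
  tc <- quantify_timecourse(imgs, c(8, 12))
  tc2 <- quantify_timecourse(shifted, c(8, 12))
  expect_equal(as.matrix(tc2[, -1]), as.matrix(tc[, -1]), tolerance = 0.01)
})

test_that("positions empty in every frame produce no growth-curve column", {
  sizes <- matrix(40, 8, 12); sizes[5, 5] <- 0
  imgs <- lapply(c(0.3, 0.6, 1), function(f)
    simulate_plate_image(cfg96, lay96, f * sizes, "grey"))
  tc <- quantify_timecourse(imgs, c(8, 12))
  expect_false("4-4" %in% names(tc))
  expect_equal(ncol(tc), 96)                 # timepoint + 95 curves
})

test_that("a blank final frame is a no-mask error", {
  imgs <- list(
    simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey"),
    EBImage::Image(matrix(0.15, 288, 192)))
  expect_error(quantify_timecourse(imgs, c(8, 12)), "no mask")
})

test_that("background estimation returns the off-colony median", {
  img <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey")
  mask <- segment_plate(img, c(8, 12))
  expect_equal(estimate_background(img, mask), 0.15, tolerance = 1e-3)

  set.seed(2)
  noisy <- EBImage::imageData(img)
  bgpix <- mask$labels == 0
  noisy[bgpix] <- pmax(0, rnorm(sum(bgpix), 0.2, 0.01))
  expect_equal(estimate_background(EBImage::Image(noisy), mask), 0.2,
               tolerance = 0.005)

  allcol <- mask
  allcol$labels <- matrix(1L, nrow(mask$labels), ncol(mask$labels))
  expect_error(estimate_background(img, allcol), "no background")
})

test_that("quantification writes per-image CSV and QC overlay", {
  out <- tempfile()
  img <- simulate_plate_image(cfg96, lay96, matrix(40, 8, 12), "grey")
  attr(img, "source_path") <- "plate01.jpg"
  quantify_batch(list(img), c(8, 12), out_dir = out)
  expect_true(file.exists(file.path(out, "plate01.csv")))
  expect_true(file.exists(file.path(out, "plate01_qc.png")))
  back <- read.csv(file.path(out, "plate01.csv"))
  expect_equal(nrow(back), 96)
})
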