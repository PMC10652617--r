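test_that("config validation rejects inconsistent parameters", {
  expect_s3_class(segmenter_config(), "victa_config")
  expect_error(segmenter_config(min_area = 100, max_area = 50))
  expect_error(segmenter_config(history = 0))
  expect_error(segmenter_config(max_movers = 0))
  expect_error(segmenter_config(learning_rate = 2))
})

test_that("config files round trip and reject unknown keys", {
  cfg <- segmenter_config(min_area = 10, max_movers = 3)
  path <- tempfile(fileext = ".yaml")
  write_segmenter_config(cfg, path)
  cfg2 <- read_segmenter_config(path)
  expect_equal(cfg2, cfg)
  writeLines("min_area: 10\nnot_a_key: 1", path)
  expect_error(read_segmenter_config(path), "unknown config keys")
})

test_that("preprocessing is a fixed point on constant frames", {
  f <- matrix(117, 40, 30)
  expect_equal(preprocess_frame(f), f)
})

test_that("preprocessing removes 1-px specks and preserves 8-px blobs", {
  cfg <- segmenter_config()
  bg <- matrix(0, 41, 41)
  speck <- bg; speck[21, 21] <- 255
  expect_equal(preprocess_frame(speck, cfg), bg)
  blob <- bg
  d <- outer(1:41, 1:41, function(i, j) sqrt((i - 21)^2 + (j - 21)^2))
  blob[d <= 4] <- 255             # diameter ~8 px
  out <- preprocess_frame(blob, cfg)
  expect_equal(abs(sum(out > 0) - sum(blob > 0)) / sum(blob > 0), 0,
               tolerance = 0.2)
})

test_that("background model converges on a static scene", {
  g <- small_geometry()
  cfg <- segmenter_config()
  model <- new_background_model(g$frame_dims, cfg)
  f <- matrix(200, 320, 240)
  masks <- lapply(1:10, function(i) update_and_mask(model, f, cfg))
  expect_true(all(masks[[10]] == 0))
  expect_true(all(masks[[2]] == 0))
})

test_that("a displaced blob on a converged background is foreground", {
  g <- small_geometry()
  cfg <- segmenter_config()
  model <- new_background_model(g$frame_dims, cfg)
  bg <- matrix(200, 320, 240)
  for (i in 1:30) update_and_mask(model, bg, cfg)
  moved <- bg; moved[100:110, 100:110] <- 30
  mask <- update_and_mask(model, moved, cfg)
  expect_true(all(mask[100:110, 100:110] == 1))
  expect_equal(sum(mask), 11 * 11)
})

test_that("uninitialized or mismatched model state is a usage error", {
  cfg <- segmenter_config()
  expect_error(update_and_mask(list(), matrix(0, 4, 4), cfg),
               "new_background_model")
  model <- new_background_model(c(10, 12), cfg)
  expect_error(update_and_mask(model, matrix(0, 5, 5), cfg), "dims")
})

test_that("mover extraction filters by area, caps the count and sorts", {
  g <- small_geometry()
  cfg <- segmenter_config(min_area = 20, max_area = 2000, max_movers = 5)
  mask <- matrix(0, 320, 240)
  ## 7 square components of distinct sizes, all well inside the ROI
  sizes <- c(5, 6, 7, 8, 9, 10, 11)
  for (i in seq_along(sizes)) {
    r <- 20 + 40 * (i - 1)
    mask[r:(r + sizes[i] - 1), 60:(60 + sizes[i] - 1)] <- 1
  }
  mv <- extract_movers(mask, cfg, g)
  expect_equal(nrow(mv), 5)
  expect_equal(mv$area, sort(mv$area, decreasing = TRUE))
  expect_true(all(mv$area >= cfg$min_area & mv$area <= cfg$max_area))
  ## the two smallest qualifying components were dropped by the cap
  expect_equal(min(mv$area), 7 * 7)
})

test_that("empty masks and sub-threshold specks yield no movers", {
  g <- small_geometry()
  cfg <- segmenter_config()
  expect_equal(nrow(extract_movers(matrix(0, 320, 240), cfg, g)), 0)
  mask <- matrix(0, 320, 240)
  mask[100, 100] <- 1    # opening removes it; area < min_area anyway
  expect_equal(nrow(extract_movers(mask, cfg, g)), 0)
})

test_that("a component is retained iff its centroid is inside the ROI", {
  g <- small_geometry()   # ROI x in [10, 230]
  cfg <- segmenter_config(open_kernel = 1, close_kernel = 1)
  mask <- matrix(0, 320, 240)
  ## centroid at x = 7.5: outside
  mask[150:159, 4:12] <- 1
  expect_equal(nrow(extract_movers(mask, cfg, g)), 0)
  ## same blob shifted so centroid x = 12.5: inside, though it overlaps
  ## the boundary
  mask <- matrix(0, 320, 240)
  mask[150:159, 9:17] <- 1
  mv <- extract_movers(mask, cfg, g)
  expect_equal(nrow(mv), 1)
  expect_equal(mv$x, 12, tolerance = 1e-9)
})

test_that("raising min_area never increases the mover count", {
  g <- small_geometry()
  set.seed(7)
  mask <- matrix(0, 320, 240)
  for (i in 1:12) {
    r <- sample(20:290, 1); c <- sample(20:210, 1)
    s <- sample(3:14, 1)
    mask[r:(r + s), c:(c + s)] <- 1
  }
  counts <- vapply(c(5, 20, 50, 100, 200), function(a)
    nrow(extract_movers(mask, segmenter_config(min_area = a,
                                               max_movers = 50), g)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection over a static video reports no movers after acclimatisation", {
  path <- write_static_video(90, w = 240, h = 320, bg = 180,
                             square = list(x = 100, y = 100, size = 12,
                                           intensity = 30))
  det <- detect_assay(path, segmenter_config(), small_geometry())
  expect_equal(nrow(det$samples), 30)
  post <- det$samples$t >= 5
  ## the static dark square is part of the background, never a mover
  expect_true(all(det$samples$n_moving == 0))
  expect_true(all(det$samples$valid))
})

test_that("detection recovers scripted movers and their regions", {
  out <- render_small_scene(duration = 10)
  det <- detect_assay(out$asset, segmenter_config(), small_geometry(),
                      assay_id = "s1")
  tc <- truth_sample_counts(out$truth)
  post <- det$samples$t >= 5
  agree <- mean(det$samples$n_moving[post] == tc$n_moving[post])
  expect_gte(agree, 0.95)
  expect_true(all(det$samples$n_moving <= 5))
  ## centroid error within one blob radius
  b <- det$blobs[det$blobs$t >= 5, ]
  tr <- out$truth$records
  err <- vapply(seq_len(nrow(b)), function(i) {
    tt <- tr[tr$sample == b$sample[i], ]
    min(sqrt((tt$x - b$x[i])^2 + (tt$y - b$y[i])^2))
  }, numeric(1))
  expect_lt(max(err), 5)
})

test_that("detection logs are deterministic and round trip through CSV", {
  out <- render_small_scene(duration = 6)
  g <- small_geometry()
  det1 <- detect_assay(out$asset, segmenter_config(), g, assay_id = "d")
  det2 <- detect_assay(out$asset, segmenter_config(), g, assay_id = "d")
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_detections(det1, p1); write_detections(det2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  log <- read_detections(p1)
  expect_named(log, c("assay_id", "t", "blob_index", "x", "y", "area",
                      "region_label", "n_moving", "valid"))
  ## every sample appears at least once
  expect_equal(length(unique(log$t)), nrow(det1$samples))
})
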