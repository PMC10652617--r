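test_that("trajectories interpolate linearly and freeze during rests", {
  wp <- data.frame(t = c(0, 10), x = c(0, 100), y = c(50, 50))
  tr <- trajectory_spec("m", wp, blob_diameter = 4)
  p <- trajectory_position(tr, c(0, 2.5, 5, 10))
  expect_equal(p$x, c(0, 25, 50, 100))
  ## a rest from 2 to 4 s pauses progress, then motion resumes smoothly
  tr2 <- trajectory_spec("m", wp,
                         resting_intervals = data.frame(t_start = 2,
                                                        t_end = 4),
                         blob_diameter = 4)
  p2 <- trajectory_position(tr2, c(0, 2, 3, 4, 5, 12))
  expect_equal(p2$x, c(0, 20, 20, 20, 30, 100))
  expect_error(trajectory_spec("m", wp, resting_intervals =
    data.frame(t_start = c(0, 1), t_end = c(2, 3))), "overlap")
})

test_that("scenes reject trajectories that leave the frame", {
  g <- small_geometry()
  bad <- trajectory_spec("m", data.frame(t = 0, x = 239, y = 50),
                         blob_diameter = 10)
  expect_error(synthetic_scene(list(bad), duration = 1, geometry = g),
               "leaves the frame")
})

test_that("renders are deterministic for identical spec and seed", {
  sc <- small_scene(duration = 2, noise_sd = 4, seed = 9)
  p1 <- tempfile(fileext = ".fsv"); p2 <- tempfile(fileext = ".fsv")
  generate_scene(sc, p1)
  generate_scene(sc, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p3 <- tempfile(fileext = ".fsv")
  generate_scene(sc, p3, seed = 10)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p3, "raw", file.size(p3))))
})

test_that("stationary scenes have full resting and zero activity truth", {
  g <- small_geometry()
  trajs <- lapply(1:5, function(m)
    trajectory_spec(paste0("m", m),
                    data.frame(t = 0, x = 40 * m, y = 100 + 20 * m)))
  sc <- synthetic_scene(trajs, duration = 180, noise_sd = 0, geometry = g)
  tm <- truth_metrics(scene_truth(sc))
  expect_equal(tm$resting_frames, 1799)
  expect_equal(tm$total_activity, 0)
  expect_equal(tm$total_activity_full, 0)
})

test_that("a 20-s single-mover bout contributes 200 mosquito-samples", {
  g <- small_geometry()
  ## circles in the upper region from t = 10 to 30 (2.1 px per 0.1-s
  ## sample, above the 1-px motion threshold), resting before and after
  te <- seq(0, 20, by = 0.05)
  wp <- data.frame(t = te, x = 120 + 60 * cos(0.35 * te),
                   y = 85 + 60 * sin(0.35 * te))
  tr <- trajectory_spec("m1", wp,
                        resting_intervals = data.frame(
                          t_start = c(0, 30), t_end = c(10, 180)))
  sc <- synthetic_scene(list(tr), duration = 180, noise_sd = 0,
                        geometry = g)
  truth <- scene_truth(sc)
  tc <- truth_sample_counts(truth)
  expect_equal(sum(tc$n_moving), 200)
  expect_equal(sum(tc$n_upper), 200)
  expect_equal(sum(tc$n_lower), 0)
  tm <- truth_metrics(truth)
  expect_equal(tm$upper_activity, 200)
})

test_that("ground truth flags are never moving inside resting intervals", {
  sc <- small_scene(duration = 8)
  sc$trajectories[[1]]$resting_intervals <-
    data.frame(t_start = 3, t_end = 6)
  truth <- scene_truth(sc)
  r <- truth$records
  rest <- r$mosquito_id == "m1" & r$t > 3 & r$t <= 6
  expect_true(all(!r$moving[rest]))
  move <- r$mosquito_id == "m1" & (r$t > 6.2 | (r$t > 0.1 & r$t < 3))
  expect_true(all(r$moving[move]))
})

test_that("presets exist and their ground truths match the phenotypes", {
  ps <- preset_scenes(noise_sd = 0)
  expect_true(all(c("crawler", "dispersed", "high_rest", "mixed") %in%
                    names(ps)))
  expect_gte(length(ps), 4)
  for (sc in ps) expect_equal(sc$n_mosquitoes, 5)
  tm_c <- truth_metrics(scene_truth(ps$crawler))
  expect_gt(tm_c$prop_lower, 0.8)
  tm_d <- truth_metrics(scene_truth(ps$dispersed))
  expect_lt(tm_d$prop_lower, 0.5)
  tm_h <- truth_metrics(scene_truth(ps$high_rest))
  expect_gt(tm_h$resting_seconds, 90)
  tm_m <- truth_metrics(scene_truth(ps$mixed))
  expect_equal(tm_m$resting_frames, 0)
})

test_that("preset flyers stay detectable: fast, separated, off the split line", {
  ps <- preset_scenes(noise_sd = 0)
  for (name in c("crawler", "dispersed")) {
    truth <- scene_truth(ps[[name]])
    r <- truth$records
    ## every mosquito displaces by at least its diameter per sample
    for (m in unique(r$mosquito_id)) {
      rm <- r[r$mosquito_id == m, ]
      disp <- sqrt(diff(rm$x)^2 + diff(rm$y)^2)
      expect_gt(min(disp), 9.9)
    }
    ## pairwise separation at every sample is at least 3 blob diameters
    mind <- min(vapply(split(r, r$sample), function(d)
      min(dist(cbind(d$x, d$y))), numeric(1)))
    expect_gte(mind, 30 - 1e-6)
    ## centroids keep a margin from the region split line
    expect_gt(min(abs(r$y - truth$geometry$split_line_y)), 20)
  }
})

test_that("synthetic life-history tables respect the recording rules", {
  lh <- simulate_life_history(c("a1", "a2"), seed = 4)
  expect_equal(nrow(lh), 10)
  expect_true(all(is.na(lh$fed_24h[lh$fed_1h])))
  expect_true(all(!is.na(lh$fed_24h[!lh$fed_1h])))
  fed <- lh$fed_1h | (!is.na(lh$fed_24h) & lh$fed_24h)
  expect_true(all(!is.na(lh$haematin[fed])))
  expect_true(all(is.na(lh$haematin[!fed])))
  expect_true(all(lh$death_day >= 0))
  expect_equal(nrow(validate_life_history(lh)), 0)
})
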