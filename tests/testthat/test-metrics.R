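test_that("a compliant 180-s assay aggregates to exactly 35 epochs", {
  det <- fake_detections(rep(0L, 1800))
  ep <- aggregate_epochs(det)
  expect_s3_class(ep, "victa_epochs")
  expect_equal(nrow(ep), 35)
  expect_equal(ep$t_start, seq(5, 175, by = 5))
  expect_equal(ep$t_end - ep$t_start, rep(5, 35))
  expect_true(all(ep$valid_samples == 50))
})

test_that("short assays are refused with the available duration reported", {
  det <- fake_detections(rep(0L, 900))   # 90 s only
  expect_error(aggregate_epochs(det), "90")
  ## but a reduced epoch structure can be requested explicitly
  ep <- aggregate_epochs(det, n_epochs = 17)
  expect_equal(nrow(ep), 17)
})

test_that("samples in the first 5 s are excluded from epochs", {
  n <- rep(0L, 1800)
  n[1:50] <- 5L                    # activity only during acclimatisation
  ep <- aggregate_epochs(fake_detections(n))
  expect_true(all(ep$activity_total == 0))
  ## and the sample at exactly t = 5 s belongs to epoch 1
  n2 <- rep(0L, 1800); n2[51] <- 3L
  ep2 <- aggregate_epochs(fake_detections(n2))
  expect_equal(ep2$activity_total[1], 3)
  expect_equal(sum(ep2$activity_total), 3)
})

test_that("static scenes yield zero activity and all-inactive epochs", {
  ep <- aggregate_epochs(fake_detections(rep(0L, 1800)))
  expect_true(all(ep$activity_total == 0))
  expect_equal(ep$inactive_samples, ep$valid_samples)
})

test_that("scripted occupancy is counted per region per epoch", {
  ## 3 movers in the upper region during exactly epochs 1-2 (t in [5, 15)):
  ## samples 51..150 since sample s sits at t = (s - 1) * 0.1
  n <- rep(0L, 1800)
  n[51:150] <- 3L
  blob_y <- as.list(rep(NA, 1800))
  for (s in 51:150) blob_y[[s]] <- 50   # upper (split at 160)
  det <- fake_detections(n, blob_y = blob_y)
  ep <- aggregate_epochs(det)
  expect_equal(ep$activity_upper[1:2], c(150, 150))
  expect_true(all(ep$activity_upper[-(1:2)] == 0))
  expect_true(all(ep$activity_lower == 0))
})

test_that("activity conserves across regional stratification", {
  set.seed(11)
  n <- sample(0:5, 1800, TRUE)
  blob_y <- lapply(n, function(k) if (k > 0) sample(c(50, 250), k, TRUE)
                   else NA)
  det <- fake_detections(n, blob_y = blob_y)
  ep <- aggregate_epochs(det)
  expect_equal(ep$activity_upper + ep$activity_lower, ep$activity_total)
  m <- summarize_assay(ep, det)
  expect_equal(m$upper_activity + m$lower_activity, m$total_activity)
  expect_equal(m$total_activity, sum(ep$activity_total))
})

test_that("invalid samples are excluded from epoch numerators and denominators", {
  n <- rep(2L, 1800)
  valid <- rep(TRUE, 1800); valid[101:150] <- FALSE  # epoch 2 half dead
  n[101:150] <- 0L                                   # invalid carry no blobs
  det <- fake_detections(n, valid = valid)
  ep <- aggregate_epochs(det)
  expect_equal(ep$valid_samples[2], 0)
  expect_equal(ep$activity_total[2], 0)
  expect_equal(ep$valid_samples[3], 50)
  m <- summarize_assay(ep, det)
  expect_equal(m$valid_frames_proportion, 1750 / 1800)
})

test_that("strict resting counts no-movement samples minus the first", {
  expect_equal(resting_frame_count(fake_detections(rep(0L, 1800))), 1799)
  expect_equal(resting_frame_count(fake_detections(rep(1L, 1800))), 0)
  n <- rep(0L, 1800)
  n[601:1200] <- 2L
  expect_equal(resting_frame_count(fake_detections(n)), 1799 - 600)
  expect_error(resting_frame_count(fake_detections(0L)), "2 samples")
})

test_that("inferred inactivity is the reciprocal of the moving count", {
  expect_equal(inferred_inactivity(0L), 5L)
  expect_equal(inferred_inactivity(5L), 0L)
  expect_equal(inferred_inactivity(2L), 3L)
  expect_equal(inferred_inactivity(c(0L, 3L, 5L)), c(5L, 2L, 0L))
  expect_error(inferred_inactivity(6L))
  ## complementarity: movers + inferred inactive = 5
  n <- sample(0:5, 100, TRUE)
  expect_true(all(n + inferred_inactivity(n) == 5L))
})

test_that("assay summary identities hold and zero activity gives NA proportion", {
  det <- fake_detections(rep(0L, 1800))
  m <- summarize_assay(aggregate_epochs(det), det)
  expect_equal(m$total_activity, 0)
  expect_true(is.na(m$prop_lower))
  expect_equal(m$resting_seconds, 0.1 * m$resting_frames)
  expect_equal(m$valid_frames_proportion, 1)
  ## 50/50 regional split
  n <- rep(2L, 1800)
  blob_y <- lapply(seq_len(1800), function(s) c(50, 250))
  det2 <- fake_detections(n, blob_y = blob_y)
  m2 <- summarize_assay(aggregate_epochs(det2), det2)
  expect_equal(m2$prop_lower, 0.5)
  expect_equal(m2$resting_seconds, 0.1 * m2$resting_frames)
  expect_equal(m2$total_activity_full, 2 * 1800)
})

test_that("epoch and metric tables are written with stable schemas", {
  det <- fake_detections(rep(1L, 1800))
  ep <- aggregate_epochs(det)
  m <- summarize_assay(ep, det)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_epochs(ep, p1, assay_id = "a1")
  write_assay_metrics(m, p2)
  e <- utils::read.csv(p1)
  expect_equal(nrow(e), 35)
  expect_named(e, c("assay_id", "index", "t_start", "t_end",
                    "activity_total", "activity_upper", "activity_lower",
                    "inactive_samples", "valid_samples"))
  mm <- utils::read.csv(p2)
  expect_named(mm, c("assay_id", "total_activity", "upper_activity",
                     "lower_activity", "prop_lower", "inactive_frames",
                     "resting_frames", "resting_seconds",
                     "valid_frames_proportion", "total_activity_full"))
})
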