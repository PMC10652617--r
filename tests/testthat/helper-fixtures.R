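## Shared fixtures: a small frame geometry and scene builders so unit tests
## run on compact videos; full-size 540 x 960 scenes are reserved for the
## end-to-end checks.

small_geometry <- function() {
  region_geometry(rbind(c(10, 10), c(230, 10), c(230, 310), c(10, 310)),
                  split_line_y = 160, frame_dims = c(240L, 320L))
}

## one mosquito orbiting in the upper half, one in the lower half of the
## small geometry, continuous motion with per-sample displacement above
## the blob diameter
small_scene <- function(duration = 12, noise_sd = 0, seed = 3,
                        n_movers = 2) {
  g <- small_geometry()
  twp <- seq(0, duration, by = 0.05)
  centres <- list(c(70, 80), c(160, 240), c(70, 240), c(160, 80))
  phases <- c(0, 2, 4, 1)
  trajs <- lapply(seq_len(n_movers), function(m)
    trajectory_spec(paste0("m", m),
                    victa:::rosette_waypoints(centres[[m]], twp,
                                              r0 = 25, ar = 8,
                                              phase = phases[m])))
  synthetic_scene(trajs, duration = duration, noise_sd = noise_sd,
                  seed = seed, geometry = g)
}

render_small_scene <- function(..., path = tempfile(fileext = ".fsv")) {
  generate_scene(small_scene(...), path)
}

## hand-built detections object for metrics tests: regular 0.1-s samples
## with prescribed per-sample counts and blob positions
fake_detections <- function(n_moving, blob_y = NULL, valid = NULL,
                            geometry = small_geometry(), interval = 0.1,
                            assay_id = "fake") {
  n <- length(n_moving)
  t <- (seq_len(n) - 1) * interval
  if (is.null(valid)) valid <- rep(TRUE, n)
  samples <- data.frame(sample = seq_len(n), t = t, n_moving = n_moving,
                        valid = valid, acclim = t < 5)
  blobs <- list()
  for (s in seq_len(n)) {
    k <- n_moving[s]
    if (k > 0) {
      y <- if (is.null(blob_y)) rep(50, k) else rep_len(blob_y[[s]], k)
      blobs[[length(blobs) + 1L]] <- data.frame(
        x = rep(100, k), y = y, area = rep(60, k), bb_x = 95, bb_y = y - 5,
        bb_w = 10, bb_h = 10, region = assign_region(y, geometry),
        sample = s, t = t[s], blob_index = seq_len(k))
    }
  }
  blobs <- if (length(blobs)) do.call(rbind, blobs)
  else data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                  bb_x = numeric(0), bb_y = numeric(0), bb_w = numeric(0),
                  bb_h = numeric(0), region = character(0),
                  sample = integer(0), t = numeric(0),
                  blob_index = integer(0))
  structure(list(assay_id = assay_id, samples = samples, blobs = blobs,
                 interval = interval, cfg = segmenter_config(),
                 geometry = geometry, video = NA_character_,
                 n_expected = n),
            class = "victa_detections")
}

## constant-background video file with optional dark square at fixed pos
write_static_video <- function(n_frames, w = 60, h = 80, fps = 30,
                               bg = 200, path = tempfile(fileext = ".fsv"),
                               square = NULL) {
  f <- matrix(bg, h, w)
  if (!is.null(square)) f[square$y + 1:square$size, square$x + 1:square$size] <- square$intensity
  write_video(replicate(n_frames, f, simplify = FALSE), path, fps = fps)
  path
}
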