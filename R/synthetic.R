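## Scripted synthetic cone-assay scenes with exact ground truth. A scene is
## five dark discs (the mosquitoes) moving over a brighter, slowly varying
## background inside the standardized 540 x 960 frame; trajectories are
## piecewise-linear through waypoints, optionally paused during resting
## intervals, rendered with a 2-px soft disc edge and optional i.i.d.
## Gaussian pixel noise. The generator emits the per-sample truth (centroid,
## moving flag, region) that every pipeline stage is validated against.
## Scenes are test fixtures, not biological flight models.

#' Script a single mosquito trajectory
#'
#' Waypoints define the path as a piecewise-linear curve; resting intervals
#' pause progress along it (position frozen at the interval start, motion
#' resuming continuously afterwards).
#'
#' @param mosquito_id identifier.
#' @param waypoints data frame with columns `t` (s), `x`, `y` (0-based px),
#'   time-sorted.
#' @param resting_intervals optional data frame with columns `t_start`,
#'   `t_end` (s), non-overlapping.
#' @param blob_diameter rendered disc diameter (px).
#' @param blob_intensity disc intensity (0-255), darker than the
#'   background.
#' @return a `victa_trajectory`.
#' @export
trajectory_spec <- function(mosquito_id, waypoints,
                            resting_intervals = NULL,
                            blob_diameter = 10, blob_intensity = 30) {
  wp <- as.data.frame(waypoints)
  stopifnot(all(c("t", "x", "y") %in% names(wp)), nrow(wp) >= 1,
            !is.unsorted(wp$t), blob_diameter > 0,
            blob_intensity >= 0, blob_intensity <= 255)
  if (!is.null(resting_intervals) && nrow(resting_intervals)) {
    ri <- as.data.frame(resting_intervals)
    stopifnot(all(c("t_start", "t_end") %in% names(ri)),
              all(ri$t_end > ri$t_start))
    ri <- ri[order(ri$t_start), , drop = FALSE]
    if (nrow(ri) > 1 && any(ri$t_start[-1] < ri$t_end[-nrow(ri)]))
      stop("resting intervals must not overlap")
  } else ri <- data.frame(t_start = numeric(0), t_end = numeric(0))
  structure(list(mosquito_id = mosquito_id, waypoints = wp,
                 resting_intervals = ri,
                 blob_diameter = blob_diameter,
                 blob_intensity = blob_intensity),
            class = "victa_trajectory")
}

## Map wall-clock time to path time: rests freeze progress.
warp_time <- function(t, rests) {
  if (!nrow(rests)) return(t)
  out <- t
  for (i in seq_len(nrow(rests)))
    out <- out - pmax(0, pmin(t, rests$t_end[i]) - rests$t_start[i])
  out
}

#' Evaluate a trajectory's position
#'
#' @param traj a [trajectory_spec()].
#' @param t vector of times (s).
#' @return data frame with columns `t`, `x`, `y`.
#' @export
trajectory_position <- function(traj, t) {
  te <- warp_time(t, traj$resting_intervals)
  wp <- traj$waypoints
  if (nrow(wp) == 1L) {
    x <- rep(wp$x, length(t)); y <- rep(wp$y, length(t))
  } else {
    x <- stats::approx(wp$t, wp$x, xout = te, rule = 2)$y
    y <- stats::approx(wp$t, wp$y, xout = te, rule = 2)$y
  }
  data.frame(t = t, x = x, y = y)
}

#' Define a synthetic cone-assay scene
#'
#' @param trajectories list of [trajectory_spec()]s (one per mosquito; the
#'   standard test has 5).
#' @param duration scene length in seconds (standard test: 180).
#' @param background_intensity background gray level (0-255), brighter than
#'   the mosquitoes.
#' @param background_drift linear background intensity change per second,
#'   emulating slow illumination drift.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise in
#'   intensity units (default 5, a plausible smartphone sensor level);
#'   0 renders noise-free.
#' @param seed RNG seed for the pixel noise; a scene renders identically
#'   for identical spec and seed.
#' @param geometry [region_geometry()] providing the frame dims and the
#'   region labels of the ground truth.
#' @param fps rendered frame rate.
#' @return a `victa_scene`.
#' @export
synthetic_scene <- function(trajectories, duration = 180,
                            background_intensity = 200,
                            background_drift = 0, noise_sd = 5, seed = 1,
                            geometry = default_cone_geometry(), fps = 30) {
  stopifnot(length(trajectories) >= 1, duration > 0, noise_sd >= 0,
            background_intensity >= 0, background_intensity <= 255,
            fps > 0)
  w <- geometry$frame_dims[1]; h <- geometry$frame_dims[2]
  for (tr in trajectories) {
    stopifnot(inherits(tr, "victa_trajectory"))
    r <- tr$blob_diameter / 2
    wp <- tr$waypoints
    if (any(wp$x < r) || any(wp$x > w - 1 - r) ||
        any(wp$y < r) || any(wp$y > h - 1 - r))
      stop("trajectory '", tr$mosquito_id, "' leaves the frame")
    if (nrow(tr$resting_intervals) &&
        any(tr$resting_intervals$t_end > duration))
      stop("resting interval beyond scene duration for '",
           tr$mosquito_id, "'")
  }
  structure(list(trajectories = trajectories,
                 n_mosquitoes = length(trajectories),
                 duration = duration,
                 background_intensity = background_intensity,
                 background_drift = background_drift, noise_sd = noise_sd,
                 seed = seed, geometry = geometry, fps = fps),
            class = "victa_scene")
}

#' @export
print.victa_scene <- function(x, ...) {
  cat("<victa_scene> ", x$n_mosquitoes, " mosquitoes, ", x$duration,
      " s at ", x$fps, " fps, ", x$geometry$frame_dims[1], "x",
      x$geometry$frame_dims[2], " px, noise sd ", x$noise_sd,
      "\n", sep = "")
  invisible(x)
}

#' Render a scene and emit its ground truth
#'
#' Writes the frame-stack video and computes the exact per-0.1-s-sample
#' truth: each mosquito's centroid, its moving flag (centroid displacement
#' from the previous sample greater than 1 px - the motion a
#' background-subtraction detector can see), and its upper/lower region
#' label. Rendering is fully deterministic for a fixed spec and seed.
#'
#' @param scene a [synthetic_scene()].
#' @param out_video output video path.
#' @param seed overrides the scene's noise seed.
#' @param interval ground-truth sampling interval (s).
#' @return a list with `asset` (the written `victa_video`) and `truth`
#'   (a `victa_truth`).
#' @export
generate_scene <- function(scene, out_video, seed = scene$seed,
                           interval = 0.1) {
  g <- scene$geometry
  w <- g$frame_dims[1]; h <- g$frame_dims[2]
  n_frames <- as.integer(round(scene$duration * scene$fps))
  tf <- (seq_len(n_frames) - 1L) / scene$fps
  pos <- lapply(scene$trajectories, trajectory_position, t = tf)
  cx <- vapply(pos, function(p) p$x, numeric(n_frames))
  cy <- vapply(pos, function(p) p$y, numeric(n_frames))
  cx <- matrix(cx, nrow = n_frames); cy <- matrix(cy, nrow = n_frames)
  radii <- vapply(scene$trajectories, function(tr) tr$blob_diameter / 2,
                  numeric(1))
  intens <- vapply(scene$trajectories, function(tr) tr$blob_intensity,
                   numeric(1))
  radius <- radii[1]; intensity <- intens[1]
  uniform <- length(unique(radii)) == 1L && length(unique(intens)) == 1L
  set.seed(seed)
  wr <- fsv_writer(out_video, w, h, scene$fps, n_frames)
  npix <- as.integer(w) * as.integer(h)
  for (i in seq_len(n_frames)) {
    bg <- scene$background_intensity + scene$background_drift * tf[i]
    frame <- matrix(bg, h, w)
    if (uniform) {
      draw_discs_cpp(frame, cx[i, ], cy[i, ], radius, intensity, 2)
    } else {
      for (m in seq_len(ncol(cx)))
        draw_discs_cpp(frame, cx[i, m], cy[i, m], radii[m], intens[m], 2)
    }
    if (scene$noise_sd > 0)
      frame <- frame + stats::rnorm(npix, 0, scene$noise_sd)
    wr$write_frame(frame)
  }
  asset <- wr$close()
  list(asset = asset, truth = scene_truth(scene, interval))
}

#' Ground truth of a scene without rendering it
#'
#' Evaluates the scripted trajectories on the 0.1-s sample grid (the same
#' nearest-frame rule the analysis sampler uses) and returns each
#' mosquito's centroid, moving flag (displacement from the previous sample
#' greater than 1 px) and region label per sample. [generate_scene()]
#' returns exactly this truth alongside the rendered video.
#'
#' @param scene a [synthetic_scene()].
#' @param interval sampling interval (s).
#' @return a `victa_truth`.
#' @export
scene_truth <- function(scene, interval = 0.1) {
  g <- scene$geometry
  n_frames <- as.integer(round(scene$duration * scene$fps))
  fake <- new_video_asset(NA_character_, g$frame_dims[1], g$frame_dims[2],
                          scene$fps, n_frames)
  idx <- sample_indices(fake, interval)
  ts <- idx / scene$fps
  n_m <- scene$n_mosquitoes
  truth <- do.call(rbind, lapply(seq_len(n_m), function(m) {
    p <- trajectory_position(scene$trajectories[[m]], ts)
    disp <- c(0, sqrt(diff(p$x)^2 + diff(p$y)^2))
    data.frame(sample = seq_along(idx), t = ts,
               mosquito_id = scene$trajectories[[m]]$mosquito_id,
               x = p$x, y = p$y,
               moving = c(FALSE, disp[-1] > 1),
               region = assign_region(p$y, g),
               stringsAsFactors = FALSE)
  }))
  truth <- truth[order(truth$sample, truth$mosquito_id), ]
  rownames(truth) <- NULL
  structure(list(records = truth, interval = interval,
                 n_samples = length(idx), n_mosquitoes = n_m,
                 geometry = g, duration = scene$duration),
            class = "victa_truth")
}

#' @export
print.victa_truth <- function(x, ...) {
  cat("<victa_truth> ", x$n_mosquitoes, " mosquitoes x ", x$n_samples,
      " samples at ", x$interval, " s\n", sep = "")
  invisible(x)
}

#' Per-sample moving counts implied by the ground truth
#'
#' @param truth a `victa_truth`.
#' @return data frame `sample`, `t`, `n_moving`, `n_upper`, `n_lower`
#'   (moving mosquitoes per region).
#' @export
truth_sample_counts <- function(truth) {
  r <- truth$records
  n <- truth$n_samples
  cnt <- function(sel) {
    x <- tapply(rep(1L, sum(sel)), r$sample[sel], sum)
    out <- integer(n)
    if (length(x)) out[as.integer(names(x))] <- as.integer(x)
    out
  }
  data.frame(sample = seq_len(n),
             t = r$t[match(seq_len(n), r$sample)],
             n_moving = cnt(r$moving),
             n_upper = cnt(r$moving & r$region == "upper"),
             n_lower = cnt(r$moving & r$region == "lower"))
}

#' Ground-truth epoch table
#'
#' Aggregates the truth's moving flags into the same 5-s epoch windows the
#' pipeline uses, for exact comparison against [aggregate_epochs()].
#'
#' @inheritParams aggregate_epochs
#' @param truth a `victa_truth`.
#' @return a data frame shaped like a `victa_epochs` table.
#' @export
truth_epochs <- function(truth, epoch_length = 5, n_epochs = 35,
                         exclude = 5) {
  sc <- truth_sample_counts(truth)
  k <- round(sc$t / truth$interval)
  per_epoch <- floor(epoch_length / truth$interval + 1e-9)
  k0 <- round(exclude / truth$interval)
  epoch <- floor((k - k0) / per_epoch) + 1
  ok <- k >= k0 & epoch <= n_epochs
  agg <- function(v) {
    x <- tapply(v[ok], epoch[ok], sum)
    r <- integer(n_epochs); r[as.integer(names(x))] <- as.integer(x); r
  }
  data.frame(index = seq_len(n_epochs),
             t_start = exclude + (seq_len(n_epochs) - 1) * epoch_length,
             t_end = exclude + seq_len(n_epochs) * epoch_length,
             activity_total = agg(sc$n_moving),
             activity_upper = agg(sc$n_upper),
             activity_lower = agg(sc$n_lower),
             inactive_samples = agg(as.integer(sc$n_moving == 0L)),
             valid_samples = agg(rep(1L, nrow(sc))))
}

#' Ground-truth assay metrics
#'
#' The behavioural metrics implied by the scripted truth, mirroring
#' [summarize_assay()]: epoch-based totals, proportion of lower-region
#' activity, strict resting frames (no mosquito moving, first sample
#' excluded) and seconds.
#'
#' @inheritParams truth_epochs
#' @return a one-row data frame.
#' @export
truth_metrics <- function(truth, epoch_length = 5, n_epochs = 35,
                          exclude = 5) {
  ep <- truth_epochs(truth, epoch_length, n_epochs, exclude)
  sc <- truth_sample_counts(truth)
  resting <- sum(sc$n_moving[-1L] == 0L)
  total <- sum(ep$activity_total)
  data.frame(total_activity = total,
             upper_activity = sum(ep$activity_upper),
             lower_activity = sum(ep$activity_lower),
             prop_lower = if (total > 0)
               sum(ep$activity_lower) / total else NA_real_,
             inactive_frames = sum(ep$inactive_samples),
             resting_frames = resting,
             resting_seconds = resting * truth$interval,
             total_activity_full = sum(sc$n_moving))
}

#' Write ground truth as delimited text
#'
#' One row per (sample, mosquito), mirroring the detection-log schema plus
#' the truth columns.
#'
#' @param truth a `victa_truth`.
#' @param path output CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth$records, path, row.names = FALSE)
  invisible(path)
}

## --- parametric paths used by the presets -------------------------------

## Non-closing rosette: circular motion with a slowly breathing radius
## (incommensurate frequencies), so speed is bounded below and the path
## never retraces itself exactly.
rosette_waypoints <- function(centre, t, r0 = 25, ar = 8, omega = 6.5,
                              phase = 0) {
  omega2 <- omega * 2 / (1 + sqrt(5))
  r <- r0 + ar * sin(omega2 * t + 1.7 * phase)
  data.frame(t = t,
             x = centre[1] + r * cos(omega * t + phase),
             y = centre[2] + r * sin(omega * t + phase))
}

## Stadium-shaped closed circuit (two straights joined by semicircles),
## traversed at constant speed: the crawl along the net surface.
racetrack_waypoints <- function(centre, t, half_len = 75, rho = 15,
                                speed = 125, phase_frac = 0) {
  per <- 4 * half_len + 2 * pi * rho
  s <- (speed * t + phase_frac * per) %% per
  x <- numeric(length(s)); y <- numeric(length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    if (si < 2 * half_len) {                 # top straight, rightward
      x[i] <- centre[1] - half_len + si; y[i] <- centre[2] - rho
    } else if (si < 2 * half_len + pi * rho) {  # right semicircle
      a <- (si - 2 * half_len) / rho
      x[i] <- centre[1] + half_len + rho * sin(a)
      y[i] <- centre[2] - rho * cos(a)
    } else if (si < 4 * half_len + pi * rho) {  # bottom straight, leftward
      x[i] <- centre[1] + half_len - (si - 2 * half_len - pi * rho)
      y[i] <- centre[2] + rho
    } else {                                  # left semicircle
      a <- (si - 4 * half_len - pi * rho) / rho
      x[i] <- centre[1] - half_len - rho * sin(a)
      y[i] <- centre[2] + rho * cos(a)
    }
  }
  data.frame(t = t, x = x, y = y)
}

#' Catalogue of preset scenes
#'
#' Named scenes mimicking the behavioural phenotypes seen in cone tests:
#'
#' * `crawler` - all five mosquitoes circuit continuously along the net
#'   surface at the cone base (untreated-net-like); ground-truth
#'   `prop_lower > 0.8` by construction.
#' * `dispersed` - five mosquitoes in continuous flight spread through the
#'   cone, three in the upper and two in the lower half (treated-net-like);
#'   ground-truth `prop_lower < 0.5`.
#' * `high_rest` - all five rest motionless for the first 100 s, then fly;
#'   ground-truth resting exceeds 90 s (resistant-strain-like).
#' * `mixed` - two mosquitoes rest for the whole test while three fly
#'   continuously.
#'
#' Flying mosquitoes follow non-retracing rosette or stadium-circuit paths
#' with per-sample displacement above the blob diameter and pairwise
#' separation of at least three blob diameters, the regime in which a
#' background-subtraction detector can be held to exact ground-truth
#' recovery. All presets use the default cone geometry, 5 mosquitoes of
#' 10 px diameter, and the standard 180-s / 30-fps format.
#'
#' @param duration scene duration (s).
#' @param noise_sd pixel-noise level passed to every scene (default the
#'   simulator's standard 5; pass 0 for noise-free renders).
#' @param seed noise seed stored in each scene.
#' @return named list of [synthetic_scene()]s.
#' @export
preset_scenes <- function(duration = 180, noise_sd = 5, seed = 1) {
  g <- default_cone_geometry()
  twp <- seq(0, duration, by = 0.05)
  rosettes <- list(A = c(270, 335), B = c(215, 475), C = c(325, 475),
                   D = c(200, 680), E = c(340, 790))
  phases <- c(A = 0, B = 1.3, C = 2.6, D = 3.9, E = 5.2)
  ros_traj <- function(name, id)
    trajectory_spec(id, rosette_waypoints(rosettes[[name]], twp,
                                          phase = phases[[name]]))
  scene <- function(trajs) synthetic_scene(trajs, duration = duration,
                                           noise_sd = noise_sd,
                                           seed = seed, geometry = g)

  crawler <- scene(lapply(1:5, function(m)
    trajectory_spec(paste0("m", m),
                    racetrack_waypoints(c(270, 620 + 60 * (m - 1)), twp,
                                        phase_frac = (m - 1) / 5))))

  dispersed <- scene(mapply(ros_traj, c("A", "B", "C", "D", "E"),
                            paste0("m", 1:5), SIMPLIFY = FALSE))

  ## rest at the path start for the first 100 s, then fly
  high_rest <- scene(lapply(1:5, function(m) {
    name <- c("A", "B", "C", "D", "E")[m]
    tr <- trajectory_spec(paste0("m", m),
                          rosette_waypoints(rosettes[[name]], twp,
                                            phase = phases[[name]]),
                          resting_intervals = data.frame(
                            t_start = 0, t_end = min(100, duration)))
    tr
  }))

  mixed <- scene(c(
    list(trajectory_spec("m1", data.frame(t = 0, x = 270, y = 620)),
         trajectory_spec("m2", data.frame(t = 0, x = 250, y = 870))),
    mapply(ros_traj, c("A", "C", "E"), paste0("m", 3:5),
           SIMPLIFY = FALSE)))

  list(crawler = crawler, dispersed = dispersed, high_rest = high_rest,
       mixed = mixed)
}

#' Generate a synthetic post-exposure life-history table
#'
#' Plausible per-mosquito records for testing the metrics/life-history
#' merge: feeding at 1 and 24 h post-exposure (the 24-h offer only made to
#' mosquitoes that did not feed at 1 h), excreted haematin for fed
#' individuals, wing length, and daily-mortality-derived longevity.
#' Synthetic fixture data, not biological output.
#'
#' @param assay_ids assay identifiers; `n_per_assay` mosquitoes are
#'   generated for each (5 cohabit one cone test).
#' @param n_per_assay mosquitoes per assay.
#' @param seed RNG seed.
#' @param treatment,strain labels recycled across assays.
#' @return data frame of life-history records.
#' @export
simulate_life_history <- function(assay_ids, n_per_assay = 5, seed = 1,
                                  treatment = c("UT", "P2", "P3", "OS",
                                                "IG2"),
                                  strain = c("KS", "NG", "BF", "VK7")) {
  set.seed(seed)
  n_assay <- length(assay_ids)
  n <- n_assay * n_per_assay
  aid <- rep(assay_ids, each = n_per_assay)
  trt <- rep(rep_len(treatment, n_assay), each = n_per_assay)
  str <- rep(rep_len(strain, n_assay), each = n_per_assay)
  fed_1h <- stats::runif(n) < 0.6
  fed_24h <- ifelse(fed_1h, NA, stats::runif(n) < 0.4)
  fed <- fed_1h | (!is.na(fed_24h) & fed_24h)
  haematin <- ifelse(fed, round(stats::runif(n, 1.76, 30), 2), NA)
  death_day <- 1L + stats::rpois(n, 12)
  data.frame(mosquito_id = sprintf("%s_m%d", aid,
                                   rep(seq_len(n_per_assay), n_assay)),
             assay_id = aid, strain = str, treatment = trt,
             fed_1h = fed_1h, fed_24h = fed_24h, haematin = haematin,
             wing_length = round(stats::rnorm(n, 3.0, 0.15), 2),
             death_day = death_day, dead_24h = death_day <= 1L,
             stringsAsFactors = FALSE)
}
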