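## Moving-mosquito detection: per-pixel Gaussian-mixture background
## segmentation of the 0.1-s sample stream, morphological regularisation of
## the foreground mask, and contour (connected-component) extraction with
## area filtering. No identity tracking is attempted: each 0.1-s sample
## yields the set of currently moving contours.

#' Segmentation configuration
#'
#' Parameters of the Gaussian-mixture background model and of the
#' morphological contour regularisation. Defaults are tuned for mosquitoes
#' filmed at the standardized 540 x 960 px / 30 fps geometry.
#'
#' @param history background memory in decoded frames (150 frames is about
#'   5 s at 30 fps, matching the acclimatisation window). The model consumes
#'   the 0.1-s sample stream, so the automatic learning rate per sample is
#'   `sample_stride / history`.
#' @param variance_threshold squared-Mahalanobis match threshold (a pixel
#'   matches a mode when its squared deviation is below
#'   `variance_threshold` times the mode variance).
#' @param learning_rate fixed per-sample learning rate in (0, 1], or `NA`
#'   for automatic (1 / samples seen, floored at the history-derived rate).
#' @param open_kernel,close_kernel diameters (px) of the disc structuring
#'   elements for the morphological opening (speck removal) and closing
#'   (hole filling) of the foreground mask.
#' @param min_area,max_area retained contour area bounds (px^2).
#' @param max_movers maximum number of movers per sample; the cone test
#'   holds five mosquitoes.
#' @param acclim_window seconds at the start of the test during which the
#'   background model is still acclimatising; samples are flagged and
#'   excluded from epoch aggregation.
#' @param n_modes Gaussian modes per pixel.
#' @param var_init,var_min,var_max initial and clamping variances for modes
#'   (squared intensity units).
#' @param background_ratio cumulative weight defining the background mode
#'   set.
#' @param median_radius radius of the pre-segmentation median blur (1 gives
#'   the standard 3 x 3 filter; 0 disables).
#' @return a `victa_config` list.
#' @export
segmenter_config <- function(history = 150, variance_threshold = 16,
                             learning_rate = NA, open_kernel = 3,
                             close_kernel = 5, min_area = 20,
                             max_area = 2000, max_movers = 5,
                             acclim_window = 5, n_modes = 3,
                             var_init = 225, var_min = 4,
                             var_max = 5 * var_init,
                             background_ratio = 0.9, median_radius = 1) {
  stopifnot(history > 0, variance_threshold > 0,
            is.na(learning_rate) ||
              (learning_rate > 0 && learning_rate <= 1),
            open_kernel >= 1, close_kernel >= 1,
            min_area < max_area, min_area >= 0, max_movers >= 1,
            acclim_window >= 0, n_modes >= 1,
            var_init > 0, var_min > 0, var_max >= var_init,
            background_ratio > 0, background_ratio < 1, median_radius >= 0)
  structure(list(history = history,
                 variance_threshold = variance_threshold,
                 learning_rate = learning_rate,
                 open_kernel = as.integer(open_kernel),
                 close_kernel = as.integer(close_kernel),
                 min_area = min_area, max_area = max_area,
                 max_movers = as.integer(max_movers),
                 acclim_window = acclim_window,
                 n_modes = as.integer(n_modes), var_init = var_init,
                 var_min = var_min, var_max = var_max,
                 background_ratio = background_ratio,
                 median_radius = as.integer(median_radius)),
            class = "victa_config")
}

#' @export
print.victa_config <- function(x, ...) {
  cat("<victa_config> GMM history", x$history, "frames, varThreshold",
      x$variance_threshold, "| open", x$open_kernel, "close", x$close_kernel,
      "| area", x$min_area, "-", x$max_area, "px^2 | max movers",
      x$max_movers, "\n")
  invisible(x)
}

#' Read / write a segmentation configuration file
#'
#' YAML key-value file mirroring the fields of [segmenter_config()]; absent
#' keys fall back to the defaults.
#'
#' @param path file path.
#' @return `read_segmenter_config` returns a `victa_config`.
#' @export
read_segmenter_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(segmenter_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(segmenter_config, vals)
}

#' @param cfg a `victa_config` to serialize.
#' @rdname read_segmenter_config
#' @export
write_segmenter_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

disc_kernel <- function(size) {
  k <- EBImage::makeBrush(if (size %% 2 == 1) size else size + 1L, "disc")
  k > 0
}

#' Preprocess a frame before background segmentation
#'
#' Denoising applied to each single-channel frame ahead of the
#' Gaussian-mixture update: a 3 x 3 median blur followed by a grayscale
#' morphological opening with the `open_kernel` disc, which removes bright
#' specks smaller than the structuring element while leaving larger
#' structures (and all dark structures, i.e. mosquitoes on a brighter
#' background) intact. Dimensions are preserved.
#'
#' @param frame `height x width` intensity matrix (0-255).
#' @param cfg a [segmenter_config()].
#' @return the denoised frame.
#' @export
preprocess_frame <- function(frame, cfg = segmenter_config()) {
  stopifnot(is.matrix(frame))
  out <- frame
  if (cfg$median_radius == 1L) {
    out <- median3_cpp(out)
  } else if (cfg$median_radius > 1L) {
    img <- EBImage::Image(t(out) / 255)
    out <- t(EBImage::imageData(
      EBImage::medianFilter(img, cfg$median_radius))) * 255
  }
  if (cfg$open_kernel > 1L) {
    k <- disc_kernel(cfg$open_kernel)
    out <- morph_cpp(morph_cpp(out, k, FALSE), k, TRUE)
  }
  out
}

#' Create a background-model state
#'
#' Allocates the per-pixel Gaussian-mixture state for a frame geometry. The
#' model initializes itself from the first frame passed to
#' [update_and_mask()]; detections during the acclimatisation window are
#' unreliable and flagged downstream.
#'
#' @param dims `c(width, height)` of the frames the model will consume.
#' @param cfg a [segmenter_config()].
#' @param sample_stride decoded frames advanced per model update (3 when
#'   sampling 30-fps footage at 0.1 s); converts `history` from decoded
#'   frames to samples for the automatic learning rate.
#' @return an environment holding the model state.
#' @export
new_background_model <- function(dims, cfg = segmenter_config(),
                                 sample_stride = 1) {
  npix <- as.integer(dims[1]) * as.integer(dims[2])
  stopifnot(npix > 0, sample_stride >= 1)
  e <- new.env(parent = emptyenv())
  e$dims <- as.integer(dims)
  e$w <- matrix(0, npix, cfg$n_modes)
  e$mu <- matrix(0, npix, cfg$n_modes)
  e$var <- matrix(cfg$var_init, npix, cfg$n_modes)
  e$n_seen <- 0L
  e$history_samples <- max(1, cfg$history / sample_stride)
  class(e) <- "victa_bgmodel"
  e
}

#' Advance the background model and classify foreground pixels
#'
#' Applies one Gaussian-mixture update (match, weight/mean/variance update,
#' weakest-mode replacement, weight renormalisation) and returns the
#' foreground mask. The first frame initializes the model (single mode per
#' pixel centred on the observed intensity), so early masks are unreliable
#' until the model has acclimatised.
#'
#' @param model a state from [new_background_model()].
#' @param frame `height x width` intensity matrix matching the model dims.
#' @param cfg the same [segmenter_config()] the model was created with.
#' @return binary `height x width` matrix (1 = moving foreground).
#' @export
update_and_mask <- function(model, frame, cfg = segmenter_config()) {
  if (!inherits(model, "victa_bgmodel"))
    stop("model must be created with new_background_model()")
  h <- model$dims[2]; w <- model$dims[1]
  if (!is.matrix(frame) || nrow(frame) != h || ncol(frame) != w)
    stop("frame dims do not match model dims")
  x <- as.numeric(frame)
  if (model$n_seen == 0L) {
    model$mu[, 1] <- x
    model$w[, 1] <- 1
    model$n_seen <- 1L
    return(matrix(0L, h, w))
  }
  model$n_seen <- model$n_seen + 1L
  alpha <- if (is.na(cfg$learning_rate))
    1 / min(model$n_seen, model$history_samples)
  else cfg$learning_rate
  mask <- gmm_update_cpp(model$w, model$mu, model$var, x, alpha,
                         cfg$variance_threshold, cfg$var_init,
                         cfg$var_min, cfg$var_max, cfg$background_ratio)
  matrix(mask, h, w)
}

#' Extract moving-mosquito contours from a foreground mask
#'
#' Regularises the mask (morphological opening with the `open_kernel` disc
#' to drop noise specks, then closing with the `close_kernel` disc to fill
#' holes), labels connected components, filters them to
#' `[min_area, max_area]`, keeps those whose centroid lies inside the cone
#' ROI, and if more than `max_movers` remain keeps the largest. Blobs are
#' returned in descending area order with 0-based centroid coordinates and
#' their upper/lower region label.
#'
#' @param mask binary `height x width` matrix from [update_and_mask()].
#' @param cfg a [segmenter_config()].
#' @param geometry a [region_geometry()] whose frame dims match the mask.
#' @return data frame with columns `x`, `y` (centroid px), `area` (px^2),
#'   `bb_x`, `bb_y`, `bb_w`, `bb_h` (bounding box), `region`.
#' @export
extract_movers <- function(mask, cfg, geometry) {
  h <- nrow(mask); w <- ncol(mask)
  if (w != geometry$frame_dims[1] || h != geometry$frame_dims[2])
    stop("mask dims do not match geometry frame dims")
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      bb_x = numeric(0), bb_y = numeric(0),
                      bb_w = numeric(0), bb_h = numeric(0),
                      region = character(0))
  if (!any(mask > 0)) return(empty)
  m <- mask
  if (cfg$open_kernel > 1L) {
    k <- disc_kernel(cfg$open_kernel)
    m <- morph_cpp(morph_cpp(m, k, FALSE), k, TRUE)
  }
  if (cfg$close_kernel > 1L) {
    k <- disc_kernel(cfg$close_kernel)
    m <- morph_cpp(morph_cpp(m, k, TRUE), k, FALSE)
  }
  if (!any(m > 0)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m)))
  idx <- which(lab > 0)
  if (!length(idx)) return(empty)
  lv <- lab[idx]
  rows <- ((idx - 1L) %% h)          # 0-based y
  cols <- ((idx - 1L) %/% h)         # 0-based x
  area <- tabulate(lv)
  keep <- which(area >= cfg$min_area & area <= cfg$max_area)
  if (!length(keep)) return(empty)
  ## rowsum orders by sorted unique label; labels from bwlabel are 1..L
  sums_x <- rowsum(cols, lv)[, 1]
  sums_y <- rowsum(rows, lv)[, 1]
  labs <- as.integer(rownames(rowsum(cols, lv)))
  df <- data.frame(label = labs,
                   x = sums_x / area[labs], y = sums_y / area[labs],
                   area = area[labs])
  bb <- t(vapply(labs, function(l) {
    r <- rows[lv == l]; c <- cols[lv == l]
    c(min(c), min(r), max(c) - min(c) + 1, max(r) - min(r) + 1)
  }, numeric(4)))
  df$bb_x <- bb[, 1]; df$bb_y <- bb[, 2]; df$bb_w <- bb[, 3]
  df$bb_h <- bb[, 4]
  df <- df[df$label %in% keep, , drop = FALSE]
  if (!nrow(df)) return(empty)
  inside <- point_in_roi(df$x, df$y, geometry)
  df <- df[inside, , drop = FALSE]
  if (!nrow(df)) return(empty)
  df <- df[order(-df$area), , drop = FALSE]
  if (nrow(df) > cfg$max_movers) df <- df[seq_len(cfg$max_movers), ,
                                          drop = FALSE]
  df$region <- assign_region(df$y, geometry)
  df$label <- NULL
  rownames(df) <- NULL
  df
}

#' Detect moving mosquitoes across a whole assay video
#'
#' Runs the full detection chain on the 0.1-s sample stream of a
#' standardized assay video: preprocessing, Gaussian-mixture background
#' update, mask regularisation and contour extraction. Fully deterministic:
#' identical video and configuration give identical detection logs.
#'
#' @param asset a `victa_video` or path to a frame-stack video.
#' @param cfg a [segmenter_config()].
#' @param geometry a [region_geometry()] matching the video dims.
#' @param assay_id identifier recorded in the detection log.
#' @param interval sampling interval in seconds (default 0.1).
#' @return a `victa_detections` object: `$samples` (one row per 0.1-s
#'   sample: `sample`, `t`, `n_moving`, `valid`, `acclim`), `$blobs` (one
#'   row per detected blob) and metadata.
#' @export
detect_assay <- function(asset, cfg = segmenter_config(),
                         geometry = default_cone_geometry(),
                         assay_id = "assay", interval = 0.1) {
  if (is.character(asset)) asset <- video_info(asset)
  if (asset$width != geometry$frame_dims[1] ||
      asset$height != geometry$frame_dims[2])
    stop("video dims (", asset$width, "x", asset$height,
         ") do not match geometry frame dims")
  stride <- max(1, round(interval * asset$fps))
  model <- new_background_model(c(asset$width, asset$height), cfg,
                                sample_stride = stride)
  samples <- list(); blobs <- list()
  i <- 0L
  stream_samples(asset, function(t, pixels, valid) {
    i <<- i + 1L
    if (valid) {
      fr <- preprocess_frame(pixels, cfg)
      mask <- update_and_mask(model, fr, cfg)
      mv <- extract_movers(mask, cfg, geometry)
    } else {
      mv <- extract_movers(matrix(0L, asset$height, asset$width), cfg,
                           geometry)
    }
    samples[[i]] <<- data.frame(sample = i, t = t, n_moving = nrow(mv),
                                valid = valid,
                                acclim = t < cfg$acclim_window)
    if (nrow(mv)) {
      mv$sample <- i; mv$t <- t; mv$blob_index <- seq_len(nrow(mv))
      blobs[[length(blobs) + 1L]] <<- mv
    }
    NULL
  }, interval = interval)
  samples <- do.call(rbind, samples)
  blobs <- if (length(blobs)) do.call(rbind, blobs)
  else data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                  bb_x = numeric(0), bb_y = numeric(0), bb_w = numeric(0),
                  bb_h = numeric(0), region = character(0),
                  sample = integer(0), t = numeric(0),
                  blob_index = integer(0))
  rownames(blobs) <- NULL
  structure(list(assay_id = assay_id, samples = samples, blobs = blobs,
                 interval = interval, cfg = cfg, geometry = geometry,
                 video = asset$source_path,
                 n_expected = length(sample_indices(asset, interval))),
            class = "victa_detections")
}

#' @export
print.victa_detections <- function(x, ...) {
  cat("<victa_detections> assay '", x$assay_id, "': ", nrow(x$samples),
      " samples at ", x$interval, " s, ", nrow(x$blobs),
      " blob detections\n", sep = "")
  invisible(x)
}

#' Write / read a detection log
#'
#' Delimited text, one row per (sample, blob) with columns `assay_id`, `t`,
#' `blob_index`, `x`, `y`, `area`, `region_label`, `n_moving`, `valid`;
#' samples with no detections contribute one row with empty blob fields so
#' every 0.1-s sample appears in the log.
#'
#' @param det a `victa_detections`.
#' @param path output CSV path.
#' @export
write_detections <- function(det, path) {
  s <- det$samples
  b <- det$blobs
  base <- data.frame(assay_id = det$assay_id, t = s$t,
                     blob_index = NA_integer_, x = NA_real_, y = NA_real_,
                     area = NA_real_, region_label = NA_character_,
                     n_moving = s$n_moving, valid = s$valid,
                     sample = s$sample)
  if (nrow(b)) {
    rows <- data.frame(assay_id = det$assay_id, t = b$t,
                       blob_index = b$blob_index, x = round(b$x, 3),
                       y = round(b$y, 3), area = b$area,
                       region_label = b$region,
                       n_moving = s$n_moving[b$sample],
                       valid = s$valid[b$sample], sample = b$sample)
    base <- rbind(base[!(base$sample %in% b$sample), ], rows)
  }
  base <- base[order(base$sample, base$blob_index), ]
  base$sample <- NULL
  utils::write.csv(base, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param path CSV path written by [write_detections()].
#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
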