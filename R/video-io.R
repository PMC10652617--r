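## Frame-stack video container (.fsv)
##
## Cone-assay footage is handled as a documented, codec-free "frame stack":
## a single ASCII header line
##
##   VICTAFSV 1 <width> <height> <fps> <n_frames> <channels>\n
##
## followed by n_frames frames of 8-bit pixels, gzip-compressed as a single
## stream. Each frame is a height x width intensity grid (0-255) stored
## column-major; 3-channel frames store three such planes (R, G, B) in
## sequence. All standardized analysis footage is single-channel, 540 x 960
## px at 30 fps.

FSV_MAGIC <- "VICTAFSV"

STD_WIDTH <- 540L
STD_HEIGHT <- 960L
STD_FPS <- 30

new_video_asset <- function(source_path, width, height, fps, n_frames,
                            channels = 1L) {
  structure(
    list(source_path = source_path, width = as.integer(width),
         height = as.integer(height), fps = fps,
         n_frames = as.integer(n_frames),
         duration = n_frames / fps, channels = as.integer(channels)),
    class = "victa_video")
}

#' @export
print.victa_video <- function(x, ...) {
  cat("<victa_video> ", x$width, "x", x$height, " px, ",
      format(x$fps), " fps, ", x$n_frames, " frames (",
      format(round(x$duration, 2)), " s)\n  ", x$source_path, "\n", sep = "")
  invisible(x)
}

#' Open a frame-stack video writer
#'
#' Returns a writer handle to which frames are appended one at a time.
#' Frames must be `height x width` numeric matrices with intensities in
#' 0-255; values are truncated to 8-bit on write.
#'
#' @param path output file path.
#' @param width,height frame dimensions in pixels.
#' @param fps frames per second.
#' @param n_frames total number of frames that will be written.
#' @param channels 1 (grayscale) or 3 (RGB; pass a list of three matrices
#'   per frame).
#' @return a list with functions `write_frame(frame)` and `close()`; `close`
#'   returns the [video asset][video_info] describing the written file.
#' @export
fsv_writer <- function(path, width, height, fps, n_frames, channels = 1L) {
  stopifnot(width > 0, height > 0, fps > 0, n_frames >= 0,
            channels %in% c(1L, 3L))
  con <- gzfile(path, "wb", compression = 1)
  header <- sprintf("%s 1 %d %d %.10g %d %d\n", FSV_MAGIC,
                    as.integer(width), as.integer(height), fps,
                    as.integer(n_frames), as.integer(channels))
  writeBin(charToRaw(header), con)
  written <- 0L
  put_plane <- function(m) {
    if (!is.matrix(m) || nrow(m) != height || ncol(m) != width)
      stop("frame must be a ", height, " x ", width, " matrix")
    v <- as.integer(m)
    v[v < 0L] <- 0L; v[v > 255L] <- 255L
    writeBin(as.raw(v), con)
  }
  list(
    write_frame = function(frame) {
      if (channels == 1L) put_plane(frame)
      else { stopifnot(is.list(frame), length(frame) == 3L)
             for (p in frame) put_plane(p) }
      written <<- written + 1L
      invisible(NULL)
    },
    close = function() {
      close(con)
      if (written != n_frames)
        warning("declared ", n_frames, " frames but wrote ", written)
      new_video_asset(path, width, height, fps, n_frames, channels)
    })
}

#' Write a short video from a list of frames
#'
#' Convenience wrapper around [fsv_writer()] for in-memory footage (test
#' fixtures, short clips). Long recordings should be streamed through
#' [fsv_writer()] directly.
#'
#' @param frames list of `height x width` matrices (intensities 0-255).
#' @param path output path.
#' @param fps frames per second.
#' @return the [video asset][video_info] describing the file, invisibly.
#' @export
write_video <- function(frames, path, fps = STD_FPS) {
  stopifnot(length(frames) >= 1)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  wr <- fsv_writer(path, w, h, fps, length(frames))
  for (f in frames) wr$write_frame(f)
  invisible(wr$close())
}

read_fsv_header <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("not a frame-stack video: truncated header")
    if (b == charToRaw("\n")) break
    bytes <- c(bytes, b)
    if (length(bytes) > 128L) stop("not a frame-stack video: bad header")
  }
  fields <- strsplit(rawToChar(bytes), " ", fixed = TRUE)[[1]]
  if (length(fields) != 7L || fields[1] != FSV_MAGIC || fields[2] != "1")
    stop("not a frame-stack video (unrecognized header)")
  list(width = as.integer(fields[3]), height = as.integer(fields[4]),
       fps = as.numeric(fields[5]), n_frames = as.integer(fields[6]),
       channels = as.integer(fields[7]))
}

#' Probe a frame-stack video
#'
#' Reads the header and returns the video's declared geometry and timing.
#'
#' @param path path to a `.fsv` file.
#' @return a `victa_video` object: `source_path`, `width`, `height` (px),
#'   `fps`, `n_frames`, `duration` (s), `channels`.
#' @export
video_info <- function(path) {
  if (!file.exists(path)) stop("no such video file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  h <- read_fsv_header(con)
  if (h$n_frames == 0L) stop("empty video (zero frames): ", path)
  new_video_asset(path, h$width, h$height, h$fps, h$n_frames, h$channels)
}

## Sequential frame reader. next_frame() returns a height x width numeric
## matrix (multi-channel input is collapsed to luma), or NULL past the end
## of the declared stream. A frame that cannot be fully decoded (truncated
## stream) is returned as NULL with ok() reporting FALSE thereafter.
frame_reader <- function(path) {
  con <- gzfile(path, "rb")
  h <- read_fsv_header(con)
  npix <- h$width * h$height
  pos <- 0L
  truncated <- FALSE
  read_plane <- function() {
    v <- readBin(con, "raw", npix)
    if (length(v) < npix) return(NULL)
    matrix(as.integer(v), nrow = h$height, ncol = h$width)
  }
  list(
    header = h,
    next_frame = function() {
      if (pos >= h$n_frames || truncated) return(NULL)
      if (h$channels == 1L) {
        m <- read_plane()
      } else {
        r <- read_plane(); g <- read_plane(); b <- read_plane()
        m <- if (is.null(r) || is.null(g) || is.null(b)) NULL
             else rgb_to_gray(r, g, b)
      }
      if (is.null(m)) { truncated <<- TRUE; return(NULL) }
      pos <<- pos + 1L
      m
    },
    pos = function() pos,
    truncated = function() truncated,
    close = function() close(con))
}

#' Convert an RGB frame to grayscale
#'
#' Standard Rec. 601 luma weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param r,g,b numeric matrices of equal dimension, intensities 0-255.
#' @return a numeric matrix of luma intensities.
#' @export
rgb_to_gray <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

## Letterbox a frame into target dims: scale to fit preserving aspect,
## centre, pad with zero intensity. Uses bilinear resampling.
letterbox_frame <- function(frame, target_w, target_h) {
  h <- nrow(frame); w <- ncol(frame)
  if (w == target_w && h == target_h) return(frame)
  s <- min(target_w / w, target_h / h)
  nw <- max(1L, as.integer(round(w * s)))
  nh <- max(1L, as.integer(round(h * s)))
  ## EBImage images are x-major; transpose in and out
  img <- EBImage::Image(t(frame) / 255)
  rs <- t(EBImage::imageData(EBImage::resize(img, w = nw, h = nh))) * 255
  out <- matrix(0, target_h, target_w)
  i0 <- (target_h - nh) %/% 2L
  j0 <- (target_w - nw) %/% 2L
  out[i0 + seq_len(nh), j0 + seq_len(nw)] <- rs
  out
}

#' Standardize a video to the analysis format
#'
#' Converts any decodable frame-stack video to the canonical analysis
#' geometry: 540 x 960 px at 30 fps, single channel. Aspect-ratio
#' mismatches are letterboxed (scale to fit, centre, zero padding) so that
#' cone geometry calibrations remain valid; frame rates are converted by
#' nearest-frame resampling.
#'
#' @param raw_path input video path.
#' @param out_path output path for the standardized video.
#' @param width,height,fps target geometry; defaults are the canonical
#'   540 x 960 px at 30 fps.
#' @return the `victa_video` asset describing the standardized output.
#' @export
standardize_video <- function(raw_path, out_path,
                              width = STD_WIDTH, height = STD_HEIGHT,
                              fps = STD_FPS) {
  asset <- video_info(raw_path)  # errors on undecodable/empty input
  n_out <- max(1L, as.integer(round(asset$duration * fps)))
  rd <- frame_reader(raw_path)
  on.exit(rd$close())
  wr <- fsv_writer(out_path, width, height, fps, n_out)
  cur <- NULL
  for (j in seq_len(n_out) - 1L) {
    ## source frame nearest to t = j / fps
    src_idx <- min(as.integer(round(j / fps * asset$fps)), asset$n_frames - 1L)
    while (rd$pos() <= src_idx) {
      f <- rd$next_frame()
      if (is.null(f)) break
      cur <- f
    }
    if (is.null(cur)) stop("decode failure before first frame of ", raw_path)
    wr$write_frame(letterbox_frame(cur, width, height))
  }
  wr$close()
}

## 0-based decoded-frame indices realizing sampling at the given interval:
## frame nearest to t = 0, interval, 2*interval, ... (at 30 fps and 0.1 s
## this is every 3rd frame). Count = floor(duration/interval) + 1, capped
## at the available frames.
sample_indices <- function(asset, interval) {
  if (interval < 1 / asset$fps - 1e-9)
    stop("sampling interval must be at least one frame period (",
         format(1 / asset$fps), " s)")
  k <- 0:floor(asset$duration / interval + 1e-9)
  idx <- as.integer(round(k * interval * asset$fps))
  idx <- idx[idx <= asset$n_frames - 1L]
  idx
}

#' Stream 0.1-s samples through a function
#'
#' Decodes the video sequentially, picks the frame nearest each sampling
#' instant (every 3rd decoded frame for 0.1-s sampling of 30-fps footage),
#' and calls `fun(t, pixels, valid)` for each sample. Samples whose frame
#' cannot be decoded are delivered with `valid = FALSE` and `NULL` pixels so
#' that valid-frame accounting can proceed downstream.
#'
#' @param asset a `victa_video` (or a path).
#' @param fun function of `(t, pixels, valid)`; its return values are
#'   collected into a list.
#' @param interval sampling interval in seconds (default 0.1).
#' @return invisibly, the list of `fun`'s return values.
#' @export
stream_samples <- function(asset, fun, interval = 0.1) {
  if (is.character(asset)) asset <- video_info(asset)
  idx <- sample_indices(asset, interval)
  rd <- frame_reader(asset$source_path)
  on.exit(rd$close())
  out <- vector("list", length(idx))
  cur <- NULL
  for (s in seq_along(idx)) {
    while (rd$pos() <= idx[s] && !rd$truncated()) {
      f <- rd$next_frame()
      if (!is.null(f)) cur <- f
    }
    ok <- rd$pos() > idx[s]
    out[[s]] <- fun(idx[s] / asset$fps, if (ok) cur else NULL, ok)
  }
  invisible(out)
}

#' Sample frames at a fixed interval
#'
#' Materializes the 0.1-s analysis sample stream as a list of timed frames.
#' Intended for short clips; full-length assays should be processed with
#' [stream_samples()], which does not hold the footage in memory.
#'
#' @inheritParams stream_samples
#' @return a list of samples, each `list(t, pixels, valid)` where `t` is
#'   seconds from video start (frame index / fps) and `pixels` a
#'   `height x width` intensity matrix.
#' @export
sample_frames <- function(asset, interval = 0.1) {
  stream_samples(asset,
                 function(t, pixels, valid) list(t = t, pixels = pixels,
                                                 valid = valid),
                 interval = interval)
}
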