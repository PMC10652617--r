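## Composite summary images: the per-pixel minimum across the 0.1-s sample
## stream. Mosquitoes are darker than the cone background, so merging the
## darkest component of each sampled frame paints every visited position
## into a single image - a minimum-intensity projection of the whole test.

new_composite <- function(pixels, n) {
  structure(list(pixels = pixels, n_samples_merged = as.integer(n),
                 width = ncol(pixels), height = nrow(pixels)),
            class = "victa_composite")
}

#' @export
print.victa_composite <- function(x, ...) {
  cat("<victa_composite> ", x$width, "x", x$height, " px, minimum over ",
      x$n_samples_merged, " samples\n", sep = "")
  invisible(x)
}

#' Composite summary image of an assay video
#'
#' Streams the video's 0.1-s samples (the same sampler used for detection)
#' and accumulates the per-pixel minimum. Undecodable samples are skipped;
#' `n_samples_merged` records how many frames entered the projection.
#'
#' @param asset a `victa_video` or path.
#' @param interval sampling interval in seconds.
#' @return a `victa_composite` with fields `pixels`, `n_samples_merged`.
#' @export
composite_summary <- function(asset, interval = 0.1) {
  if (is.character(asset)) asset <- video_info(asset)
  acc <- NULL; n <- 0L
  stream_samples(asset, function(t, pixels, valid) {
    if (valid) {
      acc <<- if (is.null(acc)) pixels else pmin(acc, pixels)
      n <<- n + 1L
    }
    NULL
  }, interval = interval)
  if (is.null(acc)) stop("no decodable samples to composite")
  new_composite(acc, n)
}

#' Composite from in-memory frames
#'
#' Per-pixel minimum over a list of equally sized intensity matrices.
#'
#' @param frames non-empty list of `height x width` matrices.
#' @return a `victa_composite`.
#' @export
composite_from_frames <- function(frames) {
  if (!length(frames)) stop("no frames to composite")
  acc <- frames[[1]]
  for (f in frames[-1]) acc <- pmin(acc, f)
  new_composite(acc, length(frames))
}

#' Merge composites
#'
#' Combines composites by per-pixel minimum; associative, commutative and
#' idempotent, so partial composites can be merged in any order.
#'
#' @param ... `victa_composite` objects of equal dimensions.
#' @return the merged `victa_composite`.
#' @export
merge_composites <- function(...) {
  cs <- list(...)
  stopifnot(length(cs) >= 1)
  acc <- cs[[1]]$pixels; n <- cs[[1]]$n_samples_merged
  for (c2 in cs[-1]) { acc <- pmin(acc, c2$pixels)
                       n <- n + c2$n_samples_merged }
  new_composite(acc, n)
}

#' Write a composite as PNG
#'
#' @param composite a `victa_composite`.
#' @param path output `.png` path.
#' @export
write_composite <- function(composite, path) {
  px <- pmin(pmax(composite$pixels, 0), 255) / 255
  png::writePNG(px, path)
  invisible(path)
}

#' @export
plot.victa_composite <- function(x, ...) {
  graphics::image(t(x$pixels)[, nrow(x$pixels):1], col = grDevices::gray.colors(256, 0, 1),
                  asp = nrow(x$pixels) / ncol(x$pixels), axes = FALSE,
                  useRaster = TRUE, ...)
  invisible(x)
}
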