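## Cone region geometry: the cone's projection onto the image (a polygon in
## pixel coordinates, origin top-left, y increasing downward) plus the
## horizontal line splitting the projection into the upper half (UHC) and
## lower half (LHC) of the cone volume. Calibrated once per camera rig.

#' Define the cone region geometry
#'
#' @param cone_roi two-column matrix or data frame of polygon vertices
#'   `(x, y)` in 0-based pixel coordinates (origin top-left, y downward).
#' @param split_line_y horizontal boundary (pixels) between the upper and
#'   lower halves of the cone volume's projection; a centroid with
#'   `y < split_line_y` is in the upper half, all others in the lower half.
#' @param frame_dims `c(width, height)` of the standardized frame.
#' @return a `victa_geometry` object.
#' @export
region_geometry <- function(cone_roi, split_line_y,
                            frame_dims = c(540L, 960L)) {
  roi <- as.matrix(cone_roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L)
    stop("cone_roi must be a polygon with at least 3 (x, y) vertices")
  colnames(roi) <- c("x", "y")
  w <- frame_dims[1]; h <- frame_dims[2]
  if (any(roi[, 1] < 0) || any(roi[, 1] > w - 1) ||
      any(roi[, 2] < 0) || any(roi[, 2] > h - 1))
    stop("cone_roi vertices must lie inside the frame")
  yr <- range(roi[, 2])
  if (!(split_line_y > yr[1] && split_line_y < yr[2]))
    stop("split_line_y must lie strictly inside the ROI's vertical extent")
  structure(list(cone_roi = roi, split_line_y = split_line_y,
                 frame_dims = as.integer(frame_dims)),
            class = "victa_geometry")
}

#' @export
print.victa_geometry <- function(x, ...) {
  cat("<victa_geometry> ", nrow(x$cone_roi), "-vertex cone ROI in ",
      x$frame_dims[1], "x", x$frame_dims[2],
      " px frame; upper/lower split at y = ", x$split_line_y, "\n", sep = "")
  invisible(x)
}

#' Default cone calibration for standardized footage
#'
#' A trapezoidal approximation of the WHO cone's projection in a 540 x 960
#' standardized frame: wide base at the net surface (bottom of frame),
#' narrowing toward the cone apex, with the upper/lower split midway up the
#' cone's vertical extent. Real rigs should be calibrated per camera setup.
#'
#' @return a `victa_geometry`.
#' @export
default_cone_geometry <- function() {
  roi <- rbind(c(70, 900), c(470, 900), c(320, 240), c(220, 240))
  region_geometry(roi, split_line_y = 570, frame_dims = c(540L, 960L))
}

#' Test points for cone ROI membership
#'
#' @param x,y 0-based pixel coordinates (vectors).
#' @param geometry a `victa_geometry`.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_roi <- function(x, y, geometry) {
  p <- geometry$cone_roi
  pracma::inpolygon(x, y, p[, 1], p[, 2], boundary = TRUE)
}

#' Assign a detection to the upper or lower cone region
#'
#' Upper iff centroid `y < split_line_y` (image origin top-left, y
#' increasing downward); a centroid exactly on the split line is assigned
#' to the lower half, the region bordering the net surface.
#'
#' @param y centroid y coordinates (px), or a blob data frame with a `y`
#'   column.
#' @param geometry a `victa_geometry`.
#' @return character vector, `"upper"` or `"lower"`.
#' @export
assign_region <- function(y, geometry) {
  if (is.data.frame(y)) y <- y$y
  ifelse(y < geometry$split_line_y, "upper", "lower")
}

#' Read / write a cone geometry calibration file
#'
#' YAML with fields `frame_width`, `frame_height`, `split_line_y`, and
#' parallel vertex lists `roi_x`, `roi_y` (0-based pixels, origin top-left).
#'
#' @param path file path.
#' @return `read_geometry` returns a `victa_geometry`.
#' @export
read_geometry <- function(path) {
  g <- yaml::read_yaml(path)
  region_geometry(cbind(g$roi_x, g$roi_y), g$split_line_y,
                  c(g$frame_width, g$frame_height))
}

#' @param geometry a `victa_geometry` to serialize.
#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  yaml::write_yaml(list(frame_width = geometry$frame_dims[1],
                        frame_height = geometry$frame_dims[2],
                        split_line_y = geometry$split_line_y,
                        roi_x = as.numeric(geometry$cone_roi[, 1]),
                        roi_y = as.numeric(geometry$cone_roi[, 2])),
                   path)
  invisible(path)
}
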