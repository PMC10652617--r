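## Top-level per-assay analysis: detection, epoch aggregation, metrics and
## composite in one call, with print/summary/plot methods.

#' Analyze one cone-assay video
#'
#' Runs the whole pipeline on a standardized assay video: moving-mosquito
#' detection on the 0.1-s sample stream, 5-s epoch aggregation with the
#' first 5 s excluded, whole-assay behavioural metrics, and (optionally)
#' the minimum-intensity composite summary image.
#'
#' @param video path to a standardized frame-stack video, or a
#'   `victa_video`.
#' @param geometry a [region_geometry()] for the rig.
#' @param cfg a [segmenter_config()].
#' @param assay_id identifier carried into all outputs.
#' @param composite render the composite summary image as well.
#' @param n_epochs,epoch_length,exclude epoch structure (35 windows of 5 s
#'   after a 5-s exclusion for the standard 180-s test).
#' @return a `victa_assay` object with elements `detections`, `epochs`,
#'   `metrics`, `composite` (or `NULL`), `assay_id`.
#' @export
analyze_assay <- function(video, geometry = default_cone_geometry(),
                          cfg = segmenter_config(), assay_id = "assay",
                          composite = TRUE, n_epochs = 35,
                          epoch_length = 5, exclude = 5) {
  det <- detect_assay(video, cfg, geometry, assay_id = assay_id)
  epochs <- aggregate_epochs(det, epoch_length = epoch_length,
                             n_epochs = n_epochs, exclude = exclude)
  metrics <- summarize_assay(epochs, det)
  comp <- if (composite) composite_summary(video) else NULL
  structure(list(assay_id = assay_id, detections = det, epochs = epochs,
                 metrics = metrics, composite = comp),
            class = "victa_assay")
}

#' @export
print.victa_assay <- function(x, ...) {
  cat("<victa_assay> '", x$assay_id, "': ", nrow(x$detections$samples),
      " samples, ", nrow(x$epochs), " epochs\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
summary.victa_assay <- function(object, ...) object$metrics

#' @export
plot.victa_assay <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$composite)) 1 else 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (!is.null(x$composite)) {
    plot(x$composite, main = paste("composite:", x$assay_id))
  }
  e <- x$epochs
  graphics::barplot(rbind(upper = e$activity_upper,
                          lower = e$activity_lower),
                    names.arg = e$index, col = c("grey70", "grey30"),
                    xlab = "epoch (5 s)", ylab = "movements",
                    main = "regional activity", legend.text = TRUE, ...)
  invisible(x)
}

#' Write all per-assay output files
#'
#' `detections.csv`, `epochs.csv`, `assay_metrics.csv` and
#' `composite.png` under the given directory.
#'
#' @param assay a `victa_assay`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_assay_outputs <- function(assay, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_detections(assay$detections, file.path(dir, "detections.csv"))
  write_epochs(assay$epochs, file.path(dir, "epochs.csv"),
               assay_id = assay$assay_id)
  write_assay_metrics(assay$metrics, file.path(dir, "assay_metrics.csv"))
  if (!is.null(assay$composite))
    write_composite(assay$composite, file.path(dir, "composite.png"))
  invisible(dir)
}
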