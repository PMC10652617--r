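## Behavioural metrics derived from the detection log: activity aggregated
## into 5-s epochs stratified by cone region, inferred and strict resting
## statistics, and whole-assay summaries. The counting unit throughout is
## the mosquito-sample: one moving mosquito detected in one 0.1-s sample
## contributes one movement count.

#' Aggregate detections into 5-s epochs
#'
#' Discards samples before the acclimatisation cut-off (first 5 s of the
#' test, during which the background model is still converging) and
#' partitions the remaining 175 s into 35 half-open windows
#' `[5 + 5k, 5 + 5(k+1))`. Per epoch, activity is the sum of `n_moving`
#' over valid samples, stratified into upper and lower cone regions by each
#' blob's centroid; `inactive_samples` counts valid samples with no moving
#' mosquito.
#'
#' @param det a `victa_detections` from [detect_assay()].
#' @param epoch_length epoch window length in seconds.
#' @param n_epochs number of epochs; the assay must span
#'   `exclude + n_epochs * epoch_length` seconds.
#' @param exclude seconds excluded at the start of the test.
#' @return a `victa_epochs` data frame with one row per epoch: `index`,
#'   `t_start`, `t_end`, `activity_total`, `activity_upper`,
#'   `activity_lower`, `inactive_samples`, `valid_samples`.
#' @export
aggregate_epochs <- function(det, epoch_length = 5, n_epochs = 35,
                             exclude = 5) {
  s <- det$samples
  need <- exclude + n_epochs * epoch_length
  span <- max(s$t) + det$interval
  if (span < need - 1e-9)
    stop("assay spans only ", format(round(span, 1)), " s of samples; ",
         need, " s are required for ", n_epochs, " epochs")
  ## index samples on the regular 0.1-s grid to avoid boundary jitter
  k <- round(s$t / det$interval)
  per_epoch <- floor(epoch_length / det$interval + 1e-9)
  k0 <- round(exclude / det$interval)
  epoch <- floor((k - k0) / per_epoch) + 1
  epoch[k < k0] <- NA
  epoch[epoch > n_epochs] <- NA
  out <- data.frame(index = seq_len(n_epochs),
                    t_start = exclude + (seq_len(n_epochs) - 1) * epoch_length,
                    t_end = exclude + seq_len(n_epochs) * epoch_length,
                    activity_total = 0L, activity_upper = 0L,
                    activity_lower = 0L, inactive_samples = 0L,
                    valid_samples = 0L)
  ok <- !is.na(epoch) & s$valid
  agg <- function(v, which) {
    x <- tapply(v[which], epoch[which], sum)
    ix <- as.integer(names(x))
    r <- integer(n_epochs); r[ix] <- as.integer(x); r
  }
  out$valid_samples <- agg(rep(1L, nrow(s)), ok)
  out$activity_total <- agg(s$n_moving, ok)
  out$inactive_samples <- agg(as.integer(s$n_moving == 0L), ok)
  b <- det$blobs
  if (nrow(b)) {
    be <- epoch[b$sample]
    bok <- !is.na(be) & s$valid[b$sample]
    for (reg in c("upper", "lower")) {
      sel <- bok & b$region == reg
      if (any(sel)) {
        x <- tapply(rep(1L, sum(sel)), be[sel], sum)
        ix <- as.integer(names(x))
        col <- paste0("activity_", reg)
        out[[col]][ix] <- as.integer(x)
      }
    }
  }
  stopifnot(all(out$activity_upper + out$activity_lower ==
                  out$activity_total))
  class(out) <- c("victa_epochs", "data.frame")
  out
}

#' Strict resting-frame count
#'
#' A resting frame is a 0.1-s sample in which none of the mosquitoes moved
#' relative to the previous sample: a valid sample with `n_moving = 0`.
#' The first sample has no predecessor and is excluded; the count runs over
#' the full test (acclimatisation window included), so for a 180-s assay
#' the maximum is 1799 out of 1800 samples.
#'
#' @param det a `victa_detections`.
#' @return integer count of resting frames.
#' @export
resting_frame_count <- function(det) {
  s <- det$samples
  if (nrow(s) < 2L) stop("resting requires at least 2 samples")
  sum(s$valid[-1L] & s$n_moving[-1L] == 0L)
}

#' Inferred per-sample inactivity
#'
#' The reciprocal of the per-sample moving count: with five mosquitoes in
#' the cone, `5 - n` of them are inferred inactive when `n` are detected
#' moving. A weaker statistic than the strict resting frame, which requires
#' all five to be still.
#'
#' @param n_moving integer vector of per-sample moving counts.
#' @param n_total mosquitoes in the cone (5 in the standard test).
#' @return integer vector of inferred inactive counts.
#' @export
inferred_inactivity <- function(n_moving, n_total = 5L) {
  stopifnot(all(n_moving >= 0L), all(n_moving <= n_total))
  as.integer(n_total - n_moving)
}

#' Summarize an assay's behavioural metrics
#'
#' Whole-test totals from the epoch table and detection log: total and
#' regional activity (mosquito-samples over the 35 epochs), the proportion
#' of activity in the lower cone region (`NA` when there was no activity,
#' never 0), inactive and resting frame counts, resting seconds, and the
#' valid-frame proportion (decoded, model-ready samples out of the expected
#' 1800). `total_activity_full` additionally reports activity over the full
#' test window including the first 5 s.
#'
#' @param epochs a `victa_epochs` from [aggregate_epochs()].
#' @param det the matching `victa_detections`.
#' @return a one-row `victa_metrics` data frame.
#' @export
summarize_assay <- function(epochs, det) {
  stopifnot(inherits(epochs, "victa_epochs"))
  s <- det$samples
  total <- sum(epochs$activity_total)
  upper <- sum(epochs$activity_upper)
  lower <- sum(epochs$activity_lower)
  resting <- resting_frame_count(det)
  out <- data.frame(
    assay_id = det$assay_id,
    total_activity = total,
    upper_activity = upper,
    lower_activity = lower,
    prop_lower = if (total > 0) lower / total else NA_real_,
    inactive_frames = sum(epochs$inactive_samples),
    resting_frames = resting,
    resting_seconds = resting * det$interval,
    valid_frames_proportion = sum(s$valid) / det$n_expected,
    total_activity_full = sum(s$n_moving[s$valid]),
    stringsAsFactors = FALSE)
  class(out) <- c("victa_metrics", "data.frame")
  out
}

#' @export
print.victa_metrics <- function(x, ...) {
  cat("<victa_metrics> assay '", x$assay_id, "'\n", sep = "")
  cat("  total activity: ", x$total_activity,
      " (upper ", x$upper_activity, ", lower ", x$lower_activity, ")\n",
      sep = "")
  cat("  prop. lower-region: ",
      if (is.na(x$prop_lower)) "undefined (no activity)"
      else format(round(x$prop_lower, 3)), "\n", sep = "")
  cat("  resting: ", x$resting_frames, " frames (",
      format(round(x$resting_seconds, 1)), " s); inactive samples: ",
      x$inactive_frames, "\n", sep = "")
  cat("  valid-frame proportion: ",
      format(round(x$valid_frames_proportion, 4)), "\n", sep = "")
  invisible(x)
}

#' Write epoch and assay-metric tables
#'
#' CSV output: `write_epochs` writes one row per assay x epoch,
#' `write_assay_metrics` one row per assay. Missing proportions (assays
#' with no activity) are written as empty fields.
#'
#' @param epochs a `victa_epochs`.
#' @param path output path.
#' @param assay_id identifier prefixed to epoch rows.
#' @export
write_epochs <- function(epochs, path, assay_id = "assay") {
  out <- cbind(assay_id = assay_id, as.data.frame(epochs))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param metrics one or more `victa_metrics` rows (rbind-compatible).
#' @rdname write_epochs
#' @export
write_assay_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
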