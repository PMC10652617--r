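## Merge per-assay behavioural metrics with per-mosquito post-exposure
## life-history records. Mosquitoes are tracked anonymously in the cone, so
## assay-level metrics attach to each of the (normally five) cohabiting
## individuals; downstream mixed-model / survival fitting consumes the
## merged table and is outside this package.

LIFE_HISTORY_COLS <- c("mosquito_id", "assay_id", "strain", "treatment",
                       "fed_1h", "fed_24h", "haematin", "wing_length",
                       "death_day", "dead_24h")

#' Read / write a life-history table
#'
#' Delimited text (CSV, header row, UTF-8) with columns `mosquito_id`,
#' `assay_id`, `strain`, `treatment` (UT/P2/P3/OS/IG2/other), `fed_1h`,
#' `fed_24h` (blood-feeding at 1 and 24 h post-exposure; the 24-h value is
#' empty for mosquitoes that fed at 1 h, which were not offered a second
#' meal), `haematin` (ug/ml, proxy for blood meal weight), `wing_length`
#' (mm), `death_day` (days post-exposure), `dead_24h`. Missing values are
#' empty fields.
#'
#' @param path CSV path.
#' @return `read_life_history` returns a data frame.
#' @export
read_life_history <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(c("mosquito_id", "assay_id"), names(df))
  if (length(missing_cols))
    stop("life-history table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  for (col in c("fed_1h", "fed_24h", "dead_24h"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' @param records data frame of life-history records.
#' @rdname read_life_history
#' @export
write_life_history <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate life-history records
#'
#' Report-only invariant checks: a 24-h feeding outcome recorded for a
#' mosquito that already fed at 1 h (no second meal was offered), negative
#' haematin, wing length or death day, and missing treatment labels.
#'
#' @param records data frame of life-history records.
#' @return data frame with one row per violation: `row`, `mosquito_id`,
#'   `field`, `message`; zero rows for a clean table.
#' @export
validate_life_history <- function(records) {
  flags <- list()
  flag <- function(rows, field, message) {
    if (any(rows)) flags[[length(flags) + 1L]] <<- data.frame(
      row = which(rows),
      mosquito_id = records$mosquito_id[rows],
      field = field, message = message, stringsAsFactors = FALSE)
  }
  if (all(c("fed_1h", "fed_24h") %in% names(records)))
    flag(!is.na(records$fed_1h) & records$fed_1h &
           !is.na(records$fed_24h),
         "fed_24h", "24-h feeding recorded despite feeding at 1 h")
  for (field in c("haematin", "wing_length", "death_day"))
    if (field %in% names(records))
      flag(!is.na(records[[field]]) & records[[field]] < 0,
           field, "negative value")
  if ("treatment" %in% names(records))
    flag(is.na(records$treatment) | records$treatment == "",
         "treatment", "missing treatment label")
  if (!length(flags))
    return(data.frame(row = integer(0), mosquito_id = character(0),
                      field = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  out[order(out$row), , drop = FALSE]
}

#' Merge assay metrics with life-history records
#'
#' Left-joins each mosquito's record with its assay's behavioural metrics
#' on `assay_id`. Every record must resolve to exactly one metrics row;
#' records referencing unknown assays abort with the offending ids listed.
#' Assays with a cohort other than the expected 5 mosquitoes are warned
#' about but kept. The output has one row per record, record order
#' preserved.
#'
#' @param metrics data frame of assay metrics (one or more
#'   [summarize_assay()] rows bound together).
#' @param records data frame of life-history records.
#' @param expected_cohort mosquitoes expected per assay.
#' @return the merged data frame (`victa_merged`).
#' @export
merge_life_history <- function(metrics, records, expected_cohort = 5L) {
  metrics <- as.data.frame(metrics)
  stopifnot("assay_id" %in% names(metrics),
            all(c("assay_id", "mosquito_id") %in% names(records)))
  if (anyDuplicated(metrics$assay_id))
    stop("duplicate assay_id in metrics: ",
         paste(unique(metrics$assay_id[duplicated(metrics$assay_id)]),
               collapse = ", "))
  dup <- duplicated(records[c("assay_id", "mosquito_id")])
  if (any(dup))
    stop("duplicate (assay_id, mosquito_id) in records: ",
         paste(unique(paste(records$assay_id[dup],
                            records$mosquito_id[dup], sep = "/")),
               collapse = ", "))
  orphan <- setdiff(records$assay_id, metrics$assay_id)
  if (length(orphan))
    stop("life-history records reference unknown assay_id: ",
         paste(orphan, collapse = ", "))
  cohort <- table(records$assay_id)
  off <- cohort[cohort != expected_cohort]
  if (length(off))
    warning("assays without the expected ", expected_cohort,
            "-mosquito cohort: ",
            paste(names(off), " (", as.integer(off), ")",
                  sep = "", collapse = ", "))
  i <- match(records$assay_id, metrics$assay_id)
  extra <- metrics[i, setdiff(names(metrics), "assay_id"), drop = FALSE]
  rownames(extra) <- NULL
  out <- cbind(records, extra)
  rownames(out) <- NULL
  class(out) <- c("victa_merged", "data.frame")
  out
}

#' Write the merged analysis-ready table
#'
#' @param merged a `victa_merged` table.
#' @param path output CSV path; missing values are written as empty
#'   fields.
#' @export
write_merged <- function(merged, path) {
  utils::write.csv(as.data.frame(merged), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
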