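#' Read a raw triaxial tracing from CSV
#'
#' Expects the package's tracing dialect: comma-separated, UTF-8, with
#' header `subject_id,sample_index,ax_g,ay_g,az_g`, one row per sample in
#' acquisition order, accelerations in g. `sample_index` must be strictly
#' increasing and the file must contain exactly one subject.
#'
#' @param path CSV file path.
#' @param rate_hz Sampling rate to attach (not stored in the file);
#'   defaults to 30 Hz.
#' @return A `raw_tracing` object.
#' @export
read_raw_csv <- function(path, rate_hz = 30) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (rate_hz <= 0) stop_input("rate_hz must be > 0")
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop_input("parse error in %s: %s", path, conditionMessage(e))
  )
  req <- c("subject_id", "sample_index", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_input("parse error in %s: missing columns %s", path,
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop_input("parse error in %s: empty file", path)
  num <- list()
  for (col in c("sample_index", "ax_g", "ay_g", "az_g")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_input("parse error in %s: non-numeric %s on row %d",
                 path, col, bad[1])
    }
    num[[col]] <- v
  }
  ids <- unique(df$subject_id)
  if (length(ids) != 1) {
    stop_input("parse error in %s: expected one subject, found %d",
               path, length(ids))
  }
  if (any(diff(num$sample_index) <= 0)) {
    stop_input("parse error in %s: sample_index not strictly increasing (row %d)",
               path, which(diff(num$sample_index) <= 0)[1] + 1L)
  }
  structure(list(
    subject_id = ids,
    rate_hz = rate_hz,
    data = data.frame(sample_index = num$sample_index,
                      ax_g = num$ax_g, ay_g = num$ay_g, az_g = num$az_g)
  ), class = "raw_tracing")
}

#' Write a raw tracing to CSV
#'
#' Inverse of [read_raw_csv()]; values round-trip within CSV float
#' precision (15 significant digits).
#'
#' @param tracing A `raw_tracing`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(tracing, path) {
  stopifnot(inherits(tracing, "raw_tracing"))
  df <- data.frame(subject_id = tracing$subject_id, tracing$data)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign high/low/intermediate fall-risk labels
#'
#' Applies the two-predictor labelling rule: a subject is **high** fall
#' risk iff SPPB total <= 9 and at least one fall in the past year;
#' **low** fall risk iff SPPB total >= 10 and no falls; every other
#' combination (falls with good SPPB, or poor SPPB without falls) is
#' **intermediate** and excluded from two-class modelling.
#'
#' @param records Data frame with columns `sppb_total` (integer 0-12) and
#'   `falls_past_year` (non-negative integer).
#' @return `records` with a `label` column in
#'   `{"high", "low", "intermediate"}`.
#' @export
assign_risk_labels <- function(records) {
  stopifnot(is.data.frame(records))
  req <- c("sppb_total", "falls_past_year")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_input("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  sppb <- records$sppb_total
  falls <- records$falls_past_year
  if (any(!is.finite(sppb)) || any(sppb < 0 | sppb > 12)) {
    stop_input("sppb_total must be in [0, 12]")
  }
  if (any(!is.finite(falls)) || any(falls < 0)) {
    stop_input("falls_past_year must be a non-negative count")
  }
  records$label <- ifelse(sppb <= 9 & falls >= 1, "high",
                          ifelse(sppb >= 10 & falls == 0, "low",
                                 "intermediate"))
  records
}

#' Write/read a cohort table
#'
#' @param cohort Data frame with columns `subject_id`, `age`,
#'   `sppb_total`, `falls_past_year` and optionally `label`.
#' @param path CSV path.
#' @return The cohort data frame (read) or `path` invisibly (write).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "sppb_total", "falls_past_year")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_input("parse error in %s: missing columns %s", path,
               paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write ground-truth objects to JSON
#'
#' @param truths List of `ground_truth` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truths, path) {
  payload <- lapply(truths, function(tr) unclass(tr))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
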