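clinical_required_cols <- function() {
  c("subject_id", "study", clustering_variables())
}

#' Read / write a clinical table as CSV
#'
#' The CSV must carry `subject_id`, `study` and the ten clustering
#' variables; empty cells become missing values. Errors name the offending
#' column (and row for unparseable numeric cells).
#'
#' @param path File path.
#' @param table Clinical data frame.
#' @return `read_clinical_csv` returns the validated data frame;
#'   `write_clinical_csv` returns `path` invisibly.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(clinical_required_cols(), names(raw))
  if (length(missing_cols) > 0) {
    stop("clinical CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$subject_id)) stop("duplicate subject_id values")
  numeric_cols <- intersect(
    c(clustering_variables(), "bmi_z", "hdl", "tc", "steatosis",
      "lobular_inflammation", "ballooning", "fibrosis_stage"), names(raw))
  for (v in numeric_cols) {
    x <- raw[[v]]
    x[x == ""] <- NA
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad) > 0) {
      stop("unparseable value in column ", v, " at row ", bad[1],
           " ('", x[bad[1]], "')")
    }
    raw[[v]] <- parsed
  }
  if ("fibrosis_stage" %in% names(raw)) {
    ok <- is.na(raw$fibrosis_stage) | raw$fibrosis_stage %in% 0:4
    if (!all(ok)) {
      stop("fibrosis_stage outside 0..4 at row ", which(!ok)[1])
    }
  }
  raw
}

#' @rdname read_clinical_csv
#' @export
write_clinical_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write an LC-MS feature table as CSV
#'
#' Wide layout: one row per feature with columns `feature_id`, `mz`,
#' `rt_seconds`, then one intensity column per injection named
#' `<sample>_<replicate>`. A sidecar CSV (`<path stem>_samples.csv`)
#' maps each sample to its study/batch.
#'
#' @param table A `feature_table`.
#' @param path Feature CSV path (sidecar path is derived from it).
#' @param mode Ionization mode to stamp on the table read back.
#' @return `read_feature_csv` returns a `feature_table`;
#'   `write_feature_csv` returns `path` invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  wide <- data.frame(feature_id = table$features$feature_id,
                     mz = table$features$mz,
                     rt_seconds = table$features$rt,
                     stringsAsFactors = FALSE)
  ints <- t(table$intensities)
  colnames(ints) <- table$injection_map$injection
  utils::write.csv(cbind(wide, ints), path, row.names = FALSE)
  utils::write.csv(table$batch_map, sidecar_path(path), row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.csv$", "_samples.csv", path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path, mode) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (col in c("feature_id", "mz", "rt_seconds")) {
    if (!col %in% names(raw)) {
      stop("feature CSV is missing mandatory column: ", col)
    }
  }
  if (!is.numeric(raw$mz)) stop("non-numeric mz column")
  if (!is.numeric(raw$rt_seconds)) stop("non-numeric rt_seconds column")
  if (anyDuplicated(raw$feature_id)) stop("duplicate feature_id values")
  inj_cols <- setdiff(names(raw), c("feature_id", "mz", "rt_seconds"))
  ints <- t(as.matrix(raw[, inj_cols, drop = FALSE]))
  batch_map <- utils::read.csv(sidecar_path(path),
                               stringsAsFactors = FALSE)
  inj <- data.frame(
    injection = inj_cols,
    sample = sub("_[0-9]+$", "", inj_cols),
    replicate = as.integer(sub("^.*_", "", inj_cols)),
    stringsAsFactors = FALSE)
  feature_table(mode = mode,
                features = data.frame(feature_id = raw$feature_id,
                                      mz = raw$mz, rt = raw$rt_seconds,
                                      stringsAsFactors = FALSE),
                intensities = ints, injection_map = inj,
                batch_map = batch_map)
}

#' Write ground truth as JSON
#'
#' @param truth Ground-truth list from the generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(subject_cluster = as.list(truth$subject_cluster),
         feature_compound = truth$feature_compound,
         differential_features = truth$differential_features,
         outlier_subjects = truth$outlier_subjects,
         extreme_subjects = truth$extreme_subjects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
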