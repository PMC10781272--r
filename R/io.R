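# CSV and JSON I/O. CSV is the canonical table format: one file per
# participant, header = datestamp, the 43 feature names, depressed; missing
# cells are empty; timestamps are ISO-8601 UTC.

ts_format <- "%Y-%m-%dT%H:%M:%SZ"

#' Write a participant table to CSV
#'
#' @param table a `participant_table`.
#' @param path output file path.
#' @param sidecar optional [cohort_spec()] written alongside as
#'   `<path>.spec.json` for provenance.
#' @return `path`, invisibly.
#' @export
write_participant_csv <- function(table, path, sidecar = NULL) {
  df <- data.frame(datestamp = format(table$timestamps, ts_format,
                                      tz = "UTC"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (fn in colnames(table$X)) df[[fn]] <- table$X[, fn]
  df[[table$schema$output_feature$name]] <- table$y
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(sidecar)) {
    sc <- sidecar[setdiff(names(sidecar), "schema")]
    jsonlite::write_json(sc, paste0(path, ".spec.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a participant table from CSV
#'
#' Validates the header against the schema, parses ISO-8601 timestamps,
#' restores empty cells as missing, and checks labels against the 1--7
#' scale. Duplicate timestamps produce a warning (EMA prompts should be
#' unique in time).
#'
#' @param path CSV file path.
#' @param schema a `feature_schema` (default: built fresh). Tables written
#'   after preprocessing may have fewer columns (dropped constant features);
#'   columns must still be a subset of the schema in schema order.
#' @param participant_id id to attach (default: file name).
#' @return a `participant_table`.
#' @export
read_participant_csv <- function(path, schema = build_feature_schema(),
                                 participant_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out_name <- schema$output_feature$name
  expected <- c(schema$timestamp_feature, schema$input_features$name, out_name)
  unknown <- setdiff(names(df), expected)
  if (length(unknown))
    stop_data("unknown column(s): ", paste(unknown, collapse = ", "))
  if (!schema$timestamp_feature %in% names(df) || !out_name %in% names(df))
    stop_data("missing required column(s)")

  ts <- as.POSIXct(df[[schema$timestamp_feature]], format = ts_format,
                   tz = "UTC")
  if (anyNA(ts)) stop_data("unparseable timestamp(s)")
  if (anyDuplicated(ts)) warning("duplicate timestamps in ", path)

  y <- df[[out_name]]
  if (anyNA(y) || any(y < schema$output_feature$min |
                      y > schema$output_feature$max))
    stop_data("labels outside [", schema$output_feature$min, ",",
              schema$output_feature$max, "] (or missing)")

  feat_cols <- intersect(schema$input_features$name, names(df))
  X <- as.matrix(df[feat_cols])
  storage.mode(X) <- "double"
  new_participant_table(ts, X, as.integer(y), schema,
                        participant_id %||%
                          tools::file_path_sans_ext(basename(path)))
}

#' Serialise a preprocessing report to JSON
#'
#' @param report a `preprocess_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
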