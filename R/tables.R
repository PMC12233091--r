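#' Write analysis statistics as paired CSV and JSON tables
#'
#' Statistics are exported twice with identical numeric content: a flat CSV
#' with one row per entity per timepoint per channel, and a JSON document
#' nested by entity. `records` must be a data frame with an `id` column
#' naming the entity each row belongs to; remaining columns are the
#' measurements.
#'
#' @param records a data frame with an `id` column (may have zero rows).
#' @param basepath output path without extension; `<basepath>.csv` and
#'   `<basepath>.json` are written.
#' @return invisibly, the two file paths.
#' @export
write_tables <- function(records, basepath) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  if (!"id" %in% names(records)) stopf("records must contain an 'id' column")
  csv_path <- paste0(basepath, ".csv")
  json_path <- paste0(basepath, ".json")
  dir.create(dirname(csv_path), recursive = TRUE, showWarnings = FALSE)
  tryCatch(write.csv(records, csv_path, row.names = FALSE),
           error = function(e) stopf("cannot write '%s': %s", csv_path, conditionMessage(e)))
  nested <- if (nrow(records) == 0) {
    setNames(list(), character())
  } else {
    lapply(split(records[setdiff(names(records), "id")],
                 factor(records$id, levels = unique(records$id))),
           function(df) { rownames(df) <- NULL; df })
  }
  jsonlite::write_json(nested, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = csv_path, json = json_path))
}
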