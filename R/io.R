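#' Read a peak table from CSV
#'
#' Comma-separated, UTF-8, decimal point, header required (the exchange
#' dialect is stated explicitly because chromatography export locales
#' often use decimal commas). Each row is one detected peak of one
#' injection. Malformed rows are rejected with their file line numbers.
#'
#' @param path Path to the CSV file.
#' @return Validated peak-table data frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "analyte", "rt", "area_target", "area_q1",
                "area_q2", "sample_weight", "thermostat_temp",
                "thermostat_time", "injection_index", "sample_type")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    warning("peak table contains a header but no records: ", path)
    return(tab)
  }
  line_no <- seq_len(nrow(tab)) + 1L   # header is line 1
  bad <- which(tab$area_target < 0 | tab$area_q1 < 0 | tab$area_q2 < 0)
  if (length(bad)) {
    stop("negative peak area(s) at line(s): ",
         paste(line_no[bad], collapse = ", "))
  }
  bad <- which(tab$injection_index < 1 | tab$sample_weight <= 0 |
                 tab$rt <= 0)
  if (length(bad)) {
    stop("invalid metadata (injection index, weight or RT) at line(s): ",
         paste(line_no[bad], collapse = ", "))
  }
  bad <- which(!tab$sample_type %in% c("standard", "flower"))
  if (length(bad)) {
    stop("unknown sample_type at line(s): ",
         paste(line_no[bad], collapse = ", "))
  }
  tab
}

#' Write a peak table to CSV
#'
#' @param table Peak-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
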