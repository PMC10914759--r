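READS_COLUMNS <- c("plate_id", "well", "role", "assay_id", "donor_id",
                   "sensor_id", "time_min", "fluorescence")

#' Write and read plate-read tables
#'
#' Long-format CSV with columns `plate_id`, `well`, `role`, `assay_id`,
#' `donor_id`, `sensor_id`, `time_min`, `fluorescence`. Doubles are written
#' with round-trip precision, so write-then-read is field-identical and the
#' file bytes are a deterministic function of the read table.
#'
#' `read_reads_csv` validates the schema: the header must match exactly,
#' sensor ids must belong to the 18-sensor panel (or `STD` for standard
#' wells), and fluorescence must be finite and non-negative. Violations
#' raise an error naming the first offending line.
#'
#' @param reads Read tibble from [generate_plate_reads()].
#' @param path CSV file path.
#' @return `read_reads_csv` returns the read tibble.
#' @export
write_reads_csv <- function(reads, path) {
  stopifnot(identical(names(reads), READS_COLUMNS))
  readr::write_csv(reads, path, na = "")
  invisible(path)
}

#' @rdname write_reads_csv
#' @export
read_reads_csv <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               na = ""))
  if (!identical(hdr, READS_COLUMNS))
    stop(sprintf("malformed reads file %s: expected columns %s", path,
                 paste(READS_COLUMNS, collapse = ", ")), call. = FALSE)
  out <- readr::read_csv(path, col_types = readr::cols(
    plate_id = "c", well = "c", role = "c", assay_id = "c", donor_id = "c",
    sensor_id = "c", time_min = "d", fluorescence = "d"
  ), na = "")
  fail <- function(rows, what) {
    if (length(rows) > 0)
      stop(sprintf("parse error at line %d of %s: %s", rows[1] + 1L, path, what),
           call. = FALSE)
  }
  fail(which(!out$sensor_id %in% c(LEAP_SENSORS, "STD")),
       "sensor_id not in the 18-sensor panel")
  fail(which(!out$role %in% c("sample", "standard", "blank")), "invalid role")
  fail(which(!is.finite(out$fluorescence) | out$fluorescence < 0),
       "fluorescence must be finite and >= 0")
  out
}
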