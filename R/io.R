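#' Read a batch of time-stamped spectra from a wide CSV file
#'
#' The canonical on-disk format is one row per spectrum: a `time_h` column
#' followed by one column per wavenumber, with the numeric wavenumbers as
#' column headers (strictly ascending).  Rows may appear in any time order;
#' the returned series is sorted.
#'
#' @param path Path to a CSV file.
#' @param batch_id Batch label to attach; defaults to the file name without
#'   extension.
#' @return A [spectra_series()].
#' @seealso [write_series_csv()]
#' @export
read_series_csv <- function(path, batch_id = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  # strict reader: fread only warns (not errors) on ragged/discarded
  # lines, so collect its warnings and promote the structural ones
  warns <- character(0)
  dt <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, header = TRUE, sep = ",", fill = FALSE,
                        colClasses = "numeric", data.table = TRUE),
      error = function(e) abort_format(sprintf(
        "cannot parse '%s' as a wide spectra CSV: %s",
        path, conditionMessage(e)))),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  bad <- grepl("Discarded|Stopped early|fewer fields|too many fields|NAs introduced",
               warns, ignore.case = TRUE)
  if (any(bad))
    abort_format(sprintf("malformed rows in '%s': %s", path,
                         paste(warns[bad], collapse = "; ")))
  hdr <- names(dt)
  if (length(hdr) < 3L || hdr[1] != "time_h")
    abort_format("first header cell must be `time_h`, followed by >= 2 wavenumber columns")
  wn <- suppressWarnings(as.numeric(hdr[-1]))
  if (any(is.na(wn)))
    abort_format(sprintf("non-numeric wavenumber header(s): %s",
                         paste(hdr[-1][is.na(wn)], collapse = ", ")))
  if (any(diff(wn) <= 0))
    abort_format("wavenumber headers must be strictly ascending")
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (any(!is.finite(m)))
    abort_format(sprintf("non-numeric or missing intensities in '%s'", path))
  if (is.null(batch_id))
    batch_id <- sub("\\.[^.]*$", "", basename(path))
  spectra_series(times = dt[["time_h"]], wavenumbers = wn, intensities = m,
                 batch_id = batch_id)
}

#' Write a series to a wide CSV file
#'
#' Inverse of [read_series_csv()]: the round trip reproduces the series to
#' full double precision (headers are written with 17 significant digits,
#' values with shortest round-trippable representation).
#'
#' @param series A [spectra_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (!inherits(series, "spectra_series"))
    abort_validation("`series` must be a spectra_series")
  if (length(series$times) < 1L)
    abort_validation("refusing to write a series with no spectra")
  # %.17g guarantees the shortest-or-better decimal that reparses to the
  # same double, so the CSV round trip is bit-exact.
  fmt <- matrix(sprintf("%.17g", series$intensities),
                nrow = nrow(series$intensities))
  dt <- data.table::as.data.table(fmt)
  data.table::setnames(dt, sprintf("%.17g", series$wavenumbers))
  dt <- cbind(data.table::data.table(time_h = sprintf("%.17g", series$times)),
              dt)
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = ",")
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    abort_io(sprintf("cannot write '%s'", path))
  invisible(path)
}
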