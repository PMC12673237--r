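#' Read and write fix and survival tables as CSV
#'
#' Fix tables have columns `id, timestamp, x, y, dop` (timestamps ISO
#' 8601, UTC); survival tables `id, outcome, source`.
#'
#' @param fixes,survival tables to write.
#' @param file path.
#' @return Writers return the path invisibly; readers the parsed table.
#' @export
write_fixes <- function(fixes, file) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(file) {
  out <- read.csv(file)
  need <- c("id", "timestamp", "x", "y", "dop")
  if (!all(need %in% names(out)))
    stop("fix table must have columns: ", paste(need, collapse = ", "))
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(out$timestamp)) stop("unparseable timestamps in ", file)
  out
}

#' @rdname write_fixes
#' @export
write_survival <- function(survival, file) {
  write.csv(survival, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fixes
#' @export
read_survival <- function(file) {
  out <- read.csv(file)
  if (!all(c("id", "outcome", "source") %in% names(out)))
    stop("survival table must have columns: id, outcome, source")
  out
}
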