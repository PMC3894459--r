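#' Read and write spike rasters as delimited text
#'
#' Tab-separated with a header line: columns \code{time_ms},
#' \code{population}, \code{channel}, sorted by time.  Duration is kept in
#' a leading comment line.
#'
#' @param raster A \code{\link{spike_raster}}.
#' @param path File path.
#' @return \code{read_raster} returns a \code{\link{spike_raster}};
#'   \code{write_raster} returns \code{path} invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms: %.10g", attr(raster, "duration")), con)
  utils::write.table(as.data.frame(raster), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  first <- readLines(path, n = 1)
  duration <- as.numeric(sub("^# duration_ms:\\s*", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spike_raster(df$time_ms, df$population, df$channel, duration = duration)
}

#' Read and write stimulus patterns as 0/1 matrix files
#'
#' Whitespace-delimited 0/1 rows (one per channel) preceded by comment
#' header lines carrying the bin width and label.
#'
#' @param p A \code{\link{stimulus_pattern}}.
#' @param path File path.
#' @return \code{read_pattern} returns a \code{\link{stimulus_pattern}}.
#' @export
write_pattern <- function(p, path) {
  stopifnot(inherits(p, "stimulus_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_ms: %.10g", p$bin_ms),
               sprintf("# label: %s", p$label)), con)
  utils::write.table(p$grid, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  hdr <- readLines(path, n = 2)
  bin_ms <- as.numeric(sub("^# bin_ms:\\s*", "", hdr[1]))
  label <- sub("^# label:\\s*", "", hdr[2])
  grid <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(grid) <- NULL
  stimulus_pattern(grid, bin_ms = bin_ms, label = label)
}

#' Read and write numeric matrices as delimited text
#'
#' Used for connectivity/efficacy matrices and activity matrices.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return \code{read_matrix} returns a numeric matrix.
#' @export
write_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' Read and write response tables
#'
#' Tab-separated with header: \code{class}, \code{rep}, \code{count},
#' \code{sigma}, \code{rate_percent}.
#'
#' @param tab Response table data frame.
#' @param path File path.
#' @return \code{read_response_table} returns the data frame.
#' @export
write_response_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(class = "character"))
}
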