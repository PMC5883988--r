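#' Read and write the package's delimited-text formats
#'
#' Panels are CSV/TSV with a header row of region labels and one row per
#' timepoint. Connectivity matrices and signed networks are square CSV/TSV
#' with a label header row and a label column; signed networks hold integer
#' entries in \{-1, 0, +1\}. Rasters are CSV with rows = steps and columns =
#' region labels. The delimiter is inferred from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path file path.
#' @param subject_id subject identifier for the panel (defaults to the file
#'   base name).
#' @return `read_panel()` a [ts_panel()]; `read_connectivity()` a
#'   [conn_matrix()]; `read_signed_network()` a `signed_network`.
#' @name serabm_io
NULL

io_sep <- function(path) if (grepl("\\.(tsv|txt)$", path)) "\t" else ","

#' @rdname serabm_io
#' @export
read_panel <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  x <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                         check.names = FALSE)
  ts_panel(as.matrix(x), colnames(x), subject_id)
}

#' @rdname serabm_io
#' @param panel a [ts_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$values, path, sep = io_sep(path),
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

read_square <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                         row.names = 1, check.names = FALSE)
  as.matrix(x)
}

write_square <- function(m, path) {
  df <- data.frame(region = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = io_sep(path), row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname serabm_io
#' @export
read_connectivity <- function(path) conn_matrix(read_square(path))

#' @rdname serabm_io
#' @param conn a [conn_matrix()].
#' @export
write_connectivity <- function(conn, path) write_square(conn, path)

#' @rdname serabm_io
#' @export
read_signed_network <- function(path) {
  m <- read_square(path)
  if (!all(m %in% c(-1, 0, 1)))
    stop("signed network file has entries outside {-1, 0, +1}")
  if (any(diag(m) != 0)) stop("signed network must have zero diagonal")
  if (!isTRUE(all.equal(m, t(m)))) stop("signed network must be symmetric")
  storage.mode(m) <- "integer"
  P <- nrow(m) * (nrow(m) - 1L) / 2
  ut <- m[upper.tri(m)]
  new_signed_network(m, rownames(m), scheme = "file",
                     positive_cost = sum(ut > 0) / P,
                     negative_cost = sum(ut < 0) / P)
}

#' @rdname serabm_io
#' @param network a `signed_network`.
#' @export
write_signed_network <- function(network, path) write_square(network, path)

#' @rdname serabm_io
#' @export
read_raster <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                         check.names = FALSE)
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  structure(m, class = c("ser_raster", "matrix", "array"))
}

#' @rdname serabm_io
#' @param raster a `ser_raster`.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(unclass(raster), path, sep = io_sep(path),
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname serabm_io
#' @param result a `sweep_result`.
#' @export
write_sweep_result <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname serabm_io
#' @export
read_sweep_result <- function(path) {
  res <- utils::read.csv(path)
  best <- which.max(res$mean_r)
  structure(res, argmax = res[best, ], class = c("sweep_result", "data.frame"))
}
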