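# Text raster I/O (ESRI ASCII grid) and tabular serialisation helpers.
# ASCII grids are dependency-free and diff-able, which keeps pipeline
# artifacts bit-reproducible in version control.

#' Write a grid-aligned value vector as an ESRI ASCII grid
#'
#' @param values numeric per grid cell, in the grid's row order (x fastest,
#'   y ascending); NA written as the nodata value.
#' @param grid the `wk_grid` the values align with.
#' @param path output path (conventionally `.asc`).
#' @param digits significant digits (default 7).
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, grid, path, digits = 7) {
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  cell <- attr(grid, "cell_km")
  if (length(values) != nx * ny) stop_wk("values do not match the grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nx), paste("nrows", ny),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cell), "NODATA_value -9999"), con)
  m <- matrix(values, nrow = nx, ncol = ny) # [x, y]
  for (j in rev(seq_len(ny))) { # top row first
    row <- signif(m[, j], digits)
    row[is.na(row)] <- -9999
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_asc()]
#' @param path file path.
#' @return list: `values` (grid row order), `nx`, `ny`, `cell`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get <- function(key) as.numeric(strsplit(hdr[grep(key, hdr, ignore.case = TRUE)],
                                           " +")[[1]][2])
  nx <- get("ncols"); ny <- get("nrows"); cell <- get("cellsize")
  nodata <- get("NODATA")
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), " +")[[1]]))
  m <- do.call(rbind, rev(rows)) # back to y ascending
  vals <- as.vector(t(m))
  vals[vals == nodata] <- NA
  list(values = vals, nx = nx, ny = ny, cell = cell)
}
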