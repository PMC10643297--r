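# ESRI ASCII grid raster reader/writer. Grids are row-major with origin at
# the top-left (GIS convention); in R they are held as matrices with row 1 =
# northernmost row.

#' Read an ESRI ASCII grid raster
#'
#' @param path path to a `.asc` file.
#' @return object of class `grid_raster`: list with `data` (numeric matrix,
#'   `NA` for NoData), `cellsize`, `xllcorner`, `yllcorner`,
#'   `nodata_value`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  i <- 0
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% hdr_keys) break
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed raster header at line ", i + 1, " of ", path)
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows")) {
    if (is.null(hdr[[k]]))
      stop("malformed raster header: missing '", k, "' (line ", i + 1,
           " of ", path, ")")
  }
  vals <- suppressWarnings(as.numeric(scan(text = lines[(i + 1):length(lines)],
                                           what = character(), quiet = TRUE)))
  if (anyNA(vals))
    stop("non-numeric raster data in ", path)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster data size mismatch in ", path, ": expected ",
         hdr$ncols * hdr$nrows, " values, got ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  structure(list(data = m, cellsize = hdr$cellsize %||% 10,
                 xllcorner = hdr$xllcorner %||% 0,
                 yllcorner = hdr$yllcorner %||% 0,
                 nodata_value = hdr$nodata_value %||% -9999),
            class = "grid_raster")
}

#' Write an ESRI ASCII grid raster
#'
#' Round-trips float data at full double precision (`%.10g`); `NA` cells are
#' written as the NoData value.
#'
#' @param grid numeric matrix or a `grid_raster`.
#' @param path output path.
#' @param cellsize,xllcorner,yllcorner,nodata_value header fields (ignored
#'   when `grid` is a `grid_raster`, which carries its own).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, cellsize = 10, xllcorner = 0,
                         yllcorner = 0, nodata_value = -9999) {
  if (inherits(grid, "grid_raster")) {
    cellsize <- grid$cellsize; xllcorner <- grid$xllcorner
    yllcorner <- grid$yllcorner; nodata_value <- grid$nodata_value
    grid <- grid$data
  }
  m <- grid
  m[is.na(m)] <- nodata_value
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
    paste("cellsize", cellsize), paste("NODATA_value", nodata_value)
  )
  rows <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("<grid_raster> ", nrow(x$data), "x", ncol(x$data), " cells, cellsize ",
      x$cellsize, "; range ", paste(signif(range(x$data, na.rm = TRUE), 4),
                                    collapse = " .. "), "\n", sep = "")
  invisible(x)
}
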