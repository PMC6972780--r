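#' Read a raster from an ESRI ASCII grid file
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. Nodata cells become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @return A numeric matrix (row 1 = northernmost row) with attributes
#'   `xllcorner`, `yllcorner` and `cellsize`.
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrows * ncols) {
    stop("ASCII grid body has ", length(body), " values, expected ",
         nrows * ncols, call. = FALSE)
  }
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  attr(m, "xllcorner") <- vals[["xllcorner"]]
  attr(m, "yllcorner") <- vals[["yllcorner"]]
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param x Numeric matrix, row 1 = northernmost row; `NA` written as the
#'   declared nodata value.
#' @param path Output file path.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param cellsize Cell edge length in map units.
#' @param nodata Value used to encode `NA`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(x))
  m <- x
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", format(xllcorner, scientific = FALSE)),
    paste("yllcorner", format(yllcorner, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  )
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
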