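#' Default land-cover legend
#'
#' Class labels and integer codes used throughout: forest plus the five matrix
#' habitat classes (oil palm, cattle pasture, river, residential, other
#' non-forest).
#' @return named integer vector mapping class label to raster code.
#' @export
default_legend <- function() {
  c(forest = 1L, oil_palm = 2L, pasture = 3L, river = 4L,
    residential = 5L, other = 6L)
}

#' Categorical land-cover raster
#'
#' A regular grid of integer class codes with an ESRI ASCII-grid georeference:
#' lower-left corner origin, square cells, cell-center coordinate convention
#' (`x = xll + (col - 0.5) * cellsize` for 1-based columns; row 1 is the top
#' row, so `y = yll + (nrows - row + 0.5) * cellsize`).
#'
#' @param codes integer matrix (nrows x ncols), row 1 = northmost row.
#' @param xll,yll coordinates of the lower-left corner (m).
#' @param cellsize cell edge length (m).
#' @param legend named integer vector mapping class label to code.
#' @param nodata integer NODATA code (cells excluded from all graphs).
#' @return an object of class `landscape_raster`.
#' @export
landscape_raster <- function(codes, xll = 0, yll = 0, cellsize = 20,
                             legend = default_legend(), nodata = -9999L) {
  codes <- as.matrix(codes); storage.mode(codes) <- "integer"
  .check(cellsize > 0, "cellsize must be positive")
  known <- c(unname(legend), nodata)
  bad <- setdiff(unique(as.vector(codes)), known)
  .check(length(bad) == 0, "unknown class code(s): %s (legend has %s)",
         paste(bad, collapse = ","), paste(legend, collapse = ","))
  structure(list(codes = codes, ncols = ncol(codes), nrows = nrow(codes),
                 xll = xll, yll = yll, cellsize = cellsize,
                 legend = legend, nodata = as.integer(nodata)),
            class = "landscape_raster")
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("landscape_raster: %d x %d cells, cellsize %g m\n",
              x$nrows, x$ncols, x$cellsize))
  tab <- table(factor(x$codes, levels = x$legend, labels = names(x$legend)))
  frac <- tab / sum(x$codes != x$nodata)
  for (k in names(tab)) if (tab[[k]] > 0)
    cat(sprintf("  %-12s %7d cells (%.1f%%)\n", k, tab[[k]], 100 * frac[[k]]))
  invisible(x)
}

#' Cell-center coordinates of every cell
#' @param raster a [landscape_raster()] or cost surface.
#' @return data.frame with `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(raster) {
  rc <- expand.grid(row = seq_len(raster$nrows), col = seq_len(raster$ncols))
  data.frame(rc,
             x = raster$xll + (rc$col - 0.5) * raster$cellsize,
             y = raster$yll + (raster$nrows - rc$row + 0.5) * raster$cellsize)
}

#' Snap projected points to grid cells
#' @param raster a [landscape_raster()] or cost surface.
#' @param x,y projected coordinates.
#' @return data.frame with 1-based `row`, `col`.
#' @export
snap_to_cell <- function(raster, x, y) {
  col <- floor((x - raster$xll) / raster$cellsize) + 1L
  row <- raster$nrows - floor((y - raster$yll) / raster$cellsize)
  .check(all(col >= 1 & col <= raster$ncols & row >= 1 & row <= raster$nrows),
         "point(s) outside raster extent")
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-keyword header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by
#' `nrows * ncols` integer class codes, northmost row first.
#'
#' @param path path to the `.asc` file.
#' @param legend named integer class legend; every non-NODATA code in the body
#'   must appear in it.
#' @return a [landscape_raster()].
#' @export
read_ascii_grid <- function(path, legend = default_legend()) {
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^[[:space:]]*[A-Za-z_]+[[:space:]]+-?[0-9.eE+-]+[[:space:]]*$",
               lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  .check(all(need %in% names(hdr)), "ASCII grid header missing: %s",
         paste(setdiff(need, names(hdr)), collapse = ","))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  .check(length(vals) == nc * nr,
         "ASCII grid body has %d values, expected %d x %d = %d",
         length(vals), nr, nc, nr * nc)
  nodata <- if (!is.null(hdr$nodata_value)) as.integer(hdr$nodata_value) else -9999L
  landscape_raster(matrix(vals, nrow = nr, ncol = nc, byrow = TRUE),
                   xll = hdr$xllcorner, yll = hdr$yllcorner,
                   cellsize = hdr$cellsize, legend = legend, nodata = nodata)
}

#' Write an ESRI ASCII grid
#' @param raster a [landscape_raster()] (or any list with the same grid
#'   fields, e.g. a cost surface written as numeric).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ascii_grid <- function(raster, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", raster$ncols),
               sprintf("nrows %d", raster$nrows),
               sprintf("xllcorner %.10g", raster$xll),
               sprintf("yllcorner %.10g", raster$yll),
               sprintf("cellsize %.10g", raster$cellsize),
               sprintf("NODATA_value %d", raster$nodata)), con)
  m <- if (!is.null(raster$codes)) raster$codes else raster$costs
  apply(m, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
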