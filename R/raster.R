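#' Construct a RasterGrid
#'
#' @param values numeric matrix, rows counted from the south (bottom) edge.
#' @param origin `(x, y)` of the lower-left corner, km.
#' @param cellSize cell side, km.
#' @param nodata missing-value sentinel.
#' @param crs free-text planar reference tag.
#' @return A [RasterGrid-class].
#' @export
rasterGrid <- function(values, origin = c(0, 0), cellSize = 1,
                       nodata = NODATA_DEFAULT, crs = "planar-km") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), nodata = as.numeric(nodata), crs = crs)
}

#' @describeIn rasterGrid Cell-value matrix (rows south to north).
#' @param x a `RasterGrid`.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname rasterGrid
#' @export
setMethod("values", "RasterGrid", function(x) x@values)

#' @describeIn rasterGrid Cell side length in km.
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname rasterGrid
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @describeIn rasterGrid `(xmin, ymin, xmax, ymax)` of the grid, km.
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' @rdname rasterGrid
#' @export
setMethod("gridExtent", "RasterGrid", function(x) {
  d <- dim(x@values)
  c(x@origin[1], x@origin[2],
    x@origin[1] + d[2] * x@cellSize, x@origin[2] + d[1] * x@cellSize)
})

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[object@values != object@nodata]
  cat(sprintf("RasterGrid %d rows x %d cols, cell %g km, origin (%g, %g)\n",
              d[1], d[2], object@cellSize, object@origin[1], object@origin[2]))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(object@values == object@nodata)))
})

setMethod("show", "LandscapeBundle", function(object) {
  cat(sprintf("LandscapeBundle: %d rasters (%s)\n  extent (%g, %g)-(%g, %g) km, cell %g km\n",
              length(object@rasters), paste(names(object@rasters), collapse = ", "),
              object@extent[1], object@extent[2], object@extent[3], object@extent[4],
              object@cellSize))
})

#' Cell-centre coordinates of a grid
#'
#' @param grid a [RasterGrid-class].
#' @return list with vectors `x` (per column) and `y` (per row) of centres, km.
#' @export
cellCentres <- function(grid) {
  d <- dim(grid@values)
  list(x = grid@origin[1] + (seq_len(d[2]) - 0.5) * grid@cellSize,
       y = grid@origin[2] + (seq_len(d[1]) - 0.5) * grid@cellSize)
}

#' Map points to grid cells
#'
#' Half-open cell intervals: a point on a cell's low edge belongs to that cell.
#'
#' @param grid a [RasterGrid-class].
#' @param x,y point coordinates, km.
#' @return data.frame with 1-based `row`, `col` and `inside` flag.
#' @export
pointToCell <- function(grid, x, y) {
  d <- dim(grid@values)
  col <- floor((x - grid@origin[1]) / grid@cellSize) + 1L
  row <- floor((y - grid@origin[2]) / grid@cellSize) + 1L
  inside <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract cell values at point locations
#'
#' @inheritParams pointToCell
#' @return numeric vector; NA outside the grid or on nodata cells.
#' @export
cellValueAt <- function(grid, x, y) {
  pc <- pointToCell(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- pc$inside
  out[ok] <- grid@values[cbind(pc$row[ok], pc$col[ok])]
  out[!is.na(out) & out == grid@nodata] <- NA_real_
  out
}

#' Exact Euclidean distance to the nearest feature cell
#'
#' Computes, for every cell centre, the distance (km) to the nearest centre of
#' a feature cell. Brute force over feature cells; intended for the moderate
#' grids used throughout (a few hundred columns).
#'
#' @param grid a [RasterGrid-class] giving the geometry.
#' @param feature logical matrix (same dim) marking feature cells.
#' @return [RasterGrid-class] of distances.
#' @export
distanceTransform <- function(grid, feature) {
  d <- dim(grid@values)
  stopifnot(all(dim(feature) == d))
  if (!any(feature)) stop("distanceTransform: no feature cells")
  cc <- cellCentres(grid)
  idx <- which(feature, arr.ind = TRUE)
  fx <- cc$x[idx[, 2]]; fy <- cc$y[idx[, 1]]
  dx2 <- outer(cc$x, fx, "-")^2   # ncols x nfeatures, reused every row
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    d2 <- dx2 + rep((cc$y[i] - fy)^2, each = d[2])
    out[i, ] <- sqrt(d2[cbind(seq_len(d[2]), max.col(-d2, ties.method = "first"))])
  }
  rasterGrid(out, grid@origin, grid@cellSize, grid@nodata, grid@crs)
}

#' Smooth a matrix with a separable Gaussian kernel
#'
#' Edge cells use a renormalised (truncated) kernel so smoothing preserves the
#' mean of constant fields.
#'
#' @param m numeric matrix.
#' @param sdCells kernel standard deviation in cell units.
#' @return smoothed matrix of the same dimension.
#' @export
gaussianSmooth <- function(m, sdCells) {
  if (sdCells <= 0) return(m)
  half <- max(1L, ceiling(3 * sdCells))
  k <- dnorm(seq(-half, half), sd = sdCells)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    padded <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
                    mat[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (o in seq_along(k)) out <- out + k[o] * padded[(o - 1) + seq_len(n), , drop = FALSE]
    out / sum(k)
  }
  t(smooth1(t(smooth1(m))))
}

#' Mean raster value within a circular buffer of each point
#'
#' Arithmetic mean over non-nodata cells whose centres lie within `radius` km
#' of the point; NA (flagged) when the buffer contains no valid cell.
#'
#' @param grid a [RasterGrid-class].
#' @param x,y point coordinates, km.
#' @param radius buffer radius, km (default 3.25, a typical village extent).
#' @return numeric vector of buffer means.
#' @export
bufferMean <- function(grid, x, y, radius = 3.25) {
  cc <- cellCentres(grid)
  v <- grid@values
  v[v == grid@nodata] <- NA
  d <- dim(v)
  cs <- grid@cellSize
  out <- numeric(length(x))
  span <- ceiling(radius / cs) + 1L
  for (i in seq_along(x)) {
    pc <- pointToCell(grid, x[i], y[i])
    rows <- max(1L, pc$row - span):min(d[1], pc$row + span)
    cols <- max(1L, pc$col - span):min(d[2], pc$col + span)
    if (pc$row > d[1] + span || pc$row < 1L - span ||
        pc$col > d[2] + span || pc$col < 1L - span || length(rows) == 0) {
      out[i] <- NA_real_
      next
    }
    dx2 <- (cc$x[cols] - x[i])^2
    dy2 <- (cc$y[rows] - y[i])^2
    inb <- outer(dy2, dx2, "+") <= radius^2
    vals <- v[rows, cols, drop = FALSE][inb]
    out[i] <- if (all(is.na(vals)) || length(vals) == 0) NA_real_ else
      mean(vals, na.rm = TRUE)
  }
  out
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text single-band interchange (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header then rows north to south), readable by
#' standard GIS tools. Values are written at full double precision so a
#' write/read round trip is exact.
#'
#' @param grid a [RasterGrid-class].
#' @param path file path (conventionally `.asc`).
#' @return `readAsciiGrid` returns a [RasterGrid-class]; `writeAsciiGrid`
#'   returns `path` invisibly.
#' @export
writeAsciiGrid <- function(grid, path) {
  d <- dim(grid@values)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", grid@origin[1]),
           sprintf("yllcorner %.10g", grid@origin[2]),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", grid@nodata))
  rows <- apply(grid@values[rev(seq_len(d[1])), , drop = FALSE], 1,
                function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  h <- setNames(vals, keys)
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  stopifnot(nrow(m) == h[["nrows"]], ncol(m) == h[["ncols"]])
  rasterGrid(m[rev(seq_len(nrow(m))), , drop = FALSE],
             origin = c(h[["xllcorner"]], h[["yllcorner"]]),
             cellSize = h[["cellsize"]], nodata = h[["nodata_value"]])
}
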