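## Minimal planar raster container used throughout the package.
##
## Values are stored in a matrix with rows = y (south to north) and
## columns = x (west to east); cell (i, j) has its center at
## (xmin + (j - 1/2) * cellsize, ymin + (i - 1/2) * cellsize).
## Coordinates are kilometres in planar mode ("planar_km") or degrees
## in geographic mode ("lonlat"); all synthetic worlds are planar.

#' Create a sea_grid raster
#'
#' @param values numeric matrix, rows = y (south first), cols = x.
#' @param xmin,ymin coordinates of the grid's lower-left corner.
#' @param cellsize cell edge length (km in planar mode).
#' @param coord_mode `"planar_km"` or `"lonlat"`.
#' @return an object of class `sea_grid`.
#' @export
sea_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                     coord_mode = c("planar_km", "lonlat")) {
  coord_mode <- match.arg(coord_mode)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, nx = ncol(values), ny = nrow(values),
                 coord_mode = coord_mode),
            class = "sea_grid")
}

#' @export
print.sea_grid <- function(x, ...) {
  cat(sprintf("<sea_grid> %d x %d cells, cellsize %g, origin (%g, %g), %s\n",
              x$nx, x$ny, x$cellsize, x$xmin, x$ymin, x$coord_mode))
  invisible(x)
}

#' Coordinates of all cell centers of a grid
#'
#' @param grid a [sea_grid()].
#' @return data.frame with columns `x`, `y`, `row`, `col` in matrix order
#'   (column-major over the values matrix).
#' @export
grid_centers <- function(grid) {
  xs <- grid$xmin + (seq_len(grid$nx) - 0.5) * grid$cellsize
  ys <- grid$ymin + (seq_len(grid$ny) - 0.5) * grid$cellsize
  data.frame(x = rep(xs, each = grid$ny), y = rep(ys, times = grid$nx),
             row = rep(seq_len(grid$ny), times = grid$nx),
             col = rep(seq_len(grid$nx), each = grid$ny))
}

#' Row/column indices of the cells containing points
#'
#' Points on a cell edge belong to the cell to the north-east of the edge;
#' points outside the extent get NA.
#'
#' @param grid a [sea_grid()].
#' @param x,y point coordinates.
#' @return data.frame with integer columns `row`, `col` (NA outside extent).
#' @export
cell_of <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row <- floor((y - grid$ymin) / grid$cellsize) + 1L
  bad <- col < 1L | col > grid$nx | row < 1L | row > grid$ny |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Nearest-cell raster lookup
#'
#' @param grid a [sea_grid()].
#' @param x,y point coordinates.
#' @return vector of cell values (NA outside extent).
#' @export
grid_lookup <- function(grid, x, y) {
  rc <- cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Center coordinates of given cells
#' @param grid a [sea_grid()].
#' @param row,col integer indices.
#' @return data.frame x, y.
#' @export
cell_center <- function(grid, row, col) {
  data.frame(x = grid$xmin + (col - 0.5) * grid$cellsize,
             y = grid$ymin + (row - 0.5) * grid$cellsize)
}

## separable box smoothing, applied k times: cheap approximate Gaussian blur
smooth_field <- function(m, passes = 3L, width = 5L) {
  if (width < 2L) return(m)
  if (width %% 2L == 0L) width <- width + 1L  # symmetric kernel
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  sm1 <- function(v) {
    vv <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
    as.numeric(stats::filter(vv, k, sides = 2))[(pad + 1L):(pad + length(v))]
  }
  for (i in seq_len(passes)) {
    if (nrow(m) >= width) m <- apply(m, 2L, sm1)
    if (ncol(m) >= width) m <- t(apply(t(m), 2L, sm1))
  }
  m
}

## correlated Gaussian random field via smoothed white noise, sd standardized
random_field <- function(ny, nx, smoothness = 5L, passes = 3L) {
  f <- smooth_field(matrix(rnorm(ny * nx), ny, nx),
                    passes = passes, width = max(2L, as.integer(smoothness)))
  f <- f - mean(f)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#'
#' @param grid a [sea_grid()].
#' @param path output file.
#' @param na_value NODATA value written for NA cells.
#' @export
write_asc <- function(grid, path, na_value = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$nx),
               sprintf("nrows %d", grid$ny),
               sprintf("xllcorner %g", grid$xmin),
               sprintf("yllcorner %g", grid$ymin),
               sprintf("cellsize %g", grid$cellsize),
               sprintf("NODATA_value %g", na_value)), con)
  v <- grid$values
  v[is.na(v)] <- na_value
  ## ASCII grids are written north row first
  for (i in rev(seq_len(grid$ny)))
    writeLines(paste(format(v[i, ], trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster into a sea_grid
#' @param path input file.
#' @param coord_mode coordinate mode stamp.
#' @return a [sea_grid()].
#' @export
read_asc <- function(path, coord_mode = "planar_km") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  sea_grid(m[rev(seq_len(nrow(m))), , drop = FALSE],
           xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
           cellsize = h[["cellsize"]], coord_mode = coord_mode)
}

## ---- polygon helpers (planar) ----

#' Signed polygon area by the shoelace formula
#' @param xy two-column matrix of vertices (closed or open ring).
#' @return area (absolute value, square units of the coordinates).
#' @export
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) stop("polygon needs >= 3 vertices")
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Test whether points fall inside a polygon
#' @param xy polygon vertices (two-column matrix, open ring).
#' @param px,py point coordinates.
#' @return logical vector.
#' @export
point_in_polygon <- function(xy, px, py) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  mgcv::in.out(rbind(xy, xy[1, ]), cbind(px, py))
}

#' Planar Euclidean distance in km
#' @param x1,y1,x2,y2 coordinates.
#' @return numeric distances.
#' @keywords internal
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

#' Write point features as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for point tables (haulout
#' catalogs, coastline vertex sets). Coordinates are written as-is in the
#' declared planar-km or lon/lat frame.
#'
#' @param points data.frame with `x`, `y` and any property columns.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_geojson_points <- function(points, path) {
  props <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
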