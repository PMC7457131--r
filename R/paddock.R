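# paddock geometry container: boundary ring, DEM, water points

#' Paddock geometry
#'
#' Bundles everything the movement module needs to know about one paddock:
#' the boundary ring (projected metric coordinates), a digital elevation
#' model, and the water points accessible inside the paddock.
#'
#' @param paddock_id,pasture_id Identifiers.
#' @param boundary Two-column matrix (x, y) of the boundary ring in metres,
#'   or a WKT POLYGON string.
#' @param dem A list as returned by [read_esri_ascii()] (`z` matrix south
#'   row first, `xll`, `yll`, `cellsize`); must cover the boundary.
#' @param water Two-column matrix of water-point coordinates (>= 1 point).
#' @param area_ha Paddock area in hectares; computed from the boundary by
#'   the shoelace formula when omitted.
#' @return An object of class `paddock`.
#' @export
paddock <- function(paddock_id, pasture_id, boundary, dem, water,
                    area_ha = NULL) {
  if (is.character(boundary)) boundary <- parse_wkt_polygon(boundary)
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3) abort_bad_arg("boundary needs >= 3 vertices.")
  if (!is_simple_polygon(boundary[, 1], boundary[, 2])) {
    abort_bad_arg("paddock boundary must be a simple polygon.")
  }
  water <- matrix(as.numeric(water), ncol = 2)
  if (nrow(water) < 1 || anyNA(water)) {
    abort_bad_arg("at least one water point is required.")
  }
  stopifnot(is.list(dem), is.matrix(dem$z))
  # DEM must cover the boundary bbox
  dem_xmax <- dem$xll + ncol(dem$z) * dem$cellsize
  dem_ymax <- dem$yll + nrow(dem$z) * dem$cellsize
  eps <- 1e-9
  if (min(boundary[, 1]) < dem$xll - eps || max(boundary[, 1]) > dem_xmax + eps ||
      min(boundary[, 2]) < dem$yll - eps || max(boundary[, 2]) > dem_ymax + eps) {
    abort_bad_arg("DEM does not cover the paddock boundary.")
  }
  area_ha <- area_ha %||% (polygon_area(boundary[, 1], boundary[, 2]) / 1e4)
  structure(
    list(paddock_id = as.character(paddock_id),
         pasture_id = as.character(pasture_id),
         boundary = boundary, dem = dem, water = water,
         area_ha = area_ha),
    class = "paddock"
  )
}

#' @export
print.paddock <- function(x, ...) {
  cat(sprintf("<paddock %s (pasture %s): %.2f ha, %d boundary vertices, %d water point(s)>\n",
              x$paddock_id, x$pasture_id, x$area_ha, nrow(x$boundary),
              nrow(x$water)))
  invisible(x)
}

# shared 5 m grid geometry anchored at the boundary bbox lower-left corner;
# cells are half-open [x0 + i*cs, x0 + (i+1)*cs)
grid_spec <- function(pad, cell_size = 5) {
  bx <- pad$boundary[, 1]; by <- pad$boundary[, 2]
  x0 <- min(bx); y0 <- min(by)
  nx <- ceiling((max(bx) - x0) / cell_size)
  ny <- ceiling((max(by) - y0) / cell_size)
  cx <- x0 + (seq_len(nx) - 0.5) * cell_size
  cy <- y0 + (seq_len(ny) - 0.5) * cell_size
  centers_x <- matrix(rep(cx, each = ny), nrow = ny)
  centers_y <- matrix(rep(cy, times = nx), nrow = ny)
  mask <- matrix(point_in_polygon(as.vector(centers_x), as.vector(centers_y),
                                  bx, by), nrow = ny)
  list(x0 = x0, y0 = y0, nx = nx, ny = ny, cell_size = cell_size,
       centers_x = centers_x, centers_y = centers_y, mask = mask)
}

# nearest-neighbour sample of a DEM-aligned matrix at arbitrary points
sample_raster <- function(dem, z, px, py) {
  j <- pmin(pmax(floor((px - dem$xll) / dem$cellsize) + 1, 1), ncol(z))
  i <- pmin(pmax(floor((py - dem$yll) / dem$cellsize) + 1, 1), nrow(z))
  z[cbind(i, j)]
}
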