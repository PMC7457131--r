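# planar geometry primitives: shoelace area, simplicity check,
# point-in-polygon, WKT POLYGON text, Esri ASCII grids.
# All coordinates are assumed to be in a projected metric (or calibrated cm)
# system already; no geodetic transforms are performed anywhere.

#' Area of a simple polygon (shoelace formula)
#'
#' Computes the unsigned area enclosed by an ordered vertex ring. The result
#' does not depend on vertex orientation (clockwise or counter-clockwise),
#' and the ring may be given open (first vertex not repeated) or closed.
#'
#' @param x,y Numeric vectors of vertex coordinates (same length, >= 3
#'   distinct vertices), e.g. claw-outline traces in calibrated cm.
#' @param check If `TRUE` (default) the ring is checked for
#'   self-intersection and an error is raised for non-simple polygons.
#' @return A single non-negative number in squared input units.
#' @examples
#' polygon_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # unit square -> 1
#' polygon_area(c(0, 4, 0), c(0, 0, 3))       # right triangle -> 6
#' @export
polygon_area <- function(x, y, check = TRUE) {
  check_number(x, "x"); check_number(y, "y")
  if (length(x) != length(y)) abort_bad_arg("`x` and `y` must have the same length.")
  # drop a repeated closing vertex
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) abort_bad_arg("a polygon needs at least 3 vertices.")
  if (check && !is_simple_polygon(x, y)) {
    abort_bad_arg("polygon is self-intersecting; outlines must be simple rings.")
  }
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# segment (p1,p2) vs (p3,p4) proper/improper intersection test
segments_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- d(x3, y3, x4, y4, x1, y1)
  d2 <- d(x3, y3, x4, y4, x2, y2)
  d3 <- d(x1, y1, x2, y2, x3, y3)
  d4 <- d(x1, y1, x2, y2, x4, y4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(ax, ay, bx, by, cx, cy) {
    min(ax, bx) <= cx && cx <= max(ax, bx) && min(ay, by) <= cy && cy <= max(ay, by)
  }
  (d1 == 0 && on_seg(x3, y3, x4, y4, x1, y1)) ||
    (d2 == 0 && on_seg(x3, y3, x4, y4, x2, y2)) ||
    (d3 == 0 && on_seg(x1, y1, x2, y2, x3, y3)) ||
    (d4 == 0 && on_seg(x1, y1, x2, y2, x4, y4))
}

# O(n^2) simplicity check; outlines are small (tens of vertices)
is_simple_polygon <- function(x, y) {
  n <- length(x)
  ix2 <- c(2:n, 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_intersect(x[i], y[i], x[ix2[i]], y[ix2[i]],
                             x[j], y[j], x[ix2[j]], y[ix2[j]])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# even-odd ray-casting point-in-polygon; px, py may be vectors
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Parse a WKT POLYGON string
#'
#' Reads the outer ring of a `POLYGON ((x y, x y, ...))` text into a
#' two-column matrix. Interior rings (holes) are not supported; paddock
#' boundaries are simple rings.
#'
#' @param wkt A single WKT character string.
#' @return A matrix with columns `x` and `y` (closing vertex removed).
#' @export
parse_wkt_polygon <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1)
  body <- sub("(?i)^\\s*POLYGON\\s*\\(\\s*\\(", "", wkt, perl = TRUE)
  if (identical(body, wkt)) abort_bad_arg("not a WKT POLYGON string.")
  body <- sub("\\)\\s*\\)\\s*$", "", body)
  if (grepl("\\)\\s*,\\s*\\(", body)) {
    abort_bad_arg("WKT polygons with interior rings are not supported.")
  }
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  m <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  if (anyNA(m)) abort_bad_arg("malformed WKT coordinate pair.")
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' @rdname parse_wkt_polygon
#' @param ring A two-column matrix of vertices.
#' @export
format_wkt_polygon <- function(ring) {
  ring <- rbind(ring, ring[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6g %.6g", ring[, 1], ring[, 2]), collapse = ", "))
}

#' Read and write Esri ASCII grids
#'
#' A minimal reader/writer for the Esri ASCII raster interchange format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header
#' followed by rows of values, north row first). Values come back as a
#' numeric matrix in map orientation: `z[row 1, ]` is the *southernmost*
#' row, so `z[i, j]` sits at x = xll + (j - 1/2) * cellsize,
#' y = yll + (i - 1/2) * cellsize.
#'
#' @param path File path.
#' @return For `read_esri_ascii`, a list with `z` (matrix, south row first),
#'   `xll`, `yll`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows) {
    abort_bad_arg("Esri ASCII grid: value count does not match header.")
  }
  z <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  z[z == nodata] <- NA_real_
  z <- z[nrows:1, , drop = FALSE] # store south row first
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  list(z = z, xll = xll, yll = yll, cellsize = hdr$cellsize, nodata = nodata)
}

#' @rdname read_esri_ascii
#' @param grid A list as returned by `read_esri_ascii` (matrix `z` south row
#'   first plus `xll`, `yll`, `cellsize`).
#' @export
write_esri_ascii <- function(grid, path) {
  z <- grid$z
  nodata <- grid$nodata %||% -9999
  zo <- z[nrow(z):1, , drop = FALSE] # back to north row first
  zo[is.na(zo)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(z)),
    sprintf("nrows %d", nrow(z)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(zo, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
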