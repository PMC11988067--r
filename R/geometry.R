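#' Build a rectangular paddock polygon of a given area
#'
#' Returns an axis-aligned rectangle in projected meters whose area equals
#' `area_m2` exactly. The study-scale default is a paddock of 36,421.74 m^2
#' (one sixth of a ~22 ha experimental pasture).
#'
#' @param area_m2 Paddock area in square meters (> 0).
#' @param aspect Width/height ratio (default 1, a square).
#' @param origin Numeric length-2, lower-left corner in projected meters.
#' @return A closed polygon: data.frame with columns `x`, `y` (first vertex
#'   repeated at the end), in projected meters.
#' @examples
#' p <- default_paddock(36421.74)
#' polygon_area(p)
#' @export
default_paddock <- function(area_m2, aspect = 1,
                            origin = c(432000, 4641000)) {
  if (!is.finite(area_m2) || area_m2 <= 0) stopf("`area_m2` must be > 0")
  if (!is.finite(aspect) || aspect <= 0) stopf("`aspect` must be > 0")
  h <- sqrt(area_m2 / aspect)
  w <- area_m2 / h
  data.frame(
    x = origin[1] + c(0, w, w, 0, 0),
    y = origin[2] + c(0, 0, h, h, 0)
  )
}

#' Shoelace area of a polygon
#'
#' @param poly data.frame with columns `x`, `y` (closed or open ring).
#' @return Area in squared units of the coordinates.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Distance from points to the polygon boundary (min over edges).
dist_to_boundary <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    len2 <- ex^2 + ey^2
    t <- ((px - x[i]) * ex + (py - y[i]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    dx <- px - (x[i] + t * ex); dy <- py - (y[i] + t * ey)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Test whether points lie inside a polygon, optionally inset by a buffer
#'
#' With `buffer_m > 0` a point qualifies only if it is inside the polygon
#' and at least `buffer_m` meters from its boundary — the point-query
#' equivalent of eroding (negatively buffering) the polygon, used to drop
#' fence-adjacent GPS fixes whose ~10 m positional error could place them
#' in a neighboring paddock.
#'
#' @param px,py Numeric vectors of projected coordinates (meters).
#' @param poly Polygon data.frame with columns `x`, `y`.
#' @param buffer_m Inward buffer distance in meters (default 0).
#' @return Logical vector.
#' @export
in_paddock <- function(px, py, poly, buffer_m = 0) {
  inside <- as.logical(pracma::inpolygon(px, py, poly$x, poly$y,
                                         boundary = TRUE))
  if (buffer_m > 0) {
    inside <- inside & dist_to_boundary(px, py, poly) >= buffer_m
  }
  inside
}

#' Write / read a paddock polygon as GeoJSON
#'
#' The polygon is stored in projected meters; the projected CRS is recorded
#' in a `crs` property on the feature (default EPSG:32612, UTM 12N).
#'
#' @param poly Polygon data.frame with columns `x`, `y`.
#' @param path Output file path.
#' @param crs CRS identifier string stored alongside the coordinates.
#' @return `path`, invisibly.
#' @export
write_paddock_geojson <- function(poly, path, crs = "EPSG:32612") {
  x <- poly$x; y <- poly$y
  n <- length(x)
  if (!(x[1] == x[n] && y[1] == y[n])) { x <- c(x, x[1]); y <- c(y, y[1]) }
  ring <- lapply(seq_along(x), function(i) c(x[i], y[i]))
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(crs = crs),
      geometry = list(type = "Polygon", coordinates = list(ring))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_paddock_geojson
#' @export
read_paddock_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  data.frame(
    x = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
    y = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
  )
}
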