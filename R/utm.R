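#' Project WGS84 coordinates to UTM (default zone 12N)
#'
#' Forward transverse-Mercator projection onto the UTM grid using the
#' standard series expansion on the WGS84 ellipsoid (scale factor 0.9996,
#' 500 km false easting). The default zone 12N covers northern Utah, where
#' the collar data this package targets were collected.
#'
#' @param lat,lon Numeric vectors of latitude/longitude in decimal degrees
#'   (WGS84). Recycled to common length.
#' @param zone UTM zone number (default 12).
#' @return A data.frame with columns `easting` and `northing`, in meters.
#' @examples
#' project_to_utm(41.9227, -111.8136)
#' @seealso [utm_to_lonlat()] for the inverse.
#' @export
project_to_utm <- function(lat, lon, zone = 12L) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stopf("latitude and longitude must be finite")
  }
  if (any(lat < -90 | lat > 90)) stopf("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180)) stopf("longitude out of [-180, 180]")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)

  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (zone * 6 - 183) * pi / 180

  phi <- lat * pi / 180
  lam <- lon * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- cos(phi) * (lam - lon0)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  easting <- 500000 + k0 * N * (A + (1 - Tt + C) * A^3 / 6 +
    (5 - 18 * Tt + Tt^2 + 72 * C - 58 * ep2) * A^5 / 120)
  northing <- k0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * Tt + Tt^2 + 600 * C - 330 * ep2) * A^6 / 720))
  data.frame(easting = easting, northing = northing)
}

#' Inverse UTM projection back to WGS84 degrees
#'
#' @param easting,northing Numeric vectors of projected coordinates in meters.
#' @param zone UTM zone number (default 12).
#' @return A data.frame with columns `lat` and `lon` in decimal degrees.
#' @export
utm_to_lonlat <- function(easting, northing, zone = 12L) {
  n <- max(length(easting), length(northing))
  easting <- rep_len(easting, n); northing <- rep_len(northing, n)

  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lon0 <- (zone * 6 - 183) * pi / 180
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))

  M <- northing / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)

  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- (easting - 500000) / (N1 * k0)

  phi <- phi1 - (N1 * tan(phi1) / R1) * (D^2 / 2 -
    (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
    (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lon0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
    (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  data.frame(lat = phi * 180 / pi, lon = lam * 180 / pi)
}
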