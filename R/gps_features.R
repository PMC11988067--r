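#' Cleaning rules for raw collar fixes
#'
#' Encodes the fix-quality screen applied before feature extraction: a fix
#' is retained only when it was computed from at least `min_satellites`
#' satellites, its altitude falls inside the plausible window for the site,
#' it is spaced at least `min_interval` seconds after the previous retained
#' fix of the same animal, and its projected position lies inside the
#' paddock inset (inward-buffered) by `buffer_m` meters.
#'
#' @param min_satellites Minimum satellite count (default 4).
#' @param altitude_window Numeric length-2, plausible altitude range in
#'   meters (default `c(1500, 1570)`, the site's elevation band).
#' @param min_interval Minimum spacing to the previous kept fix, in seconds
#'   (default 300, the collar's 5-min schedule).
#' @param paddock Polygon data.frame (`x`, `y`) in projected meters, or NULL
#'   to skip the spatial rule.
#' @param buffer_m Inward buffer in meters (default 10, matching the
#'   collars' ~10 m positional accuracy).
#' @return An object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(min_satellites = 4L,
                           altitude_window = c(1500, 1570),
                           min_interval = 300,
                           paddock = NULL,
                           buffer_m = 10) {
  if (length(altitude_window) != 2 ||
      altitude_window[1] >= altitude_window[2]) {
    stopf("`altitude_window` must be c(low, high) with low < high")
  }
  if (buffer_m < 0) stopf("`buffer_m` must be >= 0")
  if (min_interval <= 0) stopf("`min_interval` must be > 0")
  structure(list(min_satellites = as.integer(min_satellites),
                 altitude_window = as.numeric(altitude_window),
                 min_interval = as.numeric(min_interval),
                 paddock = paddock,
                 buffer_m = as.numeric(buffer_m)),
            class = "cleaning_rules")
}

#' Screen raw fixes against the cleaning rules
#'
#' Rules are applied in a fixed order — satellites, altitude, interval,
#' paddock — and each rejected fix is tagged with the first rule it failed.
#' The interval rule is enforced against the previous *kept* fix of the same
#' animal, so the filter is sequential per animal but idempotent: cleaning
#' the kept set again removes nothing.
#'
#' @param fixes data.frame of collar fixes with at least columns
#'   `animal_id`, `gmt_time` (POSIXct), `altitude_m`, `satellites`,
#'   `easting`, `northing`. Must be time-sorted within each animal.
#' @param rules A [cleaning_rules()] object.
#' @return A list with `kept` (data.frame, subset of `fixes`) and
#'   `rejected` (the dropped rows plus a `reason` column).
#' @export
clean_fixes <- function(fixes, rules = cleaning_rules()) {
  if (nrow(fixes) == 0) {
    return(list(kept = fixes,
                rejected = cbind(fixes, reason = character(0))))
  }
  ord_ok <- tapply(as.numeric(fixes$gmt_time), fixes$animal_id,
                   function(t) all(diff(t) >= 0))
  if (!all(ord_ok)) stopf("fixes must be time-sorted within each animal")

  inside <- if (is.null(rules$paddock)) rep(TRUE, nrow(fixes)) else {
    in_paddock(fixes$easting, fixes$northing, rules$paddock, rules$buffer_m)
  }

  reason <- rep(NA_character_, nrow(fixes))
  keep <- rep(FALSE, nrow(fixes))
  for (id in unique(fixes$animal_id)) {
    idx <- which(fixes$animal_id == id)
    last_kept_t <- -Inf
    for (i in idx) {
      if (fixes$satellites[i] < rules$min_satellites) {
        reason[i] <- "satellites"
      } else if (fixes$altitude_m[i] < rules$altitude_window[1] ||
                 fixes$altitude_m[i] > rules$altitude_window[2]) {
        reason[i] <- "altitude"
      } else if (as.numeric(fixes$gmt_time[i]) - last_kept_t <
                 rules$min_interval) {
        reason[i] <- "interval"
      } else if (!inside[i]) {
        reason[i] <- "paddock"
      } else {
        keep[i] <- TRUE
        last_kept_t <- as.numeric(fixes$gmt_time[i])
      }
    }
  }
  rejected <- fixes[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = fixes[keep, , drop = FALSE], rejected = rejected)
}

#' Per-step movement metrics from consecutive fixes
#'
#' Distance is the planar Euclidean distance between consecutive projected
#' positions (the data are in UTM meters before analysis; at paddock scale
#' planar and geodesic distance agree to well under 0.5%). Speed is distance
#' over elapsed minutes. The first fix of the sequence gets distance and
#' speed 0 by convention so feature rows align one-to-one with fixes.
#'
#' @param fixes Time-sorted data.frame with columns `gmt_time`, `easting`,
#'   `northing` for a single animal(-day) track.
#' @return data.frame with columns `distance` (m) and `speed` (m/min).
#' @export
step_metrics <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) stopf("step_metrics needs at least 2 fixes")
  t <- as.numeric(fixes$gmt_time)
  if (any(diff(t) < 0)) stopf("fixes must be time-sorted")
  if (any(diff(t) == 0)) stopf("duplicate timestamps in fixes")
  dx <- diff(fixes$easting); dy <- diff(fixes$northing)
  d <- c(0, sqrt(dx^2 + dy^2))
  dt_min <- c(1, diff(t) / 60)
  data.frame(distance = d, speed = d / dt_min)
}

#' Movement bearing relative to due east
#'
#' Two-argument arc-tangent of the displacement (northing change over
#' easting change), converted to degrees: due east is 0, counter-clockwise
#' positive, result in (-180, 180].
#'
#' @param first,last Numeric length-2 projected points `c(easting, northing)`.
#' @return Bearing in degrees.
#' @export
movement_bearing <- function(first, last) {
  de <- last[1] - first[1]; dn <- last[2] - first[2]
  if (de == 0 && dn == 0) stopf("bearing undefined for identical points")
  deg <- atan2(dn, de) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Straightness index of a track
#'
#' Straight-line displacement from the first to the last point divided by
#' the cumulative step-path length. 1 means perfectly straight monotone
#' travel; an out-and-back path scores 0.
#'
#' @param track data.frame with columns `x`, `y` (or `easting`, `northing`)
#'   of at least 2 projected points.
#' @return A number in \[0, 1\].
#' @export
straightness_index <- function(track) {
  if (!is.null(track$easting)) {
    x <- track$easting; y <- track$northing
  } else {
    x <- track$x; y <- track$y
  }
  n <- length(x)
  if (n < 2) stopf("straightness_index needs at least 2 points")
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path == 0) stopf("straightness undefined for zero-length path")
  disp <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  min(disp / path, 1)
}
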