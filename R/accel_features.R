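#' Basic activity-count aggregates
#'
#' Sums and means of the three per-fix activity channels, plus their
#' absolute-value variants. On count data (non-negative) the absolute
#' variants coincide with the raw ones; both are kept because the feature
#' set is defined over signed accelerometer channels in general.
#'
#' @param x,y,z Numeric vectors of per-fix activity counts.
#' @return data.frame with columns `sum_xyz`, `avg_xyz`, `abs_x`, `abs_y`,
#'   `abs_z`, `sum_xyz_abs`, `avg_sum_xyz_abs`.
#' @export
basic_aggregates <- function(x, y, z) {
  data.frame(
    sum_xyz = x + y + z,
    avg_xyz = (x + y + z) / 3,
    abs_x = abs(x), abs_y = abs(y), abs_z = abs(z),
    sum_xyz_abs = abs(x) + abs(y) + abs(z),
    avg_sum_xyz_abs = (abs(x) + abs(y) + abs(z)) / 3
  )
}

#' Activity index (Euclidean norm of the activity counts)
#'
#' `sqrt(x^2 + y^2 + z^2)` per fix — an overall movement-intensity index
#' (the magnitude of the per-interval activity vector). High values indicate
#' active behaviors, low values rest.
#'
#' @inheritParams basic_aggregates
#' @return Non-negative numeric vector.
#' @examples
#' actindex(3, 4, 0)  # 5
#' @export
actindex <- function(x, y, z) sqrt(x^2 + y^2 + z^2)

#' Dynamic (static-removed) components of the activity channels
#'
#' Subtracts a centered running mean (the static estimate) from each
#' channel. The default window of 3 fixes spans 15 min at the collars'
#' 5-min schedule. At the series edges the window shrinks symmetrically.
#'
#' @param x,y,z Numeric vectors (one series per channel, time-ordered).
#' @param window Odd positive integer window length in fixes (default 3).
#' @return data.frame with columns `dx`, `dy`, `dz`.
#' @export
dynamic_components <- function(x, y, z, window = 3L) {
  data.frame(
    dx = x - centered_running_mean(x, window),
    dy = y - centered_running_mean(y, window),
    dz = z - centered_running_mean(z, window)
  )
}

#' Overall / vectorial dynamic body acceleration
#'
#' ODBA is the L1 norm `|dx| + |dy| + |dz|` of the dynamic components;
#' VEDBA is the L2 norm `sqrt(dx^2 + dy^2 + dz^2)`. ODBA >= VEDBA always,
#' with equality iff at most one component is nonzero.
#'
#' @param dx,dy,dz Numeric vectors of dynamic components (see
#'   [dynamic_components()]).
#' @return Non-negative numeric vector.
#' @export
odba <- function(dx, dy, dz) abs(dx) + abs(dy) + abs(dz)

#' @rdname odba
#' @export
vedba <- function(dx, dy, dz) sqrt(dx^2 + dy^2 + dz^2)

#' Orientation angles from the activity channels
#'
#' `pitch_angle` is `atan(x / sqrt(y^2 + z^2))`, `roll_angle` is
#' `atan(y / sqrt(x^2 + z^2))`, both in degrees in \[-90, 90\]. When the
#' denominator is zero and the numerator nonzero, the limit value
#' (+/-90 degrees) is returned; an all-zero sample has no orientation and
#' raises an error.
#'
#' @inheritParams basic_aggregates
#' @return Numeric vector of degrees.
#' @export
pitch_angle <- function(x, y, z) {
  if (any(x == 0 & y == 0 & z == 0)) {
    stopf("orientation undefined for an all-zero sample")
  }
  atan2(x, sqrt(y^2 + z^2)) * 180 / pi
}

#' @rdname pitch_angle
#' @export
roll_angle <- function(x, y, z) {
  if (any(x == 0 & y == 0 & z == 0)) {
    stopf("orientation undefined for an all-zero sample")
  }
  atan2(y, sqrt(x^2 + z^2)) * 180 / pi
}

#' Energy expenditure over a bout
#'
#' Cumulative sum of the activity index over the fixes whose timestamp
#' falls inside the bout's half-open interval `[start, end)` — the total
#' activity expended while the behavior was observed.
#'
#' @param times POSIXct (or numeric) fix timestamps aligned with
#'   `actindex_series`.
#' @param actindex_series Numeric vector of per-fix activity-index values.
#' @param start,end Bout interval bounds (same class as `times`).
#' @return Non-negative number; 0 with a warning if the bout covers no fix.
#' @export
energy_expenditure <- function(times, actindex_series, start, end) {
  inb <- as.numeric(times) >= as.numeric(start) &
    as.numeric(times) < as.numeric(end)
  if (!any(inb)) {
    warning("bout covers no fixes; energy expenditure is 0")
    return(0)
  }
  sum(actindex_series[inb])
}

#' Combined GPS x accelerometer product features
#'
#' Element-wise products of the movement metrics with the intensity
#' metrics; the default pairing is \{distance, speed\} x \{actindex, odba,
#' vedba\} (6 columns).
#'
#' @param step data.frame with the GPS metric columns named in `gps_cols`.
#' @param accel data.frame with the intensity columns named in `accel_cols`.
#' @param gps_cols,accel_cols Character vectors naming the columns to cross.
#' @return data.frame of products named `<gps>_x_<accel>`.
#' @export
combined_features <- function(step, accel,
                              gps_cols = c("distance", "speed"),
                              accel_cols = c("actindex", "odba", "vedba")) {
  out <- list()
  for (g in gps_cols) for (a in accel_cols) {
    out[[paste(g, "x", a, sep = "_")]] <- step[[g]] * accel[[a]]
  }
  as.data.frame(out)
}

#' Stable column order of the full per-fix feature matrix
#'
#' The canonical feature set produced by [build_features()]: the three raw
#' channels, their aggregates, activity index, windowed energy, ODBA,
#' VEDBA, pitch, roll, the movement metrics and the six combined products.
#'
#' @return Character vector of column names.
#' @export
feature_columns <- function() {
  c("x", "y", "z", "sum_xyz", "avg_xyz", "abs_x", "abs_y", "abs_z",
    "sum_xyz_abs", "avg_sum_xyz_abs", "actindex", "energy", "odba", "vedba",
    "pitch", "roll", "distance", "speed", "bearing", "straightness",
    "distance_x_actindex", "distance_x_odba", "distance_x_vedba",
    "speed_x_actindex", "speed_x_odba", "speed_x_vedba")
}

#' Build the full per-fix feature matrix from cleaned fixes
#'
#' Computes, per animal-day track, the movement metrics (distance, speed,
#' bearing, cumulative-from-day-start straightness), the accelerometer
#' features (aggregates, activity index, windowed energy, ODBA/VEDBA on
#' running-mean dynamic components, pitch, roll) and the combined products,
#' and returns one feature row per fix in a stable column order.
#'
#' Row-level conventions that keep the matrix dense: the first fix of each
#' track has distance, speed and bearing 0 and straightness 1; an all-zero
#' activity sample gets pitch and roll 0; the per-fix `energy` feature is
#' the trailing-window sum of the activity index (window shared with
#' `window`), since true bout boundaries are unknown at prediction time.
#'
#' @param fixes Cleaned, time-sorted fix data.frame (columns `animal_id`,
#'   `gmt_time`, `easting`, `northing`, `x`, `y`, `z`; a `day` column is
#'   used for track grouping when present, else the UTC date).
#' @param window Odd window (fixes) for the dynamic components and the
#'   energy feature (default 3).
#' @return data.frame: `animal_id`, `gmt_time`, then the columns of
#'   [feature_columns()].
#' @export
build_features <- function(fixes, window = 3L) {
  day <- fixes$day %||% format(fixes$gmt_time, "%Y-%m-%d", tz = "UTC")
  key <- paste(fixes$animal_id, day, sep = "|")
  pieces <- lapply(split(seq_len(nrow(fixes)), key), function(idx) {
    f <- fixes[idx, , drop = FALSE]
    n <- nrow(f)
    agg <- basic_aggregates(f$x, f$y, f$z)
    ai <- actindex(f$x, f$y, f$z)
    dyn <- dynamic_components(f$x, f$y, f$z, window)

    if (n >= 2) {
      sm <- step_metrics(f)
      bearing <- c(0, vapply(2:n, function(i) {
        if (f$easting[i] == f$easting[i - 1] &&
            f$northing[i] == f$northing[i - 1]) 0 else {
          movement_bearing(c(f$easting[i - 1], f$northing[i - 1]),
                           c(f$easting[i], f$northing[i]))
        }
      }, numeric(1)))
      path <- cumsum(sm$distance)
      disp <- sqrt((f$easting - f$easting[1])^2 +
                   (f$northing - f$northing[1])^2)
      straight <- ifelse(path > 0, pmin(disp / path, 1), 1)
    } else {
      sm <- data.frame(distance = 0, speed = 0)
      bearing <- 0
      straight <- 1
    }

    zero <- f$x == 0 & f$y == 0 & f$z == 0
    pit <- rol <- numeric(n)
    if (any(!zero)) {
      pit[!zero] <- pitch_angle(f$x[!zero], f$y[!zero], f$z[!zero])
      rol[!zero] <- roll_angle(f$x[!zero], f$y[!zero], f$z[!zero])
    }

    h <- window - 1
    energy <- vapply(seq_len(n), function(i) sum(ai[max(1, i - h):i]),
                     numeric(1))

    acc <- data.frame(actindex = ai,
                      odba = odba(dyn$dx, dyn$dy, dyn$dz),
                      vedba = vedba(dyn$dx, dyn$dy, dyn$dz))
    comb <- combined_features(sm, acc)

    cbind(data.frame(animal_id = f$animal_id, gmt_time = f$gmt_time,
                     x = f$x, y = f$y, z = f$z),
          agg,
          data.frame(actindex = ai, energy = energy,
                     odba = acc$odba, vedba = acc$vedba,
                     pitch = pit, roll = rol,
                     distance = sm$distance, speed = sm$speed,
                     bearing = bearing, straightness = straight),
          comb)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$animal_id, out$gmt_time), ]
  rownames(out) <- NULL
  out[, c("animal_id", "gmt_time", feature_columns())]
}
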