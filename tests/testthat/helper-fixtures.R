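# Shared fixtures built in code. The heavier simulated datasets are created
# once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Calibrated well-separated campaign (~1,200 instances), the study-scale set.
sep_instances <- function() {
  fixture("sep_instances", function() {
    sim <- simulate_collar_data(scenario_separated(), seed = 11)
    make_instances(sim)
  })
}

# Overlapping-emissions campaign with walking a rare class.
overlap_instances <- function() {
  fixture("overlap_instances", function() {
    sim <- simulate_collar_data(scenario_overlapping(), seed = 12)
    make_instances(sim)
  })
}

# Small toy feature set with a planted class signal.
toy_classification <- function(n = 200, seed = 42) {
  set.seed(seed)
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- factor(ifelse(X$a + 0.4 * rnorm(n) > 0, "AC", "ST"))
  list(X = X, y = y)
}

make_fix_df <- function(n, animal_id = "cow01",
                        t0 = as.POSIXct("2024-08-27 13:00:00", tz = "UTC"),
                        interval = 300, easting = 432100, northing = 4641100,
                        altitude = 1530, satellites = 8, x = 10, y = 10,
                        z = 10) {
  data.frame(
    animal_id = animal_id,
    gmt_time = t0 + interval * (seq_len(n) - 1),
    easting = rep_len(easting, n), northing = rep_len(northing, n),
    altitude_m = rep_len(altitude, n),
    satellites = rep_len(satellites, n),
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n)
  )
}

event_df <- function(animal_id, starts_min, ends_min, behavior,
                     posture = NULL,
                     t0 = as.POSIXct("2024-08-27 13:00:00", tz = "UTC")) {
  data.frame(
    animal_id = animal_id,
    start = t0 + starts_min * 60,
    end = t0 + ends_min * 60,
    behavior = behavior,
    posture = posture %||% rep("NA", length(behavior))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
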