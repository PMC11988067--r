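test_that("a zero-length day yields an empty event sequence", {
  ev <- simulate_behavior_sequence(sim_config(), "c1", 0, seed = 1)
  expect_equal(nrow(ev), 0)
})

test_that("transition structure forces strict alternation when binary", {
  shares <- c(GR = 0.5, RE = 0.5)
  W <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(names(shares),
                                                   names(shares)))
  cfg <- sim_config(target_shares = shares, transition_weights = W,
                    bout_mean_min = c(GR = 8, RE = 8),
                    bout_shape = c(GR = 4, RE = 4),
                    posture_probs = c(RE = 0.5, RU = 0.5),
                    speed_params = data.frame(behavior = c("GR", "RE"),
                                              mean = c(10, 0), sd = c(5, 0)),
                    accel_params = data.frame(
                      behavior = c("GR", "RE"),
                      x_mean = c(40, 5), x_sd = c(12, 3),
                      y_mean = c(35, 4), y_sd = c(12, 3),
                      z_mean = c(30, 4), z_sd = c(12, 3)),
                    turn_sd = c(GR = 1.2, RE = 2))
  ev <- simulate_behavior_sequence(cfg, "c1", 500, seed = 2)
  expect_true(all(ev$behavior[-1] != ev$behavior[-nrow(ev)]))
  expect_setequal(unique(ev$behavior), c("GR", "RE"))
})

test_that("a behavior with no outgoing weight is a configuration error", {
  shares <- c(GR = 0.5, RE = 0.5)
  W <- matrix(0, 2, 2, dimnames = list(names(shares), names(shares)))
  W["RE", "GR"] <- 1   # GR row is all zero
  expect_error(
    sim_config(target_shares = shares, transition_weights = W,
               bout_mean_min = c(GR = 8, RE = 8),
               bout_shape = c(GR = 4, RE = 4),
               posture_probs = c(RE = 0.5),
               speed_params = data.frame(behavior = c("GR", "RE"),
                                         mean = c(10, 0), sd = c(5, 0)),
               accel_params = data.frame(
                 behavior = c("GR", "RE"),
                 x_mean = c(40, 5), x_sd = c(12, 3),
                 y_mean = c(35, 4), y_sd = c(12, 3),
                 z_mean = c(30, 4), z_sd = c(12, 3)),
               turn_sd = c(GR = 1.2, RE = 2)),
    "GR")
})

test_that("event durations respect the 3-min floor and sum to the block", {
  cfg <- sim_config()
  ev <- simulate_behavior_sequence(cfg, "c1", 240, seed = 3)
  durs <- as.numeric(ev$end - ev$start, units = "mins")
  expect_equal(sum(durs), 240, tolerance = 1e-9)
  expect_true(all(durs[-length(durs)] >= 3 - 1e-9))
  expect_true(all(ev$behavior[-1] != ev$behavior[-nrow(ev)]))
  static <- ev$behavior %in% c("RE", "RU")
  expect_true(all(ev$posture[static] %in% c("SU", "LD")))
  expect_true(all(ev$posture[!static] == "NA"))
})

test_that("behavior time shares match a 10x-length brute-force long run", {
  cfg <- sim_config()
  share_of <- function(ev) {
    durs <- as.numeric(ev$end - ev$start, units = "mins")
    tapply(durs, factor(ev$behavior, levels = cfg$behaviors), sum,
           default = 0) / sum(durs)
  }
  test_run <- share_of(simulate_behavior_sequence(cfg, "c1", 10000,
                                                  seed = 4))
  # oracle: ten independent 10,000-min runs; their spread gives the sd
  oracle <- sapply(1:10, function(i) {
    share_of(simulate_behavior_sequence(cfg, "oracle", 10000,
                                        seed = 100 + i))
  })
  mu <- rowMeans(oracle)
  sdv <- apply(oracle, 1, sd)
  expect_true(all(abs(test_run - mu) <= 3 * sdv + 1e-9))
})

test_that("a single 60-min bout at 300-s intervals yields 12 labeled fixes", {
  cfg <- sim_config()
  ev <- event_df("c1", 0, 60, "GR")
  out <- emit_fixes(ev, cfg, seed = 5)
  expect_equal(nrow(out$fixes), 12)
  expect_true(all(out$fixes$behavior == "GR"))
  expect_true(all(diff(as.numeric(out$fixes$gmt_time)) == 300))
})

test_that("every fix is covered by exactly one truth event", {
  cfg <- sim_config()
  ev <- simulate_behavior_sequence(cfg, "c1", 300, seed = 6)
  out <- emit_fixes(ev, cfg, seed = 7)
  st <- as.numeric(ev$start); en <- as.numeric(ev$end)
  for (t in as.numeric(out$fixes$gmt_time)) {
    expect_equal(sum(st < t + 1e-9 & en >= t - 1e-9), 1)
  }
  expect_error(emit_fixes(event_df("c1", c(0, 5), c(10, 15),
                                   c("GR", "W")), cfg, seed = 1),
               "overlap")
})

test_that("identical config and seed reproduce the output byte-for-byte", {
  cfg <- sim_config()
  s1 <- simulate_collar_data(cfg, n_animals = 1, n_days = 1, seed = 8)
  s2 <- simulate_collar_data(cfg, n_animals = 1, n_days = 1, seed = 8)
  expect_identical(serialize(s1$fixes, NULL), serialize(s2$fixes, NULL))
  expect_identical(serialize(s1$truth_events, NULL),
                   serialize(s2$truth_events, NULL))
  s3 <- simulate_collar_data(cfg, n_animals = 1, n_days = 1, seed = 9)
  expect_false(identical(s1$fixes$easting, s3$fixes$easting))
})

test_that("with zero corruption the cleaner removes nothing", {
  cfg <- sim_config(corruption_rates = c(satellites = 0, altitude = 0,
                                         paddock = 0))
  sim <- simulate_collar_data(cfg, n_animals = 1, n_days = 1, seed = 10)
  res <- clean_fixes(sim$fixes, cleaning_rules(paddock = cfg$paddock))
  expect_equal(nrow(res$rejected), 0)
})

test_that("simulated per-behavior speeds concentrate on their parameters", {
  cfg <- sim_config()
  ev <- simulate_behavior_sequence(cfg, "c1", 6000, seed = 11)  # ~1200 fixes
  out <- emit_fixes(ev, cfg, seed = 12)
  f <- out$fixes
  for (b in c("GR", "W")) {
    v <- f$speed_true[f$behavior == b]
    p <- cfg$speed_params[cfg$speed_params$behavior == b, ]
    # truncation at 0 inflates the mean slightly; compare against the
    # truncated-normal mean, within 3 standard errors
    tmean <- p$mean + p$sd * dnorm(-p$mean / p$sd) /
      (1 - pnorm(-p$mean / p$sd))
    expect_lt(abs(mean(v) - tmean), 3 * p$sd / sqrt(length(v)) + 1e-9)
  }
  expect_true(all(f$speed_true[f$behavior %in% c("RE", "RU")] == 0))
})

test_that("activity counts are non-negative integers with behavior contrast", {
  sim <- simulate_collar_data(sim_config(), n_animals = 1, n_days = 1,
                              seed = 13)
  f <- sim$fixes
  expect_true(all(f$x >= 0 & f$y >= 0 & f$z >= 0))
  expect_true(all(f$x == round(f$x)))
  ai <- actindex(f$x, f$y, f$z)
  expect_gt(mean(ai[f$state == "AC"]), mean(ai[f$state == "ST"]))
})

test_that("the calibrated scenario hits the reference class shares at n = 5000", {
  cfg <- sim_config()
  ev <- simulate_behavior_sequence(cfg, "c1", 25000, seed = 14)
  out <- emit_fixes(ev, cfg, seed = 15)
  expect_gte(nrow(out$fixes), 4999)
  emp <- prop.table(table(factor(out$fixes$behavior,
                                 levels = cfg$behaviors)))
  ref <- calibration_class_counts()$behavior
  target <- ref[cfg$behaviors] / sum(ref)
  expect_true(all(abs(emp - target) <= 0.03))
})

test_that("classifier accuracy is non-decreasing in emission separation", {
  accs <- sapply(c(0.1, 0.4, 1), function(s) {
    sim <- simulate_collar_data(scenario_separated(separation = s),
                                n_animals = 2, n_days = 1, seed = 16)
    inst <- make_instances(sim)
    tl <- task_labels(inst, "states")
    X <- inst[tl$rows, feature_columns()]
    rts_evaluate(model_spec("random_forest", list(n_trees = 200), seed = 17),
                 X, tl$labels, partition_spec("RTS", seed = 18))$accuracy
  })
  expect_true(all(diff(accs) >= 0))
})

test_that("fix CSV round-trips the collar schema", {
  sim <- simulate_collar_data(sim_config(), n_animals = 1, n_days = 1,
                              seed = 19)
  path <- tempfile(fileext = ".csv")
  write_fixes_csv(sim$fixes, path)
  back <- read_fixes_csv(path)
  expect_equal(names(back),
               c("animal_id", "gmt_time", "local_time", "lat", "lon",
                 "easting", "northing", "altitude_m", "temp_c", "voltage",
                 "dop", "satellites", "x", "y", "z"))
  expect_equal(nrow(back), nrow(sim$fixes))
  expect_equal(as.numeric(back$gmt_time), as.numeric(sim$fixes$gmt_time))
  expect_equal(back$x, sim$fixes$x)
  unlink(path)
})
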