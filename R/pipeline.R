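#' Run the full labeling pipeline on simulated (or real) collar output
#'
#' Convenience wrapper chaining the analysis stages: clean the raw fixes
#' ([clean_fixes()]), compute the per-fix feature matrix
#' ([build_features()]), merge short ground-truth bouts
#' ([merge_short_bouts()]) and align the labels to the kept fixes
#' ([align_labels_to_fixes()]). The result is the modeling table: one row
#' per labeled instance with all feature columns plus `behavior`,
#' `posture`, `state` and `behavior_by_posture`.
#'
#' @param sim A `sim_output` (or any list with `fixes` and `truth_events`
#'   in the same schema).
#' @param rules Cleaning rules; by default derived from the simulation
#'   config (its paddock, buffer, altitude window and fix interval).
#' @param window Dynamic-component window in fixes (default 3).
#' @return Labeled instance data.frame; the number of fixes dropped for
#'   lack of an overlapping event is in attribute `"n_dropped"`, the
#'   rejection log in attribute `"rejected"`.
#' @export
make_instances <- function(sim, rules = NULL, window = 3L) {
  cfg <- sim$config_echo
  if (is.null(rules)) {
    rules <- cleaning_rules(
      altitude_window = cfg$altitude_window %||% c(1500, 1570),
      min_interval = cfg$fix_interval %||% 300,
      paddock = cfg$paddock,
      buffer_m = cfg$buffer_m %||% 10)
  }
  cl <- clean_fixes(sim$fixes, rules)
  feats <- build_features(cl$kept, window = window)
  ev <- merge_short_bouts(sim$truth_events)
  inst <- align_labels_to_fixes(ev, cl$kept,
                                window_s = cfg$fix_interval %||% 300)
  key_f <- paste(feats$animal_id, as.numeric(feats$gmt_time))
  key_i <- paste(inst$animal_id, as.numeric(inst$gmt_time))
  out <- cbind(inst[, c("animal_id", "gmt_time", "behavior", "posture",
                        "state", "behavior_by_posture")],
               feats[match(key_i, key_f), feature_columns()])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- attr(inst, "n_dropped")
  attr(out, "rejected") <- cl$rejected
  out
}
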