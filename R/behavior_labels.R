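BEHAVIORS <- c("GR", "W", "DW", "RE", "RU")
ACTIVE_BEHAVIORS <- c("GR", "W", "DW")
STATIC_BEHAVIORS <- c("RE", "RU")

#' Reference class distribution used for simulator calibration
#'
#' The per-class instance counts (out of 1280 labeled 5-min instances from
#' three collared cows over three 12-h observation days) that the default
#' calibrated simulation scenario reproduces: grazing 535, resting 258
#' (99 lying, 159 standing), ruminating 390 (209 lying, 181 standing),
#' walking 83, drinking 14; 632 active vs 648 static; 925 standing vs 355
#' lying overall.
#'
#' @return A named list of integer counts: `behavior`, `state`, `posture`,
#'   `behavior_by_posture`, and `total`.
#' @export
calibration_class_counts <- function() {
  list(
    behavior = c(GR = 535L, RE = 258L, RU = 390L, W = 83L, DW = 14L),
    state = c(AC = 632L, ST = 648L),
    posture = c(SU = 925L, LD = 355L),
    behavior_by_posture = c(RE_LD = 99L, RE_SU = 159L,
                            RU_LD = 209L, RU_SU = 181L),
    total = 1280L
  )
}

#' Merge sub-threshold behavior bouts into their predecessors
#'
#' A behavior change is only recognized when the new behavior persists for
#' at least `min_minutes` (default 3): shorter interruptions are absorbed
#' into the preceding bout (its end time is extended), and adjacent bouts
#' of the same behavior are coalesced. The first bout of a contiguous
#' observation block has no predecessor and is kept even if short. Total
#' covered time is conserved and the operation is idempotent.
#'
#' @param events data.frame with columns `animal_id`, `start`, `end`
#'   (POSIXct or numeric seconds), `behavior`, and optionally `posture`;
#'   time-sorted and non-overlapping within each animal.
#' @param min_minutes Minimum bout duration in minutes (default 3).
#' @return data.frame of merged events with the same columns.
#' @export
merge_short_bouts <- function(events, min_minutes = 3) {
  if (nrow(events) == 0) return(events)
  if (is.null(events$posture)) events$posture <- "NA"
  out <- list()
  for (id in unique(events$animal_id)) {
    ev <- events[events$animal_id == id, , drop = FALSE]
    ev <- ev[order(as.numeric(ev$start)), , drop = FALSE]
    if (any(as.numeric(ev$end[-nrow(ev)]) > as.numeric(ev$start[-1]) + 1e-9)) {
      stopf("overlapping events for animal %s", id)
    }
    stack <- ev[1, , drop = FALSE]
    for (i in seq_len(nrow(ev))[-1]) {
      e <- ev[i, , drop = FALSE]
      top <- nrow(stack)
      adjacent <- abs(as.numeric(stack$end[top]) -
                      as.numeric(e$start)) < 1e-9
      dur_min <- (as.numeric(e$end) - as.numeric(e$start)) / 60
      if (adjacent && dur_min < min_minutes) {
        stack$end[top] <- e$end
      } else if (adjacent && e$behavior == stack$behavior[top] &&
                 e$posture == stack$posture[top]) {
        stack$end[top] <- e$end
      } else {
        stack <- rbind(stack, e)
      }
    }
    out[[length(out) + 1]] <- stack
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map behaviors to the binary activity state
#'
#' Walking, grazing and drinking water are active (AC); resting and
#' ruminating are static (ST). Grooming and nursing count as static when
#' performed for at least `min_minutes`, otherwise they fall into an
#' `OTHER` category that is excluded from modeling by default.
#'
#' @param behavior Character vector of behavior codes.
#' @param duration_min Bout durations in minutes (recycled; only used for
#'   GROOM/NURSE). Default `Inf`.
#' @param min_minutes Threshold for prolonged grooming/nursing (default 3).
#' @return Character vector over \{"AC", "ST", "OTHER"\}.
#' @export
to_state <- function(behavior, duration_min = Inf, min_minutes = 3) {
  duration_min <- rep_len(duration_min, length(behavior))
  unknown <- !behavior %in% c(BEHAVIORS, "GROOM", "NURSE")
  if (any(unknown)) {
    stopf("unknown behavior code(s): %s",
          paste(unique(behavior[unknown]), collapse = ", "))
  }
  out <- ifelse(behavior %in% ACTIVE_BEHAVIORS, "AC",
         ifelse(behavior %in% STATIC_BEHAVIORS, "ST",
         ifelse(duration_min >= min_minutes, "ST", "OTHER")))
  out
}

# Index of the event whose behavior occupies the largest share of the
# window (t0, t1]; ties to the earlier-starting behavior. Returns NA when
# no event overlaps. st/en are numeric start/end vectors for one animal's
# events (time-sorted), beh the behavior codes.
majority_event_index <- function(st, en, beh, t0, t1) {
  cand <- which(st < t1 + 1e-9 & en > t0 - 1e-9)
  if (length(cand) == 0) return(NA_integer_)
  share <- pmin(en[cand], t1) - pmax(st[cand], t0)
  by_beh <- tapply(share, beh[cand], sum)
  best <- names(by_beh)[by_beh == max(by_beh)]
  if (length(best) > 1) {
    starts <- vapply(best, function(b) min(st[cand][beh[cand] == b]),
                     numeric(1))
    best <- best[which.min(starts)]
  }
  cand[beh[cand] == best][1]
}

#' Join ground-truth behavior bouts to fixes
#'
#' Each fix is labeled with the behavior occupying the largest share of the
#' fix interval ending at the fix timestamp (default 5 min); ties go to the
#' earlier-starting behavior, consistent with the convention that brief
#' interruptions belong to the previous behavior. Fixes whose window
#' overlaps no event are dropped; their count is attached as the
#' `"n_dropped"` attribute. With `method = "instant"` the label is simply
#' the event covering the fix timestamp.
#'
#' @param events Merged behavior events (see [merge_short_bouts()]).
#' @param fixes Cleaned fixes data.frame (columns `animal_id`, `gmt_time`).
#' @param window_s Fix interval in seconds (default 300).
#' @param method `"window"` (majority share, default) or `"instant"`.
#' @return `fixes` with added columns `behavior`, `posture`, `state`,
#'   `behavior_by_posture`.
#' @export
align_labels_to_fixes <- function(events, fixes, window_s = 300,
                                  method = c("window", "instant")) {
  method <- match.arg(method)
  n <- nrow(fixes)
  behavior <- posture <- rep(NA_character_, n)
  dur_min <- rep(NA_real_, n)
  ev_start <- as.numeric(events$start); ev_end <- as.numeric(events$end)
  ev_post <- events$posture %||% rep("NA", nrow(events))
  for (i in seq_len(n)) {
    t1 <- as.numeric(fixes$gmt_time[i])
    same <- events$animal_id == fixes$animal_id[i]
    if (method == "instant") {
      cand <- which(same & ev_start < t1 + 1e-9 & ev_end > t1 - 1e-9)
      if (length(cand) == 0) next
      hit <- cand[ev_start[cand] <= t1 & ev_end[cand] > t1]
      if (length(hit) == 0) hit <- cand[length(cand)]
      j <- hit[1]
    } else {
      jj <- majority_event_index(ev_start[same], ev_end[same],
                                 events$behavior[same], t1 - window_s, t1)
      if (is.na(jj)) next
      j <- which(same)[jj]
    }
    behavior[i] <- events$behavior[j]
    posture[i] <- ev_post[j]
    dur_min[i] <- (ev_end[j] - ev_start[j]) / 60
  }
  keep <- !is.na(behavior)
  out <- fixes[keep, , drop = FALSE]
  out$behavior <- behavior[keep]
  out$posture <- posture[keep]
  out$state <- to_state(out$behavior, dur_min[keep])
  out$behavior_by_posture <- ifelse(
    out$behavior %in% STATIC_BEHAVIORS,
    paste(out$behavior, out$posture, sep = "_"),
    out$behavior
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Class counts at every label granularity
#'
#' @param instances Labeled instances (see [align_labels_to_fixes()]).
#' @return Named list of count tables: `state`, `behavior`, `posture`,
#'   `behavior_by_posture`, plus `total`.
#' @export
class_counts <- function(instances) {
  cnt <- function(x) {
    if (length(x) == 0) integer(0) else table(x)
  }
  posture <- ifelse(instances$behavior %in% STATIC_BEHAVIORS,
                    instances$posture, "SU")
  list(
    state = cnt(instances$state),
    behavior = cnt(instances$behavior),
    posture = cnt(posture),
    behavior_by_posture = cnt(instances$behavior_by_posture),
    total = nrow(instances)
  )
}

#' Extract task-specific class labels from labeled instances
#'
#' The five classification tasks and their class sets:
#' * `states`: AC vs ST (all instances).
#' * `general`: GR / RE / W, with ruminating folded into resting and
#'   drinking dropped.
#' * `fine`: GR / RE / RU, with walking and drinking dropped.
#' * `posture`: SU vs LD; active behaviors count as standing.
#' * `behavior_by_posture`: GR / RE_LD / RE_SU / RU_LD / RU_SU, with
#'   walking and drinking dropped.
#'
#' @param instances Labeled instances data.frame.
#' @param task One of `"states"`, `"general"`, `"fine"`, `"posture"`,
#'   `"behavior_by_posture"`.
#' @return A list with `rows` (integer row indices into `instances`) and
#'   `labels` (factor of task classes for those rows).
#' @export
task_labels <- function(instances,
                        task = c("states", "general", "fine", "posture",
                                 "behavior_by_posture")) {
  task <- match.arg(task)
  b <- instances$behavior
  if (task == "states") {
    rows <- which(instances$state %in% c("AC", "ST"))
    lab <- factor(instances$state[rows], levels = c("AC", "ST"))
  } else if (task == "general") {
    rows <- which(b %in% c("GR", "RE", "RU", "W"))
    lab <- factor(ifelse(b[rows] == "RU", "RE", b[rows]),
                  levels = c("GR", "RE", "W"))
  } else if (task == "fine") {
    rows <- which(b %in% c("GR", "RE", "RU"))
    lab <- factor(b[rows], levels = c("GR", "RE", "RU"))
  } else if (task == "posture") {
    rows <- seq_len(nrow(instances))
    p <- ifelse(b %in% STATIC_BEHAVIORS, instances$posture, "SU")
    lab <- factor(p, levels = c("SU", "LD"))
  } else {
    rows <- which(b %in% c("GR", "RE", "RU"))
    lab <- factor(instances$behavior_by_posture[rows],
                  levels = c("GR", "RE_LD", "RE_SU", "RU_LD", "RU_SU"))
  }
  list(rows = rows, labels = droplevels(lab))
}
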