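#' Interpolate low-confidence tracking frames
#'
#' Frames where the tracker's confidence falls below `floor` are replaced,
#' per body part and coordinate, by linear interpolation between the
#' nearest flanking confident frames; leading/trailing low-confidence
#' frames take the nearest confident value. Replaced frames get likelihood
#' equal to `floor` and are flagged in a `<part>_imputed` column.
#'
#' @param pose a `"pose_track"`.
#' @param floor confidence threshold (default 0.90); frames strictly below
#'   it are interpolated.
#' @return A `"pose_track"` with imputed coordinates.
#' @export
interpolate_low_confidence <- function(pose, floor = 0.90) {
  fr <- pose$frames
  idx <- seq_len(nrow(fr))
  for (part in pose_parts) {
    lik <- fr[[paste0(part, "_likelihood")]]
    low <- lik < floor
    if (!any(low)) {
      fr[[paste0(part, "_imputed")]] <- FALSE
      next
    }
    if (all(low))
      stop("body part '", part, "' has no frames at or above the ",
           "confidence floor; cannot interpolate")
    for (coord in c("_x", "_y")) {
      col <- paste0(part, coord)
      fr[[col]][low] <- stats::approx(idx[!low], fr[[col]][!low],
                                      xout = idx[low], rule = 2)$y
    }
    fr[[paste0(part, "_likelihood")]][low] <- floor
    fr[[paste0(part, "_imputed")]] <- low
  }
  pose$frames <- fr
  pose
}

#' Detect approaches and classify trials
#'
#' Scans the snout trajectory during each CS+ trial's sipper-access window
#' for the first frame within `radius_px` (Euclidean, pixels) of either
#' sipper port. That frame defines the first port visited and the approach
#' latency (seconds from sipper entry). A trial is *correct* when the
#' first port visited is the alcohol side, *incorrect* when the other port
#' is visited first (the eventual arrival at the correct port, if any, is
#' still recorded), and an *omission* when neither port is reached.
#' Occupancy vectors mark, at frame resolution over the \[-5, 20\] s
#' behavioral window around cue onset, the frames spent within the radius
#' of the correct and incorrect ports. CS- trials (which have no sipper
#' events) are scored for an approach to either port during the window
#' where access would have occurred, for the CS discrimination ratio.
#'
#' @param pose a `"pose_track"`, normally after
#'   [interpolate_low_confidence()].
#' @param schedule a `"task_schedule"` on the same session clock.
#' @param radius_px approach radius in pixels (default 9).
#' @param behavior_window_s window (s) around cue onset over which
#'   occupancy is tallied.
#' @return An object of class `"trial_events"`: a list with `trials` (one
#'   row per trial: `index`, `cs_type`, `alcohol_side`, `outcome`,
#'   `first_port`, `approach_time_correct`, `approach_time_incorrect`,
#'   `latency_correct_s`, `latency_incorrect_s`, `cs_minus_approach`),
#'   `occupancy_correct` / `occupancy_incorrect` (trials x frames binary
#'   matrices for CS+ trials), and `occupancy_time_s`.
#' @export
detect_and_classify <- function(pose, schedule, radius_px = 9,
                                behavior_window_s = c(-5, 20)) {
  if (radius_px <= 0) stop("radius_px must be positive")
  fr <- pose$frames
  fps <- pose$fps
  if (max(schedule$trials$cue_on) + 13 > max(fr$time_s) + 1 / fps)
    stop("pose track does not cover all trial windows ",
         "(schedule/pose clock mismatch)")
  sx <- fr$snout_x; sy <- fr$snout_y
  pl <- sipper_xy(pose, "left"); pr <- sipper_xy(pose, "right")
  dl <- sqrt((sx - pl[1])^2 + (sy - pl[2])^2)
  dr <- sqrt((sx - pr[1])^2 + (sy - pr[2])^2)
  tt <- fr$time_s
  tr <- schedule$trials
  n <- nrow(tr)
  out <- data.frame(index = tr$index, cs_type = tr$cs_type,
                    alcohol_side = tr$alcohol_side,
                    outcome = NA_character_, first_port = "none",
                    approach_time_correct = NA_real_,
                    approach_time_incorrect = NA_real_,
                    latency_correct_s = NA_real_,
                    latency_incorrect_s = NA_real_,
                    cs_minus_approach = FALSE,
                    stringsAsFactors = FALSE)
  occ_t <- seq(behavior_window_s[1], behavior_window_s[2], by = 1 / fps)
  n_occ <- length(occ_t)
  plus_idx <- which(tr$cs_type == "CS+")
  occ_c <- matrix(0L, length(plus_idx), n_occ)
  occ_i <- matrix(0L, length(plus_idx), n_occ)
  first_within <- function(d, lo, hi) {
    w <- which(tt >= lo & tt <= hi & d <= radius_px)
    if (length(w) == 0) NA_real_ else tt[w[1]]
  }
  for (k in seq_along(plus_idx)) {
    i <- plus_idx[k]
    row <- tr[i, ]
    d_cor <- if (row$alcohol_side == "left") dl else dr
    d_inc <- if (row$alcohol_side == "left") dr else dl
    t_cor <- first_within(d_cor, row$sipper_in, row$sipper_out)
    t_inc <- first_within(d_inc, row$sipper_in, row$sipper_out)
    out$approach_time_correct[i] <- t_cor
    out$approach_time_incorrect[i] <- t_inc
    out$latency_correct_s[i] <- t_cor - row$sipper_in
    out$latency_incorrect_s[i] <- t_inc - row$sipper_in
    if (is.na(t_cor) && is.na(t_inc)) {
      out$outcome[i] <- "omission"
    } else if (is.na(t_inc) || (!is.na(t_cor) && t_cor <= t_inc)) {
      out$outcome[i] <- "correct"
      out$first_port[i] <- row$alcohol_side
    } else {
      out$outcome[i] <- "incorrect"
      out$first_port[i] <- if (row$alcohol_side == "left") "right"
        else "left"
    }
    frame0 <- round((row$cue_on + behavior_window_s[1]) * fps)
    sel <- frame0 + seq_len(n_occ)
    ok <- sel >= 1 & sel <= length(tt)
    win <- tt[sel[ok]] >= row$sipper_in & tt[sel[ok]] <= row$sipper_out
    occ_c[k, ok] <- as.integer(d_cor[sel[ok]] <= radius_px & win)
    occ_i[k, ok] <- as.integer(d_inc[sel[ok]] <= radius_px & win)
  }
  minus_idx <- which(tr$cs_type == "CS-")
  for (i in minus_idx) {
    row <- tr[i, ]
    lo <- row$cue_on + 5; hi <- row$cue_on + 13
    hits <- c(first_within(dl, lo, hi), first_within(dr, lo, hi))
    out$cs_minus_approach[i] <- any(!is.na(hits))
  }
  structure(list(trials = out, occupancy_correct = occ_c,
                 occupancy_incorrect = occ_i, occupancy_time_s = occ_t,
                 plus_trials = tr$index[plus_idx],
                 radius_px = radius_px),
            class = "trial_events")
}

# Centered k-point moving average with shrinking windows at the edges.
moving_average <- function(x, k = 3) {
  h <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, 0)
}

#' Session-level behavioral metrics
#'
#' Aggregates [detect_and_classify()] output: outcome counts, the CS
#' discrimination ratio (CS+ approaches, correct or incorrect, over all
#' approaches; 0.5 is chance), mean approach latencies, three-trial
#' moving-average approach probabilities, and mean occupancy traces.
#'
#' @param events a `"trial_events"`.
#' @param schedule the matching `"task_schedule"`.
#' @return An object of class `"session_metrics"` (list): counts,
#'   `cs_ratio` (NA with `cs_ratio_defined = FALSE` when no trial of
#'   either CS type was approached), latencies, `approach_prob_correct` /
#'   `approach_prob_incorrect` (smoothed per-CS+-trial probabilities), and
#'   `occupancy_prob_correct` / `occupancy_prob_incorrect` traces.
#' @export
session_metrics <- function(events, schedule) {
  tr <- events$trials
  plus <- tr[tr$cs_type == "CS+", ]
  n_correct <- sum(plus$outcome == "correct")
  n_incorrect <- sum(plus$outcome == "incorrect")
  n_omission <- sum(plus$outcome == "omission")
  cs_plus_app <- n_correct + n_incorrect
  cs_minus_app <- sum(tr$cs_minus_approach[tr$cs_type == "CS-"])
  defined <- (cs_plus_app + cs_minus_app) > 0
  cs_ratio <- if (defined) cs_plus_app / (cs_plus_app + cs_minus_app)
    else NA_real_
  structure(list(
    n_correct = n_correct, n_incorrect = n_incorrect,
    n_omission = n_omission,
    cs_ratio = cs_ratio, cs_ratio_defined = defined,
    mean_latency_correct_s =
      mean(plus$latency_correct_s[plus$outcome == "correct"], na.rm = TRUE),
    mean_latency_incorrect_s =
      mean(plus$latency_incorrect_s[plus$outcome == "incorrect"],
           na.rm = TRUE),
    approach_prob_correct =
      moving_average(as.numeric(plus$outcome == "correct")),
    approach_prob_incorrect =
      moving_average(as.numeric(plus$outcome == "incorrect")),
    occupancy_prob_correct = colMeans(events$occupancy_correct),
    occupancy_prob_incorrect = colMeans(events$occupancy_incorrect),
    occupancy_time_s = events$occupancy_time_s),
    class = "session_metrics")
}

#' Per-epoch approach speeds and five-trial block means
#'
#' For each CS+ trial, speed is the absolute change in snout-to-sipper
#' distance over an epoch divided by the epoch duration (px/s), computed
#' toward both the correct and the incorrect sipper. Signed variants
#' (positive when the distance to that sipper shrinks, i.e. the animal
#' closes in on it) are reported alongside. Epochs are PreCue (4 s before
#' cue onset), CueOn (cue onset to sipper entry) and SipIn (sipper
#' access). Block means average trials 1-5, 6-10 and 11-15 of the
#' session's CS+ trials.
#'
#' @param pose a `"pose_track"`.
#' @param schedule a `"task_schedule"`.
#' @param events a `"trial_events"` (used to order CS+ trials).
#' @return A list with `per_trial` (data frame: trial index, epoch,
#'   `speed_to_correct`, `speed_to_incorrect`, `signed_speed_to_correct`,
#'   `signed_speed_to_incorrect`) and `blocks` (data frame of per-block
#'   mean speeds for the first 15 CS+ trials).
#' @export
epoch_speeds <- function(pose, schedule, events) {
  fr <- pose$frames
  tt <- fr$time_s
  fps <- pose$fps
  pl <- sipper_xy(pose, "left"); pr <- sipper_xy(pose, "right")
  dl <- sqrt((fr$snout_x - pl[1])^2 + (fr$snout_y - pl[2])^2)
  dr <- sqrt((fr$snout_x - pr[1])^2 + (fr$snout_y - pr[2])^2)
  tr <- schedule$trials
  plus <- tr[tr$cs_type == "CS+", ]
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    row <- plus[i, ]
    epochs <- list(PreCue = c(row$cue_on - 4, row$cue_on),
                   CueOn = c(row$cue_on, row$sipper_in),
                   SipIn = c(row$sipper_in, row$sipper_out))
    d_cor <- if (row$alcohol_side == "left") dl else dr
    d_inc <- if (row$alcohol_side == "left") dr else dl
    for (ep in names(epochs)) {
      sel <- which(tt >= epochs[[ep]][1] & tt < epochs[[ep]][2])
      if (length(sel) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          index = row$index, epoch = ep, speed_to_correct = NA_real_,
          speed_to_incorrect = NA_real_,
          signed_speed_to_correct = NA_real_,
          signed_speed_to_incorrect = NA_real_, flagged = TRUE)
        next
      }
      len <- (length(sel) - 1) / fps
      dc <- d_cor[sel[1]] - d_cor[sel[length(sel)]]
      di <- d_inc[sel[1]] - d_inc[sel[length(sel)]]
      rows[[length(rows) + 1]] <- data.frame(
        index = row$index, epoch = ep,
        speed_to_correct = abs(dc) / len,
        speed_to_incorrect = abs(di) / len,
        signed_speed_to_correct = dc / len,
        signed_speed_to_incorrect = di / len,
        flagged = FALSE)
    }
  }
  per_trial <- do.call(rbind, rows)
  blocks <- NULL
  ord <- order(plus$index)
  first15 <- plus$index[ord][seq_len(min(15, nrow(plus)))]
  blk <- split(first15, ceiling(seq_along(first15) / 5))
  for (b in seq_along(blk)) {
    sub <- per_trial[per_trial$index %in% blk[[b]], ]
    agg <- stats::aggregate(
      cbind(speed_to_correct, speed_to_incorrect) ~ epoch, data = sub,
      FUN = mean, na.rm = TRUE)
    agg$block <- b
    blocks <- rbind(blocks, agg)
  }
  list(per_trial = per_trial, blocks = blocks)
}
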