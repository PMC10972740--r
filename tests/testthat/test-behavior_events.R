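make_interp_pose <- function(x, lik) {
  n <- length(x)
  lm <- data.frame(name = c("corner_tl", "corner_tr", "corner_bl",
                            "corner_br", "sipper_left", "sipper_right"),
                   x = c(20, 620, 20, 620, 30, 610),
                   y = c(20, 20, 460, 460, 240, 240))
  frames <- data.frame(time_s = (seq_len(n) - 1) / 30)
  for (part in c("snout", "head_cap", "back", "tail")) {
    frames[[paste0(part, "_x")]] <- x
    frames[[paste0(part, "_y")]] <- 100
    frames[[paste0(part, "_likelihood")]] <- lik
  }
  pose_track(fps = 30, frames = frames, landmarks = lm)
}

test_that("low-confidence frames are linearly interpolated", {
  pose <- make_interp_pose(c(0, 999, 10), c(1, 0.5, 1))
  out <- interpolate_low_confidence(pose, floor = 0.9)
  expect_equal(out$frames$snout_x, c(0, 5, 10))
  expect_equal(out$frames$snout_likelihood[2], 0.9)
  expect_identical(out$frames$snout_imputed, c(FALSE, TRUE, FALSE))

  # all confident: identity
  pose2 <- make_interp_pose(c(1, 2, 3), c(0.95, 0.9, 1))
  out2 <- interpolate_low_confidence(pose2, floor = 0.9)
  expect_equal(out2$frames$snout_x, c(1, 2, 3))

  # low-confidence leading edge takes the nearest confident value
  pose3 <- make_interp_pose(c(0, 7, 8), c(0.1, 1, 1))
  out3 <- interpolate_low_confidence(pose3, floor = 0.9)
  expect_equal(out3$frames$snout_x[1], 7)

  # a body part with no confident frames is an error naming the part
  pose4 <- make_interp_pose(c(0, 1), c(0.1, 0.2))
  expect_error(interpolate_low_confidence(pose4, 0.9), "snout")
})

test_that("approaches are detected and trials classified per definitions", {
  sched <- mini_schedule(1)          # CS+ left, sipper_in = 10
  home <- 320
  # enters the left-port radius at t = 11.5 and stays
  wp <- data.frame(t = c(0, 10.0, 11.5, 18), x = c(home, home, 39, 39))
  pose <- mini_pose(wp, duration = 20)
  ev <- detect_and_classify(pose, sched, radius_px = 9)
  tr <- ev$trials[1, ]
  expect_equal(tr$outcome, "correct")
  expect_equal(tr$first_port, "left")
  expect_equal(tr$latency_correct_s, 1.5, tolerance = 1 / 30)

  # wrong port at +1.0 s, correct port at +3.0 s: incorrect, both
  # latencies recorded
  wp2 <- data.frame(t = c(0, 10.0, 11.0, 11.6, 13.0, 18),
                    x = c(home, home, 601, 601, 39, 39))
  pose2 <- mini_pose(wp2, duration = 20)
  ev2 <- detect_and_classify(pose2, sched, radius_px = 9)
  tr2 <- ev2$trials[1, ]
  expect_equal(tr2$outcome, "incorrect")
  expect_equal(tr2$first_port, "right")
  expect_equal(tr2$latency_incorrect_s, 1.0, tolerance = 1 / 30)
  expect_equal(tr2$latency_correct_s, 3.0, tolerance = 2 / 30)

  # never within radius: omission
  wp3 <- data.frame(t = c(0, 20), x = c(home, home))
  ev3 <- detect_and_classify(mini_pose(wp3, 20), sched, radius_px = 9)
  expect_equal(ev3$trials$outcome[1], "omission")

  # clock mismatch: pose ends before the trial does
  expect_error(detect_and_classify(mini_pose(wp3, 10), sched, 9),
               "clock mismatch")
})

test_that("session metrics follow the printed definitions", {
  # moving average with shrinking edges
  expect_equal(twocap:::moving_average(c(1, 1, 0, 0)),
               c(1, 2 / 3, 1 / 3, 0))

  s <- fixture_session()
  pose <- interpolate_low_confidence(s$pose)
  ev <- detect_and_classify(pose, s$schedule)
  m <- session_metrics(ev, s$schedule)
  expect_equal(m$n_correct + m$n_incorrect + m$n_omission, 48)
  expect_true(m$cs_ratio >= 0 && m$cs_ratio <= 1)
  expect_length(m$approach_prob_correct, 48)

  # cs ratio arithmetic on constructed events
  ev2 <- ev
  ev2$trials$outcome[ev2$trials$cs_type == "CS+"] <-
    rep(c("correct", "omission"), length.out = 48)  # 24 CS+ approaches
  ev2$trials$cs_minus_approach[ev2$trials$cs_type == "CS-"] <-
    rep(c(TRUE, FALSE), length.out = 48)            # 24 CS- approaches
  m2 <- session_metrics(ev2, s$schedule)
  expect_equal(m2$cs_ratio, 0.5)
  ev3 <- ev2
  ev3$trials$outcome[ev3$trials$cs_type == "CS+"] <-
    rep(c("correct", rep("omission", 7)), length.out = 48)  # 6 vs 18
  ev3$trials$cs_minus_approach[ev3$trials$cs_type == "CS-"] <-
    rep(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), length.out = 48)
  m3 <- session_metrics(ev3, s$schedule)
  expect_equal(m3$cs_ratio, 0.25)

  # no approaches at all: ratio undefined and flagged
  ev4 <- ev
  ev4$trials$outcome[ev4$trials$cs_type == "CS+"] <- "omission"
  ev4$trials$cs_minus_approach <- FALSE
  m4 <- session_metrics(ev4, s$schedule)
  expect_true(is.na(m4$cs_ratio))
  expect_false(m4$cs_ratio_defined)
})

test_that("epoch speeds are displacement over time toward the sipper", {
  sched <- mini_schedule(1)  # cue_on 5, sipper_in 10, CS+ left
  # constant 18 px/s toward the left sipper through the CueOn epoch
  wp <- data.frame(t = c(0, 5, 10, 20), x = c(320, 320, 230, 230))
  pose <- mini_pose(wp, duration = 20)
  ev <- detect_and_classify(pose, sched)
  sp <- epoch_speeds(pose, sched, ev)
  cue_row <- sp$per_trial[sp$per_trial$epoch == "CueOn", ]
  expect_equal(cue_row$speed_to_correct, 18, tolerance = 1e-6)

  # stationary animal: zero speed in all epochs
  wp2 <- data.frame(t = c(0, 20), x = c(320, 320))
  pose2 <- mini_pose(wp2, duration = 20)
  sp2 <- epoch_speeds(pose2, sched, detect_and_classify(pose2, sched))
  expect_true(all(abs(sp2$per_trial$speed_to_correct) < 1e-9))
  expect_true(all(abs(sp2$per_trial$speed_to_incorrect) < 1e-9))
})

test_that("congruent proactive sessions approach faster during the cue", {
  # proactive agents move toward the correct sipper during the cue on
  # congruent sessions but toward the cued (wrong) sipper on
  # incongruent ones, so the signed cue-epoch speed toward the correct
  # sipper separates the session types
  mean_cue_speed <- function(session_type, seed) {
    sched <- generate_schedule(session_type = session_type, seed = seed)
    agent <- noise_free_agent(control_mode = "proactive",
                              p_follow_cue = 1, p_omit = 0)
    pose <- generate_pose(sched, agent, seed = seed)$pose
    ev <- detect_and_classify(pose, sched)
    sp <- epoch_speeds(pose, sched, ev)
    cue <- sp$per_trial[sp$per_trial$epoch == "CueOn", ]
    mean(cue$signed_speed_to_correct, na.rm = TRUE)
  }
  seeds <- 1:10
  con <- vapply(seeds, function(s) mean_cue_speed("congruent", s), 0)
  inc <- vapply(seeds, function(s) mean_cue_speed("incongruent", s), 0)
  expect_gt(mean(con), mean(inc))
  expect_true(mean(con > inc) >= 0.9)
})

test_that("events recover ground truth exactly on noise-free sessions", {
  sched <- generate_schedule(seed = 21)
  agent <- noise_free_agent()
  res <- generate_pose(sched, agent, seed = 21)
  ev <- detect_and_classify(res$pose, sched)
  plus <- res$truth$cs_type == "CS+"
  expect_identical(ev$trials$outcome[plus], res$truth$outcome[plus])
  expect_identical(ev$trials$first_port[plus], res$truth$first_port[plus])
  app <- plus & !is.na(res$truth$approach_time)
  det <- ifelse(ev$trials$outcome[app] == "correct",
                ev$trials$approach_time_correct[app],
                ev$trials$approach_time_incorrect[app])
  expect_true(all(abs(det - res$truth$approach_time[app]) <= 2 / 30))
})

test_that("outcomes partition CS+ trials and detection is radius-monotone", {
  s <- fixture_session()
  pose <- interpolate_low_confidence(s$pose)
  for (r in c(5, 9, 20)) {
    ev <- detect_and_classify(pose, s$schedule, radius_px = r)
    plus <- ev$trials[ev$trials$cs_type == "CS+", ]
    expect_equal(sum(plus$outcome %in%
                       c("correct", "incorrect", "omission")), 48)
  }
  small <- detect_and_classify(pose, s$schedule, radius_px = 6)
  large <- detect_and_classify(pose, s$schedule, radius_px = 15)
  approached_small <- small$trials$outcome != "omission" &
    small$trials$cs_type == "CS+"
  approached_large <- large$trials$outcome != "omission" &
    large$trials$cs_type == "CS+"
  expect_true(all(approached_large[approached_small]))
})
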