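#' Behavioral agent parameters for the session generator
#'
#' Describes how the simulated animal behaves. `control_mode` selects the
#' decision rule: a `"proactive"` agent applies the learned cue rule (go to
#' the CS+ side), so on incongruent sessions it approaches the cued -- now
#' incorrect -- side with probability `p_follow_cue`; a `"reactive"` agent
#' decides at sipper time and approaches the alcohol side with probability
#' `p_correct_congruent` regardless of session type. On congruent sessions
#' both rules coincide and `p_correct_congruent` is the probability of a
#' correct first approach.
#'
#' @param control_mode `"proactive"` or `"reactive"`.
#' @param p_correct_congruent probability of a correct first approach when
#'   the decision rule points at the alcohol side.
#' @param p_follow_cue probability a proactive agent approaches the CS+
#'   side regardless of the alcohol side (drives incongruent errors).
#' @param p_omit probability of approaching neither port on a CS+ trial.
#' @param p_approach_cs_minus probability of checking a port on a CS-
#'   trial (sets the CS discrimination ratio below 1).
#' @param latency_mean_s,latency_sd_s departure latency from cue onset,
#'   Gaussian, truncated at 0.5 s.
#' @param speed_px_s locomotion speed in px/s.
#' @param position_noise_px Gaussian jitter added to every tracked point.
#' @param check_duration_s dwell at the wrong port before correcting, on
#'   incorrect trials.
#' @param low_conf_frac fraction of frames given a likelihood below the
#'   confidence floor (with corrupted coordinates), to exercise
#'   interpolation.
#' @return A list of class `"agent_params"`.
#' @export
agent_params <- function(control_mode = c("proactive", "reactive"),
                         p_correct_congruent = 0.85,
                         p_follow_cue = 0.85,
                         p_omit = 0.10,
                         p_approach_cs_minus = 0.15,
                         latency_mean_s = 4.5,
                         latency_sd_s = 1.0,
                         speed_px_s = 150,
                         position_noise_px = 1.5,
                         check_duration_s = 1.0,
                         low_conf_frac = 0.02) {
  control_mode <- match.arg(control_mode)
  probs <- c(p_correct_congruent, p_follow_cue, p_omit, p_approach_cs_minus)
  if (any(probs < 0 | probs > 1))
    stop("agent probabilities must lie in [0, 1]")
  if (p_correct_congruent + p_omit > 1 + 1e-12)
    stop("p_correct_congruent + p_omit must not exceed 1")
  if (position_noise_px < 0) stop("position_noise_px must be >= 0")
  structure(list(control_mode = control_mode,
                 p_correct_congruent = p_correct_congruent,
                 p_follow_cue = p_follow_cue, p_omit = p_omit,
                 p_approach_cs_minus = p_approach_cs_minus,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s, speed_px_s = speed_px_s,
                 position_noise_px = position_noise_px,
                 check_duration_s = check_duration_s,
                 low_conf_frac = low_conf_frac),
            class = "agent_params")
}

#' Neural population parameters for the session generator
#'
#' Describes the simulated population: gamma-distributed baseline rates
#' and fractions of cue-modulated, sipper-modulated and side-selective
#' units. Side units fire above baseline on trials toward their preferred
#' side; `side_code_onset` places that surplus before the approach
#' (`"pre_approach"`, the proactive regime: side identity is encoded while
#' the goal is being maintained) or after it (`"post_approach"`, the
#' reactive regime: side identity appears only once the approach is under
#' way). The side-coding window spans `side_code_lead_s` seconds on the
#' corresponding side of the approach time.
#'
#' @param n_units number of units.
#' @param baseline_shape,baseline_scale gamma parameters of the baseline
#'   rate distribution (Hz); defaults give a 5 Hz mean.
#' @param frac_cue_mod,frac_sipper_mod,frac_side population fractions
#'   (must sum to at most 1; the remainder is untuned).
#' @param cue_gain,sipper_gain,side_gain multiplicative rate factors
#'   applied inside the respective windows.
#' @param side_code_onset `"pre_approach"` or `"post_approach"`.
#' @param side_code_lead_s length (s) of the side-coding window.
#' @param refractory_s absolute refractory period (s).
#' @return A list of class `"population_params"`.
#' @export
population_params <- function(n_units = 40,
                              baseline_shape = 2, baseline_scale = 2.5,
                              frac_cue_mod = 0.25, frac_sipper_mod = 0.25,
                              frac_side = 0.30,
                              cue_gain = 3, sipper_gain = 3, side_gain = 3,
                              side_code_onset = c("pre_approach",
                                                  "post_approach"),
                              side_code_lead_s = 1.5,
                              refractory_s = 0.002) {
  side_code_onset <- match.arg(side_code_onset)
  fr <- c(frac_cue_mod, frac_sipper_mod, frac_side)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("population fractions must be >= 0 and sum to at most 1")
  if (any(c(cue_gain, sipper_gain, side_gain) < 0))
    stop("gains must be >= 0")
  structure(list(n_units = n_units, baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 frac_cue_mod = frac_cue_mod,
                 frac_sipper_mod = frac_sipper_mod, frac_side = frac_side,
                 cue_gain = cue_gain, sipper_gain = sipper_gain,
                 side_gain = side_gain, side_code_onset = side_code_onset,
                 side_code_lead_s = side_code_lead_s,
                 refractory_s = refractory_s),
            class = "population_params")
}

#' Generate a session schedule
#'
#' Builds one 2CAP session: `n_trials` trials (default 96) in random
#' order, half CS+ and half CS-, with the CS+ side drawn uniformly per
#' trial. Every trial has a 4 s cue; CS+ trials add a 1 s delay and 8 s of
#' sipper access. On congruent sessions the alcohol side equals the CS+
#' side; on incongruent sessions it is the opposite side. Cue style (solid
#' vs 1 Hz blink) is assigned randomly and counterbalanced.
#'
#' @param config a [twocap_config()] (supplies trial count and ITI).
#' @param session_type `"congruent"` or `"incongruent"`.
#' @param strain `"wistar"` or `"prat"` (metadata only).
#' @param seed integer seed; identical seeds give identical schedules.
#' @param session_id identifier for the generated session.
#' @return A validated `"task_schedule"`.
#' @export
generate_schedule <- function(config = twocap_config(),
                              session_type = c("congruent", "incongruent"),
                              strain = c("wistar", "prat"),
                              seed = 1, session_id = NULL) {
  session_type <- match.arg(session_type)
  strain <- match.arg(strain)
  set.seed(seed)
  n <- config$n_trials
  n_plus <- n %/% 2
  cs_type <- sample(rep(c("CS+", "CS-"), c(n_plus, n - n_plus)))
  cs_side <- ifelse(cs_type == "CS+",
                    sample(c("left", "right"), n, replace = TRUE), "both")
  alcohol_side <- rep("none", n)
  plus <- cs_type == "CS+"
  alcohol_side[plus] <- if (session_type == "congruent") cs_side[plus] else
    ifelse(cs_side[plus] == "left", "right", "left")
  cue_style <- sample(rep(c("solid", "blink_1Hz"), length.out = n))
  trial_len <- 4 + 1 + 8
  cue_on <- config$iti_s + (seq_len(n) - 1) * (trial_len + config$iti_s)
  trials <- data.frame(
    index = seq_len(n), cs_type = cs_type, cs_side = cs_side,
    alcohol_side = alcohol_side,
    cue_on = cue_on, cue_off = cue_on + 4,
    sipper_in = ifelse(plus, cue_on + 5, NA_real_),
    sipper_out = ifelse(plus, cue_on + 13, NA_real_),
    cue_style = cue_style)
  if (is.null(session_id))
    session_id <- sprintf("sim_%s_%s_%d", strain, session_type, seed)
  task_schedule(session_id = session_id, strain = strain,
                session_type = session_type, trials = trials,
                n_trials = n)
}

# Arena geometry (px, video-frame convention, 640x480 arena).
arena_landmarks <- function() {
  data.frame(
    name = c("corner_tl", "corner_tr", "corner_bl", "corner_br",
             "sipper_left", "sipper_right"),
    x = c(20, 620, 20, 620, 30, 610),
    y = c(20, 20, 460, 460, 240, 240))
}
arena_home <- c(320, 240)

# Decide first-approach side for one CS+ trial under the agent's rule.
choose_first_port <- function(agent, session_type, cs_side, alcohol_side) {
  other <- function(s) if (s == "left") "right" else "left"
  if (agent$control_mode == "reactive" || session_type == "congruent") {
    if (stats::runif(1) < agent$p_correct_congruent) alcohol_side
    else other(alcohol_side)
  } else {
    if (stats::runif(1) < agent$p_follow_cue) cs_side else alcohol_side
  }
}

#' Generate a pose track and behavioral ground truth
#'
#' Simulates the snout trajectory for one session: the animal rests at the
#' chamber center between trials, departs after a truncated-Gaussian
#' latency from cue onset on non-omitted CS+ trials, travels at constant
#' speed to its chosen sipper (on incorrect trials it dwells at the wrong
#' port, then corrects), holds at the port until the sipper retracts, and
#' returns home. The other body parts follow the snout with a fixed offset.
#' Ground-truth labels (outcome, first port, approach time) are computed
#' from the noise-free trajectory geometry: the first port whose approach
#' radius is entered during the access window defines the outcome, so the
#' labels remain faithful whatever the latency draws.
#'
#' @param schedule a `"task_schedule"`.
#' @param agent an [agent_params()].
#' @param config a [twocap_config()] (frame rate, approach radius,
#'   likelihood floor).
#' @param seed integer seed.
#' @return A list with `pose` (a `"pose_track"`) and `truth` (a data frame
#'   with one row per trial: `index`, `cs_type`, `outcome`, `first_port`,
#'   `approach_time`, `approach_side`, `cs_minus_approach`).
#' @export
generate_pose <- function(schedule, agent, config = twocap_config(),
                          seed = 1) {
  set.seed(seed + 1L)
  fps <- config$fps
  radius <- config$approach_radius_px
  lm <- arena_landmarks()
  port <- list(left = c(lm$x[lm$name == "sipper_left"],
                        lm$y[lm$name == "sipper_left"]),
               right = c(lm$x[lm$name == "sipper_right"],
                         lm$y[lm$name == "sipper_right"]))
  tr <- schedule$trials
  duration <- max(tr$cue_on) + 13 + config$iti_s
  # Waypoints (time, x, y); interpolated to frames at the end.
  wt <- c(0); wx <- c(arena_home[1]); wy <- c(arena_home[2])
  add_wp <- function(t, xy) {
    wt <<- c(wt, t); wx <<- c(wx, xy[1]); wy <<- c(wy, xy[2])
  }
  travel <- function(from, to) sqrt(sum((from - to)^2)) / agent$speed_px_s
  truth <- data.frame(index = tr$index, cs_type = tr$cs_type,
                      outcome = NA_character_, first_port = "none",
                      approach_time = NA_real_,
                      approach_side = NA_character_,
                      cs_minus_approach = FALSE,
                      stringsAsFactors = FALSE)
  draw_latency <- function()
    max(0.5, stats::rnorm(1, agent$latency_mean_s, agent$latency_sd_s))
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (row$cs_type == "CS-") {
      if (stats::runif(1) < agent$p_approach_cs_minus) {
        side <- sample(c("left", "right"), 1)
        depart <- row$cue_on + 5 + draw_latency() - 4
        tt <- travel(arena_home, port[[side]])
        add_wp(depart, arena_home)
        add_wp(depart + tt, port[[side]])
        add_wp(depart + tt + 1, port[[side]])
        add_wp(depart + tt + 1 + tt, arena_home)
        # counted as a CS- approach if within the mock access window
        enter <- depart + tt - radius / agent$speed_px_s
        leave <- depart + tt + 1 + radius / agent$speed_px_s
        truth$cs_minus_approach[i] <-
          enter <= row$cue_on + 13 && leave >= row$cue_on + 5
      }
      truth$outcome[i] <- NA_character_
      next
    }
    omit <- stats::runif(1) < agent$p_omit
    if (omit) { truth$outcome[i] <- "omission"; next }
    first <- choose_first_port(agent, schedule$session_type,
                               row$cs_side, row$alcohol_side)
    correct_side <- row$alcohol_side
    depart <- row$cue_on + draw_latency()
    t1 <- travel(arena_home, port[[first]])
    visits <- data.frame(side = first, arrive = depart + t1,
                         leave = depart + t1 +
                           if (first == correct_side) 0 else
                             agent$check_duration_s)
    if (first != correct_side) {
      t2 <- travel(port[[first]], port[[correct_side]])
      visits <- rbind(visits, data.frame(
        side = correct_side, arrive = visits$leave[1] + t2, leave = NA))
    }
    # dwell at the final (correct) port until the sipper retracts
    last <- nrow(visits)
    visits$leave[last] <- max(row$sipper_out,
                              visits$arrive[last] + 0.5)
    add_wp(depart, arena_home)
    for (v in seq_len(last)) {
      add_wp(visits$arrive[v], port[[visits$side[v]]])
      add_wp(visits$leave[v], port[[visits$side[v]]])
    }
    add_wp(visits$leave[last] + travel(port[[visits$side[last]]],
                                       arena_home), arena_home)
    # Truth from geometry: first port whose radius is entered during
    # the access window.
    r_dt <- radius / agent$speed_px_s
    hit <- NULL
    for (v in seq_len(last)) {
      enter <- visits$arrive[v] - r_dt
      leave <- visits$leave[v] + r_dt
      if (enter <= row$sipper_out && leave >= row$sipper_in) {
        hit <- c(visits$side[v], max(enter, row$sipper_in)); break
      }
    }
    if (is.null(hit)) {
      truth$outcome[i] <- "omission"
    } else {
      truth$first_port[i] <- hit[1]
      truth$approach_time[i] <- as.numeric(hit[2])
      truth$approach_side[i] <- hit[1]
      truth$outcome[i] <- if (hit[1] == correct_side) "correct"
        else "incorrect"
    }
  }
  # Interpolate waypoints to the frame grid; hold position between
  # excursions (waypoints bracket each excursion with home positions).
  time_s <- seq(0, duration, by = 1 / fps)
  add_wp(duration, arena_home)  # anchor: at rest at session end
  ord <- order(wt)
  sx <- stats::approx(wt[ord], wx[ord], xout = time_s, rule = 2,
                      ties = "ordered")$y
  sy <- stats::approx(wt[ord], wy[ord], xout = time_s, rule = 2,
                      ties = "ordered")$y
  n <- length(time_s)
  noise <- function() stats::rnorm(n, 0, agent$position_noise_px)
  frames <- data.frame(time_s = time_s)
  offsets <- list(snout = c(0, 0), head_cap = c(0, 18), back = c(0, 45),
                  tail = c(0, 80))
  for (part in names(offsets)) {
    frames[[paste0(part, "_x")]] <- sx + offsets[[part]][1] + noise()
    frames[[paste0(part, "_y")]] <- sy + offsets[[part]][2] + noise()
    lik <- rep(1, n)
    if (agent$low_conf_frac > 0) {
      k <- max(0L, round(agent$low_conf_frac * n))
      # never corrupt the first or last frame of the session so every
      # part keeps confident anchors for interpolation
      idx <- sample(2:(n - 1), min(k, n - 2))
      lik[idx] <- stats::runif(length(idx), 0, config$likelihood_floor - 0.01)
      frames[[paste0(part, "_x")]][idx] <-
        frames[[paste0(part, "_x")]][idx] + stats::runif(length(idx), -60, 60)
      frames[[paste0(part, "_y")]][idx] <-
        frames[[paste0(part, "_y")]][idx] + stats::runif(length(idx), -60, 60)
    }
    frames[[paste0(part, "_likelihood")]] <- lik
  }
  pose <- pose_track(fps = fps, frames = frames, landmarks = lm)
  list(pose = pose, truth = truth)
}

# Evaluate a piecewise rate: baseline everywhere, baseline*gain inside
# the (sorted, non-overlapping) intervals.
piecewise_rate <- function(t, baseline, gain, starts, ends) {
  r <- rep(baseline, length(t))
  if (length(starts) > 0) {
    i <- findInterval(t, starts)
    inside <- i >= 1 & t <= ends[pmax(i, 1)]
    r[inside] <- baseline * gain
  }
  r
}

# Inhomogeneous Poisson sampler with absolute refractory period via
# thinning. The thinning hazard is rate/(1 - rate*refractory) so the
# realized rate after dead-time removal matches the nominal rate.
sample_spike_train <- function(duration, baseline, gain, starts, ends,
                               refractory_s) {
  rmax <- baseline * max(gain, 1)
  if (rmax <= 0) return(numeric(0))
  hmax <- rmax / (1 - min(rmax * refractory_s, 0.5))
  n_cand <- stats::rpois(1, hmax * duration)
  if (n_cand == 0) return(numeric(0))
  tc <- sort(stats::runif(n_cand, 0, duration))
  rt <- piecewise_rate(tc, baseline, gain, starts, ends)
  ht <- rt / (1 - pmin(rt * refractory_s, 0.5))
  keep <- stats::runif(n_cand) < ht / hmax
  t <- tc[keep]
  # greedy dead-time enforcement: repeatedly drop the first violator of
  # each violation cluster (clusters are short at physiological rates)
  repeat {
    if (length(t) < 2) break
    viol <- which(diff(t) < refractory_s) + 1L
    if (length(viol) == 0) break
    drop <- viol[!(viol - 1L) %in% viol]
    t <- t[-drop]
  }
  t
}

#' Generate a spike-train population with ground-truth tuning
#'
#' Each unit is an inhomogeneous Poisson process with an absolute
#' refractory period, sampled by thinning. Rates are the unit's baseline
#' multiplied by its class gain inside the class window: cue-modulated
#' units during the 4 s cue, sipper-modulated units during the first and
#' last second of sipper access, and side-selective units around the
#' approach on trials toward their preferred side (before the approach in
#' the proactive regime, after it in the reactive regime). ISI-violation
#' fractions are zero by construction.
#'
#' @param schedule a `"task_schedule"`.
#' @param truth the truth table from [generate_pose()] (supplies approach
#'   times and sides).
#' @param pop a [population_params()].
#' @param seed integer seed.
#' @return A `"spike_data"` whose units carry `truth_class` labels.
#' @export
generate_spikes <- function(schedule, truth, pop, seed = 1) {
  set.seed(seed + 2L)
  tr <- schedule$trials
  duration <- max(tr$cue_on) + 13 + 30
  n <- pop$n_units
  n_cue <- round(pop$frac_cue_mod * n)
  n_sip <- round(pop$frac_sipper_mod * n)
  n_side <- round(pop$frac_side * n)
  classes <- c(rep("cue_mod", n_cue), rep("sipper_mod", n_sip),
               rep(c("side_left", "side_right"), length.out = n_side),
               rep("untuned", max(0, n - n_cue - n_sip - n_side)))[1:n]
  baseline <- stats::rgamma(n, shape = pop$baseline_shape,
                            scale = pop$baseline_scale)
  baseline <- pmax(baseline, 0.5)
  plus <- tr$cs_type == "CS+"
  cue_iv <- cbind(tr$cue_on, tr$cue_off)
  sip_iv <- rbind(cbind(tr$sipper_in[plus], tr$sipper_in[plus] + 1),
                  cbind(tr$sipper_out[plus] - 1, tr$sipper_out[plus]))
  sip_iv <- sip_iv[order(sip_iv[, 1]), , drop = FALSE]
  side_iv <- function(pref) {
    ok <- !is.na(truth$approach_time) & truth$approach_side == pref
    ta <- truth$approach_time[ok]
    if (length(ta) == 0) return(cbind(numeric(0), numeric(0)))
    iv <- if (pop$side_code_onset == "pre_approach")
      cbind(ta - pop$side_code_lead_s, ta)
    else cbind(ta, ta + pop$side_code_lead_s)
    iv[order(iv[, 1]), , drop = FALSE]
  }
  iv_left <- side_iv("left"); iv_right <- side_iv("right")
  units <- vector("list", n)
  for (u in seq_len(n)) {
    iv <- switch(classes[u],
                 cue_mod = cue_iv,
                 sipper_mod = sip_iv,
                 side_left = iv_left,
                 side_right = iv_right,
                 cbind(numeric(0), numeric(0)))
    gain <- switch(classes[u],
                   cue_mod = pop$cue_gain,
                   sipper_mod = pop$sipper_gain,
                   side_left = pop$side_gain,
                   side_right = pop$side_gain, 1)
    st <- sample_spike_train(duration, baseline[u], gain,
                             iv[, 1], iv[, 2], pop$refractory_s)
    viol <- if (length(st) > 1) mean(diff(st) < pop$refractory_s) else 0
    units[[u]] <- list(unit_id = sprintf("u%03d", u), spike_times = st,
                       isi_violation_fraction = viol,
                       truth_class = classes[u])
  }
  spike_data(units, session_id = schedule$session_id)
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper chaining [generate_schedule()], [generate_pose()]
#' and [generate_spikes()] under one seed.
#'
#' @param session_type,strain passed to [generate_schedule()].
#' @param agent an [agent_params()].
#' @param pop a [population_params()].
#' @param config a [twocap_config()].
#' @param seed integer seed.
#' @return A list with `schedule`, `pose`, `truth`, `spikes`.
#' @export
generate_session <- function(session_type = "congruent",
                             strain = "wistar",
                             agent = agent_params(),
                             pop = population_params(),
                             config = twocap_config(), seed = 1) {
  schedule <- generate_schedule(config, session_type, strain, seed = seed)
  beh <- generate_pose(schedule, agent, config, seed = seed)
  spikes <- generate_spikes(schedule, beh$truth, pop, seed = seed)
  list(schedule = schedule, pose = beh$pose, truth = beh$truth,
       spikes = spikes)
}
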