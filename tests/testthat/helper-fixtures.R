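# Shared fixtures, built in code. Sessions are cached so expensive
# generation runs once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A noiseless, fully deterministic agent: every decision is forced.
noise_free_agent <- function(...) {
  agent_params(position_noise_px = 0, low_conf_frac = 0, ...)
}

# Default synthetic session (congruent, proactive, default population).
fixture_session <- function() {
  cached("session_default", generate_session(seed = 11))
}

# A tiny hand-built schedule with n CS+ trials (validation relaxed).
mini_schedule <- function(n_plus = 2, session_type = "congruent",
                          iti = 30) {
  cue_on <- 5 + (seq_len(n_plus) - 1) * (13 + iti)
  cs_side <- rep(c("left", "right"), length.out = n_plus)
  alcohol <- if (session_type == "congruent") cs_side else
    ifelse(cs_side == "left", "right", "left")
  trials <- data.frame(
    index = seq_len(n_plus), cs_type = "CS+", cs_side = cs_side,
    alcohol_side = alcohol, cue_on = cue_on, cue_off = cue_on + 4,
    sipper_in = cue_on + 5, sipper_out = cue_on + 13,
    cue_style = "solid")
  task_schedule("mini", "wistar", session_type, trials,
                n_trials = n_plus)
}

# A pose track whose snout follows the supplied (time, x, y) waypoints
# (linear interpolation; other parts ride along), landmarks at the
# standard arena positions.
mini_pose <- function(waypoints, duration, fps = 30) {
  lm <- data.frame(
    name = c("corner_tl", "corner_tr", "corner_bl", "corner_br",
             "sipper_left", "sipper_right"),
    x = c(20, 620, 20, 620, 30, 610),
    y = c(20, 20, 460, 460, 240, 240))
  tt <- seq(0, duration, by = 1 / fps)
  if (is.null(waypoints$y)) waypoints$y <- 240  # sipper height
  x <- approx(waypoints$t, waypoints$x, xout = tt, rule = 2)$y
  y <- approx(waypoints$t, waypoints$y, xout = tt, rule = 2)$y
  frames <- data.frame(time_s = tt)
  for (part in c("snout", "head_cap", "back", "tail")) {
    frames[[paste0(part, "_x")]] <- x
    frames[[paste0(part, "_y")]] <- y
    frames[[paste0(part, "_likelihood")]] <- 1
  }
  pose_track(fps = fps, frames = frames, landmarks = lm)
}

# Homogeneous-Poisson spike train helper (rate Hz over duration s).
poisson_train <- function(rate, duration) {
  n <- rpois(1, rate * duration)
  sort(runif(n, 0, duration))
}
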