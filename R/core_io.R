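#' Analysis configuration
#'
#' Collects the analysis constants used throughout the pipeline. Defaults
#' are the values of the published protocol: a 9 px approach radius, a 0.90
#' tracking-confidence floor, 100 ms rate bins, a \[-4, 18\] s cue-centered
#' window, a \[-2, 2\] s approach-centered window, the first 15 trials for
#' cue-centered averaging (and up to 15 correct trials per side for the
#' left/right analysis), a +/-0.01 loading-split threshold, 1000 bootstrap
#' trial pairs and 3-dimensional subspaces.
#'
#' @param approach_radius_px snout-to-sipper distance (px) defining an
#'   approach.
#' @param likelihood_floor tracker confidence below which a frame is
#'   interpolated.
#' @param bin_width_s firing-rate bin width in seconds.
#' @param cue_window_s two-element window (s) around cue onset.
#' @param approach_window_s two-element window (s) around the approach.
#' @param n_trials_used number of trials entering trial averages.
#' @param loading_threshold absolute loading below which a unit is excluded
#'   from the sign split.
#' @param n_bootstrap number of bootstrap (left, right) trial pairs.
#' @param subspace_dim dimensionality of each enumerated PC subspace.
#' @param n_trials total trials per session (48 CS+ plus 48 CS-).
#' @param iti_s inter-trial interval in seconds.
#' @param fps video frame rate (frames/s).
#' @param sigma_max_s cap on the adaptive kernel width in seconds.
#' @param sigma_units `"seconds"` evaluates the kernel-width rule with the
#'   mean ISI in seconds; `"bins"` evaluates it in bin units.
#' @param rng_seed optional integer seed recorded with the configuration.
#' @return A list of class `"twocap_config"`.
#' @export
twocap_config <- function(approach_radius_px = 9,
                          likelihood_floor = 0.90,
                          bin_width_s = 0.1,
                          cue_window_s = c(-4, 18),
                          approach_window_s = c(-2, 2),
                          n_trials_used = 15,
                          loading_threshold = 0.01,
                          n_bootstrap = 1000,
                          subspace_dim = 3,
                          n_trials = 96,
                          iti_s = 30,
                          fps = 30,
                          sigma_max_s = 2,
                          sigma_units = c("seconds", "bins"),
                          rng_seed = NULL) {
  sigma_units <- match.arg(sigma_units)
  cfg <- list(
    approach_radius_px = approach_radius_px,
    likelihood_floor = likelihood_floor,
    bin_width_s = bin_width_s,
    cue_window_s = cue_window_s,
    approach_window_s = approach_window_s,
    n_trials_used = n_trials_used,
    loading_threshold = loading_threshold,
    n_bootstrap = n_bootstrap,
    subspace_dim = subspace_dim,
    n_trials = n_trials,
    iti_s = iti_s,
    fps = fps,
    sigma_max_s = sigma_max_s,
    sigma_units = sigma_units,
    rng_seed = rng_seed
  )
  class(cfg) <- "twocap_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("approach_radius_px", "likelihood_floor", "bin_width_s",
           "n_trials_used", "loading_threshold", "n_bootstrap",
           "subspace_dim", "n_trials", "fps", "sigma_max_s")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive scalar", call. = FALSE)
  }
  for (nm in c("cue_window_s", "approach_window_s")) {
    w <- cfg[[nm]]
    if (length(w) != 2 || w[1] >= w[2])
      stop("config window '", nm, "' must be ordered [start, end]",
           call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a flat YAML key set mirroring [twocap_config()]; keys absent from
#' the file keep their defaults, and `overrides` (named values, e.g. from a
#' script's command line) take precedence over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list overriding file values.
#' @return A `"twocap_config"` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(twocap_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(twocap_config, vals)
}

# ---- TaskSchedule ----------------------------------------------------------

#' Construct a task schedule
#'
#' A schedule holds the per-trial contingencies and event times for one
#' 2CAP session: 96 trials, 48 CS+ (cue on one side, sipper access follows)
#' and 48 CS- (cue on both sides, no sipper). On congruent sessions alcohol
#' is presented on the CS+ side; on incongruent sessions on the opposite
#' side. Each CS+ trial has a 4 s cue, a 1 s delay, then 8 s of sipper
#' access.
#'
#' @param session_id character session identifier.
#' @param strain `"wistar"` or `"prat"`.
#' @param session_type `"congruent"` or `"incongruent"`.
#' @param trials data frame with columns `index`, `cs_type` ("CS+"/"CS-"),
#'   `cs_side` ("left"/"right"/"both"), `alcohol_side`
#'   ("left"/"right"/"none"), `cue_on`, `cue_off`, `sipper_in`,
#'   `sipper_out` (seconds from session start; NA where undefined) and
#'   `cue_style` ("solid"/"blink_1Hz").
#' @param n_trials expected number of trials (default 96).
#' @return A list of class `"task_schedule"`.
#' @export
task_schedule <- function(session_id, strain = c("wistar", "prat"),
                          session_type = c("congruent", "incongruent"),
                          trials, n_trials = 96) {
  strain <- match.arg(strain)
  session_type <- match.arg(session_type)
  obj <- structure(
    list(session_id = as.character(session_id), strain = strain,
         session_type = session_type, trials = as.data.frame(trials)),
    class = "task_schedule")
  validate_schedule(obj, n_trials = n_trials)
  obj
}

validate_schedule <- function(sched, n_trials = 96) {
  tr <- sched$trials
  need <- c("index", "cs_type", "cs_side", "alcohol_side", "cue_on",
            "cue_off", "sipper_in", "sipper_out", "cue_style")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("schedule is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tr) != n_trials)
    stop("schedule has ", nrow(tr), " trials; expected ", n_trials)
  if (anyDuplicated(tr$index))
    stop("duplicate trial index: ",
         tr$index[duplicated(tr$index)][1])
  n_plus <- sum(tr$cs_type == "CS+")
  if (n_trials == 96 && (n_plus != 48 || sum(tr$cs_type == "CS-") != 48))
    stop("expected 48 CS+ and 48 CS- trials; got ", n_plus, " CS+")
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    if (row$cs_type == "CS+") {
      ok <- isTRUE(all.equal(row$cue_off, row$cue_on + 4)) &&
        isTRUE(all.equal(row$sipper_in, row$cue_off + 1)) &&
        isTRUE(all.equal(row$sipper_out, row$sipper_in + 8))
      if (!ok)
        stop("trial ", row$index,
             ": CS+ event times violate cue 4 s / delay 1 s / access 8 s")
      if (!row$cs_side %in% c("left", "right"))
        stop("trial ", row$index, ": CS+ trial must have cs_side left/right")
      if (!row$alcohol_side %in% c("left", "right"))
        stop("trial ", row$index, ": CS+ trial must have an alcohol side")
      same <- row$alcohol_side == row$cs_side
      if (sched$session_type == "congruent" && !same)
        stop("trial ", row$index,
             ": congruent session requires alcohol_side == cs_side")
      if (sched$session_type == "incongruent" && same)
        stop("trial ", row$index,
             ": incongruent session requires alcohol_side != cs_side")
    } else {
      if (row$cs_side != "both")
        stop("trial ", row$index, ": CS- trial must have cs_side 'both'")
      if (row$alcohol_side != "none" ||
          !is.na(row$sipper_in) || !is.na(row$sipper_out))
        stop("trial ", row$index, ": CS- trial must have no sipper events")
      if (!isTRUE(all.equal(row$cue_off, row$cue_on + 4)))
        stop("trial ", row$index, ": cue duration must be 4 s")
    }
  }
  invisible(sched)
}

# ---- PoseTrack -------------------------------------------------------------

pose_parts <- c("snout", "head_cap", "back", "tail")
pose_landmarks <- c("corner_tl", "corner_tr", "corner_bl", "corner_br",
                    "sipper_left", "sipper_right")

#' Construct a pose track
#'
#' Frame-by-frame coordinates for the four tracked body parts (snout,
#' head cap, back, tail) plus the six static landmarks (four corners, two
#' sipper ports), in the video-frame pixel convention (origin top-left,
#' x rightward, y downward) at `fps` frames per second.
#'
#' @param fps frames per second (default 30).
#' @param frames data frame with a `time_s` column and, per body part,
#'   `<part>_x`, `<part>_y`, `<part>_likelihood` columns.
#' @param landmarks data frame with columns `name`, `x`, `y` covering the
#'   six landmarks.
#' @return A list of class `"pose_track"`.
#' @export
pose_track <- function(fps = 30, frames, landmarks) {
  obj <- structure(list(fps = fps, frames = as.data.frame(frames),
                        landmarks = as.data.frame(landmarks)),
                   class = "pose_track")
  validate_pose(obj)
  obj
}

validate_pose <- function(pose) {
  fr <- pose$frames
  for (part in pose_parts) {
    cols <- paste0(part, c("_x", "_y", "_likelihood"))
    miss <- setdiff(cols, names(fr))
    if (length(miss) > 0)
      stop("pose track missing columns for body part '", part, "': ",
           paste(miss, collapse = ", "))
    lik <- fr[[paste0(part, "_likelihood")]]
    bad <- which(lik < 0 | lik > 1)
    if (length(bad) > 0)
      stop("likelihood outside [0,1] for '", part, "' at frame ", bad[1],
           " (value ", lik[bad[1]], ")")
  }
  miss_lm <- setdiff(pose_landmarks, pose$landmarks$name)
  if (length(miss_lm) > 0)
    stop("pose track missing landmarks: ", paste(miss_lm, collapse = ", "))
  invisible(pose)
}

sipper_xy <- function(pose, side) {
  lm <- pose$landmarks
  row <- lm[lm$name == paste0("sipper_", side), ]
  c(row$x, row$y)
}

# ---- SpikeData -------------------------------------------------------------

#' Construct spike data
#'
#' Sorted single-unit spike times for one session. Each unit carries its
#' fraction of inter-spike-interval (ISI) violations; units used in the
#' analyses must have strictly fewer than 5% ISIs shorter than the
#' refractory period (see [qc_filter()]). Synthetic units may carry a
#' ground-truth tuning class.
#'
#' @param units list of lists with fields `unit_id`, `spike_times`
#'   (seconds, will be sorted ascending), `isi_violation_fraction`, and
#'   optional `truth_class` (one of `"cue_mod"`, `"sipper_mod"`,
#'   `"side_left"`, `"side_right"`, `"untuned"`).
#' @param session_id character identifier.
#' @return A list of class `"spike_data"`.
#' @export
spike_data <- function(units, session_id = "session") {
  units <- lapply(units, function(u) {
    if (is.unsorted(u$spike_times)) u$spike_times <- sort(u$spike_times)
    if (length(u$spike_times) > 0 && u$spike_times[1] < 0)
      stop("unit ", u$unit_id, ": negative spike time ", u$spike_times[1])
    if (is.null(u$isi_violation_fraction))
      u$isi_violation_fraction <- NA_real_
    if (is.null(u$truth_class)) u$truth_class <- NA_character_
    u
  })
  structure(list(units = units, session_id = as.character(session_id)),
            class = "spike_data")
}

# ---- Pose CSV (three-row-header dialect) -----------------------------------

#' Write a pose table
#'
#' Writes the three-row-header CSV dialect used by markerless pose
#' trackers: a `scorer` row, a `bodyparts` row, and a `coords` row with an
#' x/y/likelihood triplet per tracked point, followed by numeric rows
#' keyed by frame index. Static landmarks are written as constant columns
#' with likelihood 1.
#'
#' @param pose a `"pose_track"`.
#' @param path output file path.
#' @param scorer label for the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(pose, path, scorer = "twocap") {
  fr <- pose$frames
  n <- nrow(fr)
  cols <- list(frame = seq_len(n) - 1L)
  parts <- character(0)
  for (part in pose_parts) {
    cols[[paste0(part, ".x")]] <- fr[[paste0(part, "_x")]]
    cols[[paste0(part, ".y")]] <- fr[[paste0(part, "_y")]]
    cols[[paste0(part, ".likelihood")]] <- fr[[paste0(part, "_likelihood")]]
    parts <- c(parts, rep(part, 3))
  }
  for (lmn in pose_landmarks) {
    row <- pose$landmarks[pose$landmarks$name == lmn, ]
    cols[[paste0(lmn, ".x")]] <- rep(row$x, n)
    cols[[paste0(lmn, ".y")]] <- rep(row$y, n)
    cols[[paste0(lmn, ".likelihood")]] <- rep(1, n)
    parts <- c(parts, rep(lmn, 3))
  }
  header1 <- c("scorer", rep(scorer, length(parts)))
  header2 <- c("bodyparts", parts)
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts) / 3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  mat <- do.call(cbind, cols)
  utils::write.table(mat, con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pose table
#'
#' Parses the three-row-header pose CSV dialect written by
#' [write_pose_table()] (and by common markerless trackers) back into a
#' [pose_track()]. All ten tracked points must be present; landmark
#' coordinates are taken from the first frame.
#'
#' @param path CSV file path.
#' @param fps frame rate used to reconstruct `time_s` (default 30).
#' @return A `"pose_track"`.
#' @export
read_pose_table <- function(path, fps = 30) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3)
    stop("pose table format error: expected 3 header rows, got ",
         length(hdr))
  h1 <- strsplit(hdr[1], ",")[[1]]
  h2 <- strsplit(hdr[2], ",")[[1]]
  h3 <- strsplit(hdr[3], ",")[[1]]
  if (tolower(h1[1]) != "scorer" || tolower(h2[1]) != "bodyparts" ||
      tolower(h3[1]) != "coords")
    stop("pose table format error: header rows must be scorer/bodyparts/",
         "coords; got '", h1[1], "'/'", h2[1], "'/'", h3[1], "'")
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  names(dat) <- c("frame", paste(h2[-1], h3[-1], sep = "."))
  known <- c(pose_parts, pose_landmarks)
  got_parts <- unique(h2[-1])
  unknown <- setdiff(got_parts, known)
  if (length(unknown) > 0)
    stop("unknown body-part name(s) in pose table: ",
         paste(unknown, collapse = ", "))
  for (p in got_parts) {
    if (!paste0(p, ".likelihood") %in% names(dat))
      stop("pose table format error: missing likelihood column for '",
           p, "'")
  }
  miss <- setdiff(known, got_parts)
  if (length(miss) > 0)
    stop("pose table missing tracked point(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(dat)
  frames <- data.frame(time_s = (seq_len(n) - 1) / fps)
  for (part in pose_parts) {
    frames[[paste0(part, "_x")]] <- dat[[paste0(part, ".x")]]
    frames[[paste0(part, "_y")]] <- dat[[paste0(part, ".y")]]
    frames[[paste0(part, "_likelihood")]] <- dat[[paste0(part, ".likelihood")]]
  }
  landmarks <- data.frame(
    name = pose_landmarks,
    x = unname(vapply(pose_landmarks,
                      function(l) dat[[paste0(l, ".x")]][1], 0)),
    y = unname(vapply(pose_landmarks,
                      function(l) dat[[paste0(l, ".y")]][1], 0)),
    row.names = NULL)
  pose_track(fps = fps, frames = frames, landmarks = landmarks)
}

# ---- Spike / schedule CSV --------------------------------------------------

#' Write and read tidy spike tables
#'
#' The spike table is a tidy CSV with one row per spike: `unit_id`,
#' `spike_time_s`, and optional `truth_class` / `isi_violation_fraction`
#' columns (constant within a unit). On read, spike times are sorted
#' ascending within each unit.
#'
#' @param spikes a `"spike_data"`.
#' @param path CSV file path.
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns a `"spike_data"`.
#' @export
write_spike_table <- function(spikes, path) {
  rows <- lapply(spikes$units, function(u) {
    if (length(u$spike_times) == 0) return(NULL)
    data.frame(unit_id = u$unit_id, spike_time_s = u$spike_times,
               truth_class = u$truth_class,
               isi_violation_fraction = u$isi_violation_fraction)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @param session_id session identifier attached on read.
#' @export
read_spike_table <- function(path, session_id = "session") {
  if (!file.exists(path)) stop("spike file not found: ", path)
  dat <- utils::read.csv(path)
  if (!all(c("unit_id", "spike_time_s") %in% names(dat)))
    stop("spike table must have unit_id and spike_time_s columns")
  bad <- which(dat$spike_time_s < 0)
  if (length(bad) > 0)
    stop("negative spike time in row ", bad[1], " (unit ",
         dat$unit_id[bad[1]], ")")
  units <- lapply(split(dat, dat$unit_id), function(d) {
    list(unit_id = d$unit_id[1],
         spike_times = sort(d$spike_time_s),
         isi_violation_fraction =
           if ("isi_violation_fraction" %in% names(d))
             d$isi_violation_fraction[1] else NA_real_,
         truth_class = if ("truth_class" %in% names(d))
           as.character(d$truth_class[1]) else NA_character_)
  })
  spike_data(unname(units), session_id = session_id)
}

#' Write and read schedule tables
#'
#' Schedules are stored as plain CSV, one row per trial, with the session
#' metadata (`session_id`, `strain`, `session_type`) repeated per row.
#'
#' @param sched a `"task_schedule"`.
#' @param path CSV file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   a validated `"task_schedule"`.
#' @export
write_schedule <- function(sched, path) {
  tr <- sched$trials
  tr$session_id <- sched$session_id
  tr$strain <- sched$strain
  tr$session_type <- sched$session_type
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param n_trials expected trial count (default 96).
#' @export
read_schedule <- function(path, n_trials = 96) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  tr <- utils::read.csv(path)
  meta <- c("session_id", "strain", "session_type")
  if (!all(meta %in% names(tr)))
    stop("schedule table must carry session_id, strain, session_type")
  task_schedule(session_id = tr$session_id[1], strain = tr$strain[1],
                session_type = tr$session_type[1],
                trials = tr[, setdiff(names(tr), meta)],
                n_trials = n_trials)
}

# ---- Results JSON ----------------------------------------------------------

#' Serialize analysis results to JSON
#'
#' Generic JSON round trip for pipeline result objects (lists of numeric
#' vectors/matrices and metadata). The object's class is stored alongside
#' the data so `read_results()` restores it.
#'
#' @param obj a list-like result object.
#' @param path JSON file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   the restored object.
#' @export
write_results <- function(obj, path) {
  payload <- list(class = class(obj), data = unclass(obj))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj <- payload$data
  class(obj) <- payload$class
  if (inherits(obj, "perm_distance") && is.matrix(obj$subspaces))
    obj$subspaces <- lapply(seq_len(nrow(obj$subspaces)),
                            function(i) as.integer(obj$subspaces[i, ]))
  obj
}
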