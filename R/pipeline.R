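#' Left/right encoding analysis for one session
#'
#' Runs the approach-centered pipeline end to end on one session: detect
#' and classify approaches from the pose track, QC-filter the units,
#' build approach-aligned rate tensors for the correct left and correct
#' right trials (up to `config$n_trials_used` per side), fit the
#' side-concatenated PCA on the trial means, project the single trials
#' into the retained space, enumerate the 3-component subspaces and
#' compute the bootstrap left/right distance per subspace, and compute
#' the loading-split pre/post side differences for every enumerated
#' component.
#'
#' @param session a list with `schedule`, `pose`, `spikes` (e.g. from
#'   [generate_session()]); a `truth` element, if present, is ignored --
#'   events are always re-derived from the pose.
#' @param config a [twocap_config()].
#' @param seed seed for the bootstrap draws.
#' @param pre_approach_only restrict the distance statistic to bins
#'   before the approach (default TRUE).
#' @param n_components number of leading components over which subspaces
#'   are enumerated; the default derives it from the broken stick on the
#'   data at hand (with a floor of `config$subspace_dim`). Set it
#'   explicitly (e.g. 9, giving 84 subspaces) to compare distance
#'   distributions at a fixed subspace count across conditions.
#' @return A list: `events`, `metrics`, `pca`, `projection`,
#'   `n_retained`, `n_subspace` (components actually enumerated),
#'   `distance` (a `"perm_distance"`), `prepost` (data frame over
#'   components and sign groups), `left_mean`, `right_mean`,
#'   `n_left`, `n_right`.
#' @export
side_encoding_analysis <- function(session, config = twocap_config(),
                                   seed = 1, pre_approach_only = TRUE,
                                   n_components = NULL) {
  pose <- interpolate_low_confidence(session$pose,
                                     floor = config$likelihood_floor)
  events <- detect_and_classify(pose, session$schedule,
                                radius_px = config$approach_radius_px)
  metrics <- session_metrics(events, session$schedule)
  spikes <- qc_filter(session$spikes)
  ev <- events$trials
  correct <- ev[ev$cs_type == "CS+" & ev$outcome == "correct", ]
  pick_side <- function(side) {
    d <- correct[correct$first_port == side, ]
    d <- d[order(d$index), ]
    utils::head(d, config$n_trials_used)
  }
  left <- pick_side("left"); right <- pick_side("right")
  if (nrow(left) == 0 || nrow(right) == 0)
    stop("session has no correct approaches on one side (",
         nrow(left), " left, ", nrow(right), " right)")
  tens <- function(d) estimate_rates(
    spikes, session$schedule, alignment = "approach",
    align_times = d$approach_time_correct,
    window_s = config$approach_window_s, config = config)
  lt <- tens(left); rt <- tens(right)
  lm_mean <- trial_average(lt); rm_mean <- trial_average(rt)
  fit <- side_concatenated_pca(list(lm_mean), list(rm_mean))
  n_ret <- fit$pca$retained
  n_sub <- if (is.null(n_components)) max(n_ret, config$subspace_dim)
    else n_components
  n_sub <- min(n_sub, ncol(fit$pca$coefficients))
  comps <- seq_len(n_sub)
  lt_list <- lapply(seq_len(dim(lt$rates)[3]),
                    function(j) lt$rates[, , j, drop = TRUE])
  rt_list <- lapply(seq_len(dim(rt$rates)[3]),
                    function(j) rt$rates[, , j, drop = TRUE])
  lscores <- project_trials(fit$pca, lt_list, components = comps)
  rscores <- project_trials(fit$pca, rt_list, components = comps)
  subs <- subspace_permutations(n_sub, config$subspace_dim)
  dist <- permutation_distance(
    lscores, rscores, subs, n_bootstrap = config$n_bootstrap,
    pre_approach_only = pre_approach_only,
    approach_index = fit$projection$approach_index, seed = seed)
  prepost <- do.call(rbind, lapply(comps, function(pc) {
    sp <- split_by_loading(fit$pca, pc,
                           threshold = config$loading_threshold)
    pp <- prepost_side_difference(sp, lm_mean, rm_mean,
                                  fit$projection$approach_index)
    pp$component <- pc
    pp
  }))
  list(events = events, metrics = metrics, pca = fit$pca,
       projection = fit$projection, n_retained = n_ret,
       n_subspace = n_sub, distance = dist, prepost = prepost,
       left_mean = lm_mean, right_mean = rm_mean,
       n_left = nrow(left), n_right = nrow(right))
}
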