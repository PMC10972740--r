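#' Filter units on ISI violations
#'
#' Retains units whose fraction of inter-spike intervals shorter than the
#' refractory period is strictly below `max_violation` (the published
#' criterion: fewer than 5% ISI violations). The violation fraction is
#' recomputed from the spike times; units with fewer than two spikes are
#' excluded and reported.
#'
#' @param spikes a `"spike_data"`.
#' @param max_violation exclusive upper bound on the violation fraction.
#' @param refractory_s ISI threshold defining a violation (s).
#' @return A filtered `"spike_data"` with refreshed
#'   `isi_violation_fraction` fields.
#' @export
qc_filter <- function(spikes, max_violation = 0.05, refractory_s = 0.002) {
  kept <- list()
  for (u in spikes$units) {
    if (length(u$spike_times) < 2) {
      message("qc_filter: excluding unit ", u$unit_id,
              " (fewer than 2 spikes)")
      next
    }
    viol <- mean(diff(u$spike_times) < refractory_s)
    if (viol >= max_violation) next
    u$isi_violation_fraction <- viol
    kept[[length(kept) + 1]] <- u
  }
  spike_data(kept, session_id = spikes$session_id)
}

#' Inter-spike-interval statistics
#'
#' Mean and coefficient of variation (sample standard deviation over
#' mean) of the successive differences of a spike train; these set the
#' unit's adaptive smoothing-kernel width via [kernel_sigma()].
#'
#' @param spike_times ascending spike times (s); at least 3 spikes.
#' @return A list of class `"isi_stats"`: `mean_isi_s`, `cv`, `n_isi`.
#' @export
isi_stats <- function(spike_times) {
  if (length(spike_times) < 3)
    stop("isi_stats requires at least 3 spikes; got ", length(spike_times))
  isi <- diff(spike_times)
  m <- mean(isi)
  structure(list(mean_isi_s = m, cv = stats::sd(isi) / m,
                 n_isi = length(isi)),
            class = "isi_stats")
}

#' Adaptive kernel width from ISI statistics
#'
#' The per-neuron smoothing width is the square root of the mean ISI
#' multiplied by the inverse coefficient of variation,
#' `sigma = sqrt(mean_isi) / cv`, capped at `sigma_max_s`. Irregular
#' (bursty) units therefore get narrow kernels and regular units wide
#' ones; a zero CV (perfectly regular train) yields the cap. With
#' `units = "bins"` the mean ISI is first expressed in bin units and the
#' resulting sigma converted back to seconds.
#'
#' @param stats an `"isi_stats"`.
#' @param sigma_max_s cap in seconds (default 2).
#' @param units `"seconds"` (default) or `"bins"`.
#' @param bin_width_s bin width used when `units = "bins"`.
#' @return Kernel standard deviation in seconds.
#' @export
kernel_sigma <- function(stats, sigma_max_s = 2,
                         units = c("seconds", "bins"),
                         bin_width_s = 0.1) {
  units <- match.arg(units)
  if (stats$cv <= 0) return(sigma_max_s)
  sig <- if (units == "seconds") sqrt(stats$mean_isi_s) / stats$cv
    else sqrt(stats$mean_isi_s / bin_width_s) / stats$cv * bin_width_s
  min(sig, sigma_max_s)
}

# Discrete Gaussian kernel truncated at +/- 3 sigma, renormalized to
# unit mass so smoothing conserves spike count.
gaussian_kernel <- function(sigma_s, bin_width_s) {
  h <- max(1L, ceiling(3 * sigma_s / bin_width_s))
  x <- (-h:h) * bin_width_s
  k <- exp(-x^2 / (2 * sigma_s^2))
  k / sum(k)
}

# Bin centers on the bin-width grid spanning both endpoints inclusive.
window_bins <- function(window_s, bin_width_s) {
  seq(window_s[1], window_s[2], by = bin_width_s)
}

#' Event-aligned smoothed firing-rate tensor
#'
#' Bins each unit's spikes at `config$bin_width_s` (100 ms) around the
#' alignment event of every included trial, converts counts to Hz, and
#' convolves each trial's rate vector with the unit's adaptive Gaussian
#' kernel (truncated at three sigma, renormalized; see [kernel_sigma()]).
#' Bin centers lie on the bin-width grid and include both window
#' endpoints, so the cue-centered \[-4, 18\] s window yields 221 bins.
#' For `alignment = "cue_on"` the first `config$n_trials_used` CS+ trials
#' are used; for `alignment = "approach"` supply explicit `align_times`
#' (e.g. truth or detected approach times). Trials whose window extends
#' beyond the recorded data are dropped with a message.
#'
#' @param spikes a `"spike_data"` (normally after [qc_filter()]).
#' @param schedule a `"task_schedule"`.
#' @param alignment `"cue_on"` or `"approach"`.
#' @param align_times numeric alignment times (s), required for
#'   `"approach"`; defaults to the CS+ cue onsets for `"cue_on"`.
#' @param window_s window around the event; defaults to the config's
#'   cue or approach window.
#' @param config a [twocap_config()].
#' @return An object of class `"rate_tensor"`: list with `rates` (units x
#'   bins x trials array, Hz), `bins` (centers, s), `unit_ids`,
#'   `alignment`, `window_s`, `sigma_s` (per unit), `trial_ids`.
#' @export
estimate_rates <- function(spikes, schedule,
                           alignment = c("cue_on", "approach"),
                           align_times = NULL, window_s = NULL,
                           config = twocap_config()) {
  alignment <- match.arg(alignment)
  tr <- schedule$trials
  if (alignment == "cue_on") {
    plus <- tr[tr$cs_type == "CS+", ]
    plus <- plus[order(plus$index), ]
    plus <- plus[seq_len(min(config$n_trials_used, nrow(plus))), ]
    if (is.null(align_times)) align_times <- plus$cue_on
    trial_ids <- plus$index
    if (is.null(window_s)) window_s <- config$cue_window_s
  } else {
    if (is.null(align_times))
      stop("alignment = 'approach' requires align_times")
    trial_ids <- seq_along(align_times)
    if (is.null(window_s)) window_s <- config$approach_window_s
  }
  if (any(is.na(align_times)))
    stop("alignment times must be available for every included trial")
  bw <- config$bin_width_s
  centers <- window_bins(window_s, bw)
  nb <- length(centers)
  rec_end <- max(tr$cue_on) + 13 + config$iti_s
  ok <- align_times + window_s[1] - bw / 2 >= 0 &
    align_times + window_s[2] + bw / 2 <= rec_end
  if (any(!ok)) {
    message("estimate_rates: dropping ", sum(!ok),
            " trial(s) whose window exceeds the recording")
    align_times <- align_times[ok]
    trial_ids <- trial_ids[ok]
  }
  nt <- length(align_times)
  nu <- length(spikes$units)
  rates <- array(0, dim = c(nu, nb, nt))
  sigmas <- numeric(nu)
  edges <- c(centers - bw / 2, centers[nb] + bw / 2)
  for (u in seq_len(nu)) {
    st <- spikes$units[[u]]$spike_times
    if (length(st) >= 3) {
      s <- isi_stats(st)
      sigmas[u] <- kernel_sigma(s, sigma_max_s = config$sigma_max_s,
                                units = config$sigma_units,
                                bin_width_s = bw)
    } else {
      sigmas[u] <- config$sigma_max_s
    }
    kern <- gaussian_kernel(sigmas[u], bw)
    h <- (length(kern) - 1L) %/% 2L
    for (j in seq_len(nt)) {
      rel <- st - align_times[j]
      rel <- rel[rel >= edges[1] & rel < edges[nb + 1]]
      if (length(rel) == 0) next
      counts <- tabulate(findInterval(rel, edges), nbins = nb)
      padded <- c(numeric(h), counts / bw, numeric(h))
      sm <- stats::convolve(padded, rev(kern), type = "filter")
      rates[u, , j] <- sm
    }
  }
  structure(list(rates = rates, bins = centers,
                 unit_ids = vapply(spikes$units, `[[`, "", "unit_id"),
                 alignment = alignment, window_s = window_s,
                 sigma_s = sigmas, trial_ids = trial_ids),
            class = "rate_tensor")
}

#' Trial-averaged unit-by-time rate matrix
#'
#' Averages a [estimate_rates()] tensor over trials, yielding the N x M
#' matrix entering the population PCA.
#'
#' @param tensor a `"rate_tensor"`.
#' @return units x bins matrix (Hz) with unit ids as row names.
#' @export
trial_average <- function(tensor) {
  m <- apply(tensor$rates, c(1, 2), mean)
  rownames(m) <- tensor$unit_ids
  m
}

#' Event modulation index per unit
#'
#' Compares each unit's firing in the `pre_s` seconds before and `post_s`
#' seconds after an event (cue onset or sipper entry) across trials. The
#' index is `(post - pre) / (post + pre)` on trial-pooled mean rates, in
#' \[-1, 1\]; significance is a paired Wilcoxon signed-rank test across
#' trials at `alpha`. Units with no spikes in either window are flagged
#' untested.
#'
#' @param spikes a `"spike_data"`.
#' @param schedule a `"task_schedule"`.
#' @param event `"cue_on"` or `"sipper_in"`.
#' @param pre_s,post_s window lengths in seconds (default 1 each).
#' @param alpha significance level (default 0.05).
#' @return A list with `units` (data frame: `unit_id`, `index`, `p_value`,
#'   `significant`, `sign`, `tested`) and summary proportions
#'   `prop_positive` / `prop_negative` of significantly modulated units.
#' @export
modulation_index <- function(spikes, schedule,
                             event = c("cue_on", "sipper_in"),
                             pre_s = 1, post_s = 1, alpha = 0.05) {
  event <- match.arg(event)
  if (pre_s <= 0 || post_s <= 0) stop("pre_s and post_s must be positive")
  tr <- schedule$trials
  times <- if (event == "cue_on") tr$cue_on else
    tr$sipper_in[tr$cs_type == "CS+"]
  times <- times[!is.na(times)]
  rows <- lapply(spikes$units, function(u) {
    st <- u$spike_times
    pre <- vapply(times, function(t0)
      sum(st >= t0 - pre_s & st < t0) / pre_s, 0)
    post <- vapply(times, function(t0)
      sum(st >= t0 & st < t0 + post_s) / post_s, 0)
    r_pre <- mean(pre); r_post <- mean(post)
    if (r_pre + r_post == 0)
      return(data.frame(unit_id = u$unit_id, index = NA_real_,
                        p_value = NA_real_, significant = FALSE,
                        sign = NA_character_, tested = FALSE))
    idx <- (r_post - r_pre) / (r_post + r_pre)
    p <- if (all(post == pre)) 1 else
      suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                          exact = FALSE)$p.value)
    data.frame(unit_id = u$unit_id, index = idx, p_value = p,
               significant = p < alpha,
               sign = if (idx > 0) "positive" else if (idx < 0)
                 "negative" else "zero",
               tested = TRUE)
  })
  units <- do.call(rbind, rows)
  n_tested <- sum(units$tested)
  list(units = units,
       prop_positive = sum(units$significant & units$sign == "positive",
                           na.rm = TRUE) / max(n_tested, 1),
       prop_negative = sum(units$significant & units$sign == "negative",
                           na.rm = TRUE) / max(n_tested, 1))
}
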