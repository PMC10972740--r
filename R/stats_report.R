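#' Compare per-condition subspace distance distributions
#'
#' Rank-based omnibus test (Kruskal-Wallis) across the conditions'
#' subspace mean distances, followed by Tukey-Kramer pairwise comparisons
#' (Tukey's HSD on the unequal-n one-way layout) with confidence bounds.
#'
#' @param distances named list of numeric vectors, one per condition
#'   (each the per-subspace mean distances of [permutation_distance()]).
#' @return An object of class `"group_comparison"`: list with
#'   `statistic`, `df`, `p_value`, `post_hoc` (data frame of pairwise
#'   contrasts with confidence bounds and adjusted p), `correction`.
#' @export
compare_distance_distributions <- function(distances) {
  if (length(distances) < 2)
    stop("need at least 2 groups")
  if (any(vapply(distances, length, 0L) < 3))
    stop("each group needs at least 3 values")
  flagged <- vapply(distances, function(x) stats::var(x) == 0, TRUE)
  if (any(flagged))
    message("compare_distance_distributions: constant group(s): ",
            paste(names(distances)[flagged], collapse = ", "))
  g <- factor(rep(names(distances), vapply(distances, length, 0L)),
              levels = names(distances))
  x <- unlist(distances, use.names = FALSE)
  kw <- stats::kruskal.test(x, g)
  post <- NULL
  if (stats::var(x) > 0) {
    tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
    post <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(statistic = unname(kw$statistic),
                 statistic_name = "Kruskal-Wallis chi-squared",
                 df = unname(kw$parameter), p_value = kw$p.value,
                 post_hoc = post, correction = "TukeyKramer",
                 constant_groups = names(distances)[flagged]),
            class = "group_comparison")
}

#' Per-trial outcome-proportion tests with FDR correction
#'
#' For each of the first `n_trials` CS+ trial positions, compares the
#' outcome counts (correct / incorrect / omission) between the two
#' session types with a chi-squared test on the 2 x 3 table, falling back
#' to Fisher's exact test when any expected cell is below 1.
#' Benjamini-Hochberg correction is applied across trials.
#'
#' @param counts_congruent,counts_incongruent matrices (trials x 3
#'   outcome columns) of per-trial outcome counts across sessions.
#' @param n_trials number of trial positions analysed (default 15).
#' @param alpha significance level on the adjusted p-values.
#' @return Data frame: `trial`, `p_raw`, `p_fdr`, `significant`, `exact`
#'   (whether the exact fallback was used).
#' @export
proportions_over_trials <- function(counts_congruent, counts_incongruent,
                                    n_trials = 15, alpha = 0.05) {
  n_trials <- min(n_trials, nrow(counts_congruent),
                  nrow(counts_incongruent))
  p_raw <- numeric(n_trials)
  exact <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    tab <- rbind(counts_congruent[t, ], counts_incongruent[t, ])
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
      p_raw[t] <- 1
      next
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expd < 1)) {
      exact[t] <- TRUE
      message("proportions_over_trials: expected cell < 1 at trial ", t,
              "; using Fisher's exact test")
      p_raw[t] <- stats::fisher.test(tab)$p.value
    } else {
      p_raw[t] <- suppressWarnings(stats::chisq.test(tab)$p.value)
    }
  }
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  data.frame(trial = seq_len(n_trials), p_raw = p_raw, p_fdr = p_fdr,
             significant = p_fdr < alpha, exact = exact)
}

#' Latency ~ distance regression with session-type interaction
#'
#' Fits `Latency ~ Distance + Session + Distance:Session` over sessions
#' (Session coded 0 = congruent, 1 = incongruent) and reports the
#' coefficient table, R-squared and overall F, plus the Pearson
#' correlation between latency and distance within each session type.
#'
#' @param data data frame with columns `latency`, `distance`,
#'   `session_type` (`"congruent"`/`"incongruent"`).
#' @return A list with `coefficients` (data frame: term, estimate, p),
#'   `r_squared`, `f_statistic`, `f_p_value`, and `correlations` (per
#'   session type: `r`, `p`).
#' @export
latency_distance_regression <- function(data) {
  need <- c("latency", "distance", "session_type")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  for (st in unique(data$session_type)) {
    if (sum(data$session_type == st) < 3)
      stop("need at least 3 sessions per session type; '", st,
           "' has fewer")
  }
  if (stats::var(data$distance) == 0)
    stop("zero variance in the distance predictor")
  data$session <- as.numeric(data$session_type == "incongruent")
  fit <- stats::lm(latency ~ distance * session, data = data)
  sm <- summary(fit)
  co <- stats::coef(sm)
  coefficients <- data.frame(term = rownames(co),
                             estimate = co[, "Estimate"],
                             p_value = co[, "Pr(>|t|)"],
                             row.names = NULL)
  corrs <- lapply(split(data, data$session_type), function(d) {
    if (nrow(d) < 3 || stats::var(d$distance) == 0 ||
        stats::var(d$latency) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(d$distance, d$latency)
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  f <- sm$fstatistic
  list(coefficients = coefficients, r_squared = sm$r.squared,
       f_statistic = unname(f["value"]),
       f_p_value = if (is.null(f)) NA_real_ else
         unname(stats::pf(f["value"], f["numdf"], f["dendf"],
                          lower.tail = FALSE)),
       correlations = corrs, fit = fit)
}

#' Omnibus behavioral comparisons across sessions
#'
#' Per-metric two-way ANOVA (strain x session type) with Tukey HSD post
#' hocs, and a per-strain multivariate omnibus (MANOVA) over the metric
#' vector. Collinear or constant metrics are dropped with a warning
#' before the multivariate test.
#'
#' @param metrics data frame with columns `strain`, `session_type` and
#'   one numeric column per behavioral metric.
#' @return A list with `per_metric` (named list of ANOVA tables +
#'   TukeyHSD) and `manova_by_strain` (per strain: approximate F, df,
#'   p-value, metrics used).
#' @export
omnibus_behavior_tests <- function(metrics) {
  meta <- c("strain", "session_type")
  if (!all(meta %in% names(metrics)))
    stop("metrics must carry strain and session_type columns")
  vars <- setdiff(names(metrics), meta)
  metrics$strain <- factor(metrics$strain)
  metrics$session_type <- factor(metrics$session_type)
  per_metric <- lapply(vars, function(v) {
    fit <- stats::aov(stats::reformulate(c("strain", "session_type"),
                                         response = v), data = metrics)
    list(anova = summary(fit)[[1]],
         tukey = stats::TukeyHSD(fit))
  })
  names(per_metric) <- vars
  manova_by_strain <- lapply(split(metrics, metrics$strain), function(d) {
    use <- vars[vapply(vars, function(v) stats::var(d[[v]]) > 0, TRUE)]
    dropped <- setdiff(vars, use)
    y <- as.matrix(d[, use, drop = FALSE])
    # drop collinear columns until the covariance is nonsingular
    while (ncol(y) > 1 && qr(stats::cov(y))$rank < ncol(y)) {
      dropped <- c(dropped, colnames(y)[ncol(y)])
      y <- y[, -ncol(y), drop = FALSE]
    }
    if (length(dropped) > 0)
      warning("omnibus_behavior_tests: dropped collinear/constant ",
              "metric(s): ", paste(dropped, collapse = ", "),
              call. = FALSE)
    fit <- stats::manova(y ~ session_type, data = d)
    sm <- summary(fit)$stats
    list(f = sm["session_type", "approx F"],
         df = sm["session_type", c("num Df", "den Df")],
         p_value = sm["session_type", "Pr(>F)"],
         metrics_used = colnames(y))
  })
  list(per_metric = per_metric, manova_by_strain = manova_by_strain)
}

#' Repeated-measures time-by-side interaction screen
#'
#' For each component's sign-group mean rate traces, runs a
#' repeated-measures ANOVA (subject as the error stratum, side and time
#' as within factors) and extracts the main-effect and time-by-side
#' interaction p-values. The design must be balanced (every subject
#' measured on both sides at every time point).
#'
#' @param traces data frame with columns `component`, `subject`, `side`
#'   (`"left"`/`"right"`), `time` (bin index or seconds) and `rate`.
#' @return Data frame: `component`, `p_side`, `p_time`, `p_interaction`.
#' @export
interaction_screen <- function(traces) {
  need <- c("component", "subject", "side", "time", "rate")
  if (!all(need %in% names(traces)))
    stop("traces must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(traces, traces$component), function(d) {
    tab <- table(d$subject, d$side, d$time)
    if (any(tab != 1))
      stop("unbalanced design for component ", d$component[1],
           ": every subject needs one value per side and time")
    d$subject <- factor(d$subject)
    d$side <- factor(d$side)
    d$time <- factor(d$time)
    fit <- stats::aov(rate ~ side * time + Error(subject / (side * time)),
                      data = d)
    sm <- summary(fit)
    pick <- function(stratum, term) {
      tb <- sm[[stratum]][[1]]
      rn <- trimws(rownames(tb))
      tb[match(term, rn), "Pr(>F)"]
    }
    data.frame(component = d$component[1],
               p_side = pick("Error: subject:side", "side"),
               p_time = pick("Error: subject:time", "time"),
               p_interaction = pick("Error: subject:side:time",
                                    "side:time"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$component), ]
}
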