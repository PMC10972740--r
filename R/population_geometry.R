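#' Broken-stick component-retention thresholds
#'
#' Expected explained-variance fractions under random partitioning of
#' total variance among `p` components: `b_k = (1/p) * sum_{i=k..p} 1/i`.
#' A component is worth retaining only if its observed explained fraction
#' exceeds its threshold; for `p = 7` the first component must exceed 37%.
#'
#' @param p total number of components (>= 1).
#' @return An object of class `"broken_stick"`: list with `p` and
#'   `thresholds` (length `p`, strictly decreasing, summing to 1).
#' @export
broken_stick <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p != round(p))
    stop("p must be a positive integer")
  inv <- 1 / seq_len(p)
  b <- rev(cumsum(rev(inv))) / p
  structure(list(p = as.integer(p), thresholds = b),
            class = "broken_stick")
}

#' Number of components to retain under the broken stick
#'
#' Returns the largest `K` such that the observed explained fraction
#' exceeds the broken-stick threshold for every component up to `K`
#' (retention stops at the first component that fails).
#'
#' @param explained_fraction observed explained-variance fractions, in
#'   component order.
#' @param stick a [broken_stick()] of matching length (longer sticks are
#'   truncated; shorter is an error).
#' @return Integer retained-component count (possibly 0).
#' @export
retain_components <- function(explained_fraction, stick) {
  b <- stick$thresholds
  n <- length(explained_fraction)
  if (length(b) < n)
    stop("broken stick has fewer thresholds than components")
  ok <- explained_fraction > b[seq_len(n)]
  if (!ok[1]) return(0L)
  fail <- which(!ok)
  if (length(fail) == 0) n else fail[1] - 1L
}

# PCA on a timepoints x units matrix: unit (column) means removed, sign
# fixed so each component's largest-magnitude loading is positive.
pca_core <- function(x) {
  if (all(abs(x - mean(x)) < 1e-12))
    stop("input matrix is constant; PCA is degenerate (zero variance)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coefficients <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  stick <- broken_stick(length(explained))
  structure(list(coefficients = coefficients, scores = scores,
                 explained_fraction = explained,
                 column_means = pc$center,
                 retained = retain_components(explained, stick),
                 stick = stick),
            class = "pca_result")
}

#' Cue-centered population PCA
#'
#' The first PCA strategy: each session contributes a trial-averaged
#' units x bins rate matrix over the cue-centered window (first 15
#' trials); the matrices of one strain's congruent and incongruent
#' sessions are stacked vertically (units pooled), the pooled matrix is
#' mean-centered per unit and decomposed with units as variables, and the
#' broken stick decides how many components are kept.
#'
#' @param session_matrices list of units x bins matrices (e.g. from
#'   [trial_average()]) sharing one bin grid.
#' @return A `"pca_result"`: `coefficients` (units x components, unit
#'   loadings), `scores` (bins x components, time courses),
#'   `explained_fraction`, `column_means` (per-unit means removed),
#'   `retained`.
#' @export
cue_centered_pca <- function(session_matrices) {
  nb <- unique(vapply(session_matrices, ncol, 0L))
  if (length(nb) != 1)
    stop("sessions have inconsistent bin grids: ",
         paste(vapply(session_matrices, ncol, 0L), collapse = ", "))
  stacked <- do.call(rbind, session_matrices)  # (pooled units) x bins
  pca_core(t(stacked))
}

#' Side-concatenated population PCA
#'
#' The second PCA strategy, for left/right encoding: per condition the
#' left-trial mean and right-trial mean (units x bins, approach-centered)
#' are concatenated in time (left half then right half, doubling the time
#' dimension); conditions within a session type are stacked vertically
#' (units pooled) and decomposed as in [cue_centered_pca()]. Scores are
#' split back into the left and right halves.
#'
#' @param left_matrices,right_matrices lists (one element per condition)
#'   of units x bins mean-rate matrices, row-aligned between the two
#'   lists.
#' @param approach_index bin index of the approach within the window
#'   (defaults to the midpoint).
#' @return A list with `pca` (a `"pca_result"` over the concatenated
#'   matrix) and `projection` (class `"side_projection"`: `left_scores`
#'   and `right_scores`, bins x components, plus `approach_index`).
#' @export
side_concatenated_pca <- function(left_matrices, right_matrices,
                                  approach_index = NULL) {
  if (length(left_matrices) != length(right_matrices))
    stop("left and right condition lists differ in length")
  for (i in seq_along(left_matrices)) {
    if (is.null(left_matrices[[i]]) || nrow(left_matrices[[i]]) == 0)
      stop("condition ", i, " has no left-trial data")
    if (is.null(right_matrices[[i]]) || nrow(right_matrices[[i]]) == 0)
      stop("condition ", i, " has no right-trial data")
    if (!identical(dim(left_matrices[[i]]), dim(right_matrices[[i]])))
      stop("condition ", i, ": left and right matrices differ in shape")
  }
  lr <- mapply(function(l, r) cbind(l, r), left_matrices, right_matrices,
               SIMPLIFY = FALSE)
  stacked <- do.call(rbind, lr)  # units x 2M
  m <- ncol(left_matrices[[1]])
  pca <- pca_core(t(stacked))
  if (is.null(approach_index)) approach_index <- (m + 1) %/% 2
  proj <- structure(list(left_scores = pca$scores[seq_len(m), , drop = FALSE],
                         right_scores = pca$scores[m + seq_len(m), ,
                                                   drop = FALSE],
                         approach_index = approach_index),
                    class = "side_projection")
  list(pca = pca, projection = proj)
}

#' Project single trials into a fitted PC space
#'
#' Maps each single-trial units x bins rate matrix into the score space of
#' a fitted PCA: the PCA's per-unit column means are subtracted and the
#' centered matrix is multiplied by the coefficient loadings (the standard
#' score map).
#'
#' @param pca a `"pca_result"` fitted on matching units (row order must
#'   agree).
#' @param trial_matrices list of units x bins single-trial matrices.
#' @param components which components to keep (default all retained, or
#'   all if none retained).
#' @return List of bins x components score matrices, one per trial.
#' @export
project_trials <- function(pca, trial_matrices, components = NULL) {
  if (is.null(components)) {
    k <- if (pca$retained > 0) pca$retained else ncol(pca$coefficients)
    components <- seq_len(k)
  }
  lapply(trial_matrices, function(m) {
    x <- t(m)  # bins x units
    xc <- sweep(x, 2, pca$column_means, `-`)
    xc %*% pca$coefficients[, components, drop = FALSE]
  })
}

#' Enumerate 3-component subspaces
#'
#' All unordered `k`-element subsets of the first `n` component indices,
#' in lexicographic order: `choose(n, k)` subspaces (84 for `n = 9`, 56
#' for `n = 8` at the default `k = 3`).
#'
#' @param n number of retained components (>= k).
#' @param k subspace dimensionality (default 3).
#' @return List of integer index vectors.
#' @export
subspace_permutations <- function(n, k = 3) {
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  cmb <- utils::combn(n, k)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

#' Bootstrap left/right subspace distance statistic
#'
#' For each enumerated 3-component subspace, `n_bootstrap` (left, right)
#' single-trial pairs are drawn with replacement from the two trial
#' pools; the Euclidean distance between the paired trials' subspace
#' trajectories is taken at each time sample (restricted to bins strictly
#' before the approach when `pre_approach_only`) and averaged over samples
#' and pairs, giving one mean separation per subspace.
#'
#' @param left_scores,right_scores lists of bins x components single-trial
#'   score matrices (from [project_trials()]); columns index the retained
#'   components that `subspaces` refer to.
#' @param subspaces list of component-index triples
#'   ([subspace_permutations()]).
#' @param n_bootstrap number of trial pairs (default 1000).
#' @param pre_approach_only restrict to bins before `approach_index`.
#' @param approach_index bin index of the approach (defaults to the
#'   window midpoint).
#' @param seed integer seed for the bootstrap draws.
#' @return An object of class `"perm_distance"`: list with `subspaces`,
#'   `mean_distance` (one value per subspace), `n_bootstrap`,
#'   `pre_approach_only`.
#' @export
permutation_distance <- function(left_scores, right_scores, subspaces,
                                 n_bootstrap = 1000,
                                 pre_approach_only = TRUE,
                                 approach_index = NULL, seed = 1) {
  nl <- length(left_scores); nr <- length(right_scores)
  if (nl == 0 || nr == 0)
    stop("empty trial pool: ", nl, " left, ", nr, " right")
  nb <- nrow(left_scores[[1]])
  if (is.null(approach_index)) approach_index <- (nb + 1) %/% 2
  bins <- if (pre_approach_only) seq_len(approach_index - 1) else
    seq_len(nb)
  set.seed(seed)
  li <- sample.int(nl, n_bootstrap, replace = TRUE)
  ri <- sample.int(nr, n_bootstrap, replace = TRUE)
  # stack pools once: bins x comps x trials
  la <- simplify2array(left_scores)
  ra <- simplify2array(right_scores)
  md <- vapply(subspaces, function(ss) {
    dl <- la[bins, ss, li, drop = FALSE] - ra[bins, ss, ri, drop = FALSE]
    mean(sqrt(apply(dl^2, c(1, 3), sum)))
  }, 0)
  structure(list(subspaces = subspaces, mean_distance = md,
                 n_bootstrap = n_bootstrap,
                 pre_approach_only = pre_approach_only,
                 approach_index = approach_index),
            class = "perm_distance")
}

#' Split units by loading sign on one component
#'
#' Partitions units into positive loaders (loading at or above
#' `threshold`), negative loaders (at or below `-threshold`) and an
#' excluded middle band that is not analysed (the published threshold is
#' 0.01).
#'
#' @param pca a `"pca_result"`.
#' @param component component index (must not exceed the number of
#'   computed components).
#' @param threshold absolute loading cut (default 0.01).
#' @return A list with integer unit-index vectors `positive`, `negative`,
#'   `excluded`.
#' @export
split_by_loading <- function(pca, component, threshold = 0.01) {
  if (component > ncol(pca$coefficients))
    stop("component ", component, " exceeds the decomposition size")
  l <- pca$coefficients[, component]
  list(positive = which(l >= threshold),
       negative = which(l <= -threshold),
       excluded = which(abs(l) < threshold))
}

#' Pre/post-approach left-right rate difference per sign group
#'
#' For each loading-sign group, averages the group's mean rate trace per
#' side, forms `diff(t) = left(t) - right(t)`, and averages it over the
#' bins before and after the approach. Positive values mean the group's
#' activity is skewed toward encoding the left side.
#'
#' @param split a [split_by_loading()] result.
#' @param left_rates,right_rates units x bins mean-rate matrices over the
#'   approach window (rows aligned with the PCA's units).
#' @param approach_index bin index of the approach (excluded from both
#'   halves).
#' @return A data frame with one row per sign group: `group`, `n_units`,
#'   `pre_diff`, `post_diff` (Hz; NA and flagged when a group is empty).
#' @export
prepost_side_difference <- function(split, left_rates, right_rates,
                                    approach_index) {
  nb <- ncol(left_rates)
  pre <- seq_len(approach_index - 1)
  post <- (approach_index + 1):nb
  one <- function(idx, name) {
    if (length(idx) == 0)
      return(data.frame(group = name, n_units = 0L, pre_diff = NA_real_,
                        post_diff = NA_real_, flagged = TRUE))
    d <- colMeans(left_rates[idx, , drop = FALSE]) -
      colMeans(right_rates[idx, , drop = FALSE])
    data.frame(group = name, n_units = length(idx),
               pre_diff = mean(d[pre]), post_diff = mean(d[post]),
               flagged = FALSE)
  }
  rbind(one(split$positive, "positive"), one(split$negative, "negative"))
}

#' Select the component with a time-by-side interaction in both session
#' types
#'
#' Given per-component interaction screens (from [interaction_screen()])
#' for the two session types, returns the component(s) whose time-by-side
#' interaction is significant in both. Several qualifying components are
#' all returned (no silent tie-break); none yields an empty result.
#'
#' @param screen_congruent,screen_incongruent data frames with columns
#'   `component` and `p_interaction`.
#' @param alpha significance level (default 0.05).
#' @return Integer vector of qualifying component indices (possibly
#'   empty).
#' @export
select_interaction_pc <- function(screen_congruent, screen_incongruent,
                                  alpha = 0.05) {
  sig_c <- screen_congruent$component[
    screen_congruent$p_interaction < alpha]
  sig_i <- screen_incongruent$component[
    screen_incongruent$p_interaction < alpha]
  out <- sort(intersect(sig_c, sig_i))
  if (length(out) == 0)
    message("select_interaction_pc: no component is significant in both ",
            "session types")
  as.integer(out)
}
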