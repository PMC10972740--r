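# Left/right encoding: side-concatenated PCA, subspace permutation
# distances, loading splits with pre/post differences, and the
# interaction screen.
#
# Each session is analysed end to end (side_encoding_analysis); the
# per-subspace distance distributions (84 subspaces over 9 components)
# are compared across the four strain-by-session-type conditions with a
# Kruskal-Wallis omnibus and Tukey-Kramer post hocs.

source("analysis/00_common.R")

cfg <- twocap_config()
res_by_id <- list()
for (i in seq_len(nrow(cohort))) {
  row <- cohort[i, ]
  s <- get_session(row)
  res_by_id[[row$id]] <- suppressMessages(
    side_encoding_analysis(s, cfg, seed = row$seed, n_components = 9))
}

# per-condition distance distributions: pool subspace means over the
# condition's sessions
cond <- interaction(cohort$strain, cohort$session_type, sep = "_")
dists <- lapply(split(cohort$id, cond), function(ids)
  unlist(lapply(ids, function(id)
    res_by_id[[id]]$distance$mean_distance)))
cmp <- compare_distance_distributions(dists)
cat(sprintf("Kruskal-Wallis over conditions: chi-sq = %.2f, p = %.2g\n",
            cmp$statistic, cmp$p_value))
print(cmp$post_hoc[order(cmp$post_hoc$p_adj), ][1:4, ])
write_results(structure(list(
  condition_means = vapply(dists, mean, 0),
  omnibus_chisq = cmp$statistic, omnibus_p = cmp$p_value),
  class = "list"), "results/05_distance_comparison.json")

# pre/post side differences per loading-sign group, summarized per
# condition on the component with the strongest side signal
pp <- do.call(rbind, lapply(cohort$id, function(id) {
  r <- res_by_id[[id]]
  best <- r$prepost[!r$prepost$flagged, ]
  best <- best[which.max(abs(best$post_diff) + abs(best$pre_diff)), ]
  cbind(cohort[cohort$id == id, c("id", "strain", "session_type")],
        best)
}))
write.csv(pp, "results/05_prepost_differences.csv", row.names = FALSE)
cat("\n|left - right| rate differences (Hz), condition means:\n")
print(aggregate(cbind(abs_pre = abs(pre_diff),
                      abs_post = abs(post_diff)) ~
                  strain + session_type, pp, mean))
cat("Proactive (Wistar) sessions separate sides before the approach;",
    "\nreactive (P rat) sessions after it.\n")

# interaction screen on the pooled session-type PCA: sessions of one
# session type share one decomposition, so component indices are
# comparable across sessions; each sign group's session-level mean
# traces enter the repeated-measures screen, and a component counts as
# interacting if either sign group shows the time-by-side interaction
screen_for <- function(stype) {
  ids <- cohort$id[cohort$session_type == stype]
  lmats <- lapply(ids, function(id) res_by_id[[id]]$left_mean)
  rmats <- lapply(ids, function(id) res_by_id[[id]]$right_mean)
  fit <- side_concatenated_pca(lmats, rmats)
  offsets <- c(0, cumsum(vapply(lmats, nrow, 0L)))
  nb <- ncol(lmats[[1]])
  keep <- seq(1, nb, by = 4)  # thin time for the RANOVA
  screen_group <- function(group) {
    traces <- do.call(rbind, lapply(1:6, function(pc) {
      sp <- split_by_loading(fit$pca, pc, cfg$loading_threshold)
      do.call(rbind, lapply(seq_along(ids), function(k) {
        idx <- sp[[group]]
        idx <- idx[idx > offsets[k] & idx <= offsets[k + 1]] - offsets[k]
        if (length(idx) == 0) return(NULL)
        data.frame(component = pc, subject = ids[k],
                   side = rep(c("left", "right"), each = length(keep)),
                   time = rep(keep, 2),
                   rate = c(colMeans(lmats[[k]][idx, keep, drop = FALSE]),
                            colMeans(rmats[[k]][idx, keep, drop = FALSE])))
      }))
    }))
    interaction_screen(traces)
  }
  pos <- screen_group("positive"); neg <- screen_group("negative")
  merged <- merge(pos, neg, by = "component",
                  suffixes = c("_pos", "_neg"))
  data.frame(component = merged$component,
             p_interaction = pmin(merged$p_interaction_pos,
                                  merged$p_interaction_neg))
}
sc <- screen_for("congruent"); si <- screen_for("incongruent")
pick <- select_interaction_pc(sc, si)
cat("\nComponents with a time-by-side interaction in both session",
    "types:", if (length(pick)) paste(pick, collapse = ", ") else
      "(none)", "\n")
write.csv(rbind(cbind(sc, session_type = "congruent"),
                cbind(si, session_type = "incongruent")),
          "results/05_interaction_screen.csv", row.names = FALSE)
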