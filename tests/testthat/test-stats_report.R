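test_that("distance-distribution omnibus behaves at the null and under
           shift", {
  set.seed(20)
  null_groups <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20),
                      d = rnorm(20))
  g0 <- compare_distance_distributions(null_groups)
  expect_gt(g0$p_value, 0.05)
  # identical values in all groups: flagged, non-significant
  same <- lapply(1:4, function(i) rep(1, 5))
  names(same) <- letters[1:4]
  expect_message(gs <- compare_distance_distributions(same), "constant")
  expect_false(isTRUE(gs$p_value < 0.05))

  shifted <- null_groups
  shifted$d <- shifted$d + 5
  g1 <- compare_distance_distributions(shifted)
  expect_lt(g1$p_value, 0.001)
  d_contrasts <- grepl("d", g1$post_hoc$contrast)
  expect_true(all(g1$post_hoc$p_adj[d_contrasts] < 0.05))
  expect_true(all(g1$post_hoc$p_adj[!d_contrasts] > 0.05))

  # two groups: reduces to the two-sample rank test
  two <- list(a = rnorm(15), b = rnorm(15, 1))
  g2 <- compare_distance_distributions(two)
  w <- wilcox.test(two$a, two$b, exact = FALSE, correct = FALSE)
  expect_equal(g2$p_value, w$p.value, tolerance = 1e-10)

  expect_error(compare_distance_distributions(list(a = 1:5)), "2 groups")
  expect_error(compare_distance_distributions(list(a = 1:5, b = 1:2)),
               "at least 3 values")
})

test_that("per-trial proportion tests apply FDR and the exact fallback", {
  # identical counts: nothing significant
  cc <- matrix(10, 15, 3, dimnames = list(NULL, c("correct", "incorrect",
                                                  "omission")))
  res0 <- proportions_over_trials(cc, cc)
  expect_true(all(!res0$significant))
  # one extreme trial
  ci <- cc
  cc1 <- cc; cc1[1, ] <- c(15, 0, 0)
  ci1 <- cc; ci1[1, ] <- c(0, 15, 0)
  res1 <- suppressMessages(proportions_over_trials(cc1, ci1))
  expect_true(res1$significant[1])
  expect_true(all(!res1$significant[-1]))
  # FDR never decreases p and preserves order
  expect_true(all(res1$p_fdr >= res1$p_raw - 1e-15))
  ord <- order(res1$p_raw)
  expect_true(all(diff(res1$p_fdr[ord]) >= -1e-15))
  # sparse table triggers the exact fallback
  cs <- matrix(c(1, 0, 0), 1, 3, byrow = TRUE)
  ci2 <- matrix(c(0, 1, 0), 1, 3, byrow = TRUE)
  expect_message(proportions_over_trials(cs, ci2, n_trials = 1),
                 "exact")
})

test_that("the latency-distance regression recovers exact and
           interaction-only structures", {
  # exact fit within one session type
  d <- data.frame(distance = 1:6, latency = 2 * (1:6),
                  session_type = rep(c("congruent", "incongruent"), 3))
  d$latency <- 2 * d$distance  # both types on the same exact line
  fit <- suppressWarnings(latency_distance_regression(d))
  slope <- fit$coefficients$estimate[fit$coefficients$term == "distance"]
  expect_equal(slope, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$correlations$congruent$r, 1, tolerance = 1e-9)

  # latency independent of distance: slope CI covers 0
  set.seed(21)
  d2 <- data.frame(distance = runif(40), latency = rnorm(40),
                   session_type = rep(c("congruent", "incongruent"), 20))
  fit2 <- latency_distance_regression(d2)
  ci <- stats::confint(fit2$fit)["distance", ]
  expect_true(ci[1] < 0 && ci[2] > 0)

  # interaction-only structure: opposite slopes by session type
  set.seed(22)
  x <- runif(30)
  d3 <- rbind(
    data.frame(distance = x, latency = -1 * x + rnorm(30, sd = 0.05),
               session_type = "congruent"),
    data.frame(distance = x, latency = 1 * x + rnorm(30, sd = 0.05),
               session_type = "incongruent"))
  fit3 <- latency_distance_regression(d3)
  co <- fit3$coefficients
  expect_lt(co$p_value[co$term == "distance:session"], 0.001)
  expect_lt(fit3$correlations$congruent$r, 0)
  expect_gt(fit3$correlations$incongruent$r, 0)

  expect_error(latency_distance_regression(
    data.frame(distance = rep(1, 8), latency = rnorm(8),
               session_type = rep(c("congruent", "incongruent"), 4))),
    "zero variance")
})

test_that("behavioral omnibus detects shifts and tolerates dropped
           metrics", {
  set.seed(23)
  base <- function(n, strain, stype, shift = 0)
    data.frame(strain = strain, session_type = stype,
               m1 = rnorm(n) + shift, m2 = rnorm(n) + shift,
               m3 = rnorm(n) + shift)
  null_d <- rbind(base(10, "wistar", "congruent"),
                  base(10, "wistar", "incongruent"),
                  base(10, "prat", "congruent"),
                  base(10, "prat", "incongruent"))
  r0 <- omnibus_behavior_tests(null_d)
  expect_gt(r0$manova_by_strain$wistar$p_value, 0.05)
  expect_gt(r0$manova_by_strain$prat$p_value, 0.05)

  shift_d <- rbind(base(10, "wistar", "congruent"),
                   base(10, "wistar", "incongruent", shift = 3),
                   base(10, "prat", "congruent"),
                   base(10, "prat", "incongruent"))
  r1 <- omnibus_behavior_tests(shift_d)
  expect_lt(r1$manova_by_strain$wistar$p_value, 0.001)
  expect_gt(r1$manova_by_strain$prat$p_value, 0.05)
  expect_lt(r1$per_metric$m1$anova["session_type", "Pr(>F)"], 0.05)

  # a constant metric is dropped with a warning, others unchanged
  shift_d$m4 <- 1
  # the constant metric is reported once per strain stratum
  expect_warning(expect_warning(r2 <- omnibus_behavior_tests(shift_d),
                                "m4"), "m4")
  expect_equal(r2$manova_by_strain$wistar$p_value,
               r1$manova_by_strain$wistar$p_value, tolerance = 1e-12)
})

test_that("the repeated-measures screen isolates time-by-side
           interactions", {
  mk <- function(component, f) {
    g <- expand.grid(subject = paste0("s", 1:6), side = c("left", "right"),
                     time = 1:8)
    g$component <- component
    g$rate <- f(g) + rnorm(nrow(g), sd = 0.3)
    g
  }
  set.seed(24)
  traces <- rbind(
    mk(1, function(g) 0),                                    # null
    mk(2, function(g) ifelse(g$time > 4 & g$side == "left", 3, 0)),
    mk(3, function(g) as.numeric(g$time)))                   # time ramp
  out <- interaction_screen(traces)
  expect_gt(out$p_interaction[out$component == 1], 0.05)
  expect_lt(out$p_interaction[out$component == 2], 0.01)
  expect_lt(out$p_time[out$component == 3], 0.001)
  expect_gt(out$p_interaction[out$component == 3], 0.05)
  # unbalanced design is an error
  bad <- mk(1, function(g) 0)[-1, ]
  expect_error(interaction_screen(bad), "unbalanced")
})
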