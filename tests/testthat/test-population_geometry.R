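test_that("broken-stick thresholds match the closed form", {
  bs7 <- broken_stick(7)
  expect_equal(bs7$thresholds[1], sum(1 / (1:7)) / 7, tolerance = 1e-12)
  expect_equal(round(100 * bs7$thresholds[1]), 37)
  bs3 <- broken_stick(3)
  expect_equal(bs3$thresholds, c(11 / 18, 5 / 18, 2 / 18),
               tolerance = 1e-12)
  expect_equal(broken_stick(1)$thresholds, 1)
  expect_error(broken_stick(0), "positive integer")
  # strictly decreasing, sums to 1, for a sweep of p
  for (p in c(2, 5, 9, 40, 221)) {
    b <- broken_stick(p)$thresholds
    expect_true(all(diff(b) < 0))
    expect_equal(sum(b), 1, tolerance = 1e-12)
  }
})

test_that("retention keeps components until the first broken-stick failure", {
  stick <- broken_stick(7)
  expect_gte(retain_components(c(0.5, 0.3, 0.1, 0.05, 0.03, 0.01, 0.01),
                               stick), 2)
  # 0.5 > 0.3704 and 0.3 > 0.2276, but 0.1 < 0.1561 stops retention
  expect_identical(retain_components(c(0.5, 0.3, 0.1, 0.05, 0.03, 0.01,
                                       0.01), stick), 2L)
  expect_identical(retain_components(rep(1 / 7, 7), stick), 0L)
  expect_identical(retain_components(c(1, rep(0, 6)), stick), 1L)
})

test_that("PCA satisfies the reconstruction identity and norm conventions", {
  set.seed(10)
  x <- matrix(rnorm(40 * 8), 40, 8)  # units x bins
  pca <- cue_centered_pca(list(x[1:25, ], x[26:40, ]))
  rec <- sweep(pca$scores %*% t(pca$coefficients), 2,
               pca$column_means, `+`)
  expect_equal(rec, t(x), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(colSums(pca$coefficients^2) - 1) < 1e-9))
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_fraction), 1 + 1e-9)
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(pca$coefficients))) {
    v <- pca$coefficients[, k]
    expect_gte(v[which.max(abs(v))], 0)
  }
  expect_error(cue_centered_pca(list(matrix(1, 5, 8))), "degenerate")
  expect_error(cue_centered_pca(list(x, x[, 1:4])), "inconsistent bin")
})

test_that("duplicating units leaves explained variance and score shape
           unchanged", {
  set.seed(11)
  x <- matrix(rnorm(20 * 30), 20, 30)
  p1 <- cue_centered_pca(list(x))
  p2 <- cue_centered_pca(list(x, x))
  k <- min(5, ncol(p1$scores))
  expect_equal(p2$explained_fraction[1:k], p1$explained_fraction[1:k],
               tolerance = 1e-8)
  # scores are identical up to the sqrt(2) renormalization of loadings
  for (j in 1:k) {
    expect_equal(abs(stats::cor(p1$scores[, j], p2$scores[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(stats::sd(p2$scores[, j]) / stats::sd(p1$scores[, j]),
                 sqrt(2), tolerance = 1e-8)
  }
})

test_that("a dominant cue-locked unit drives the first component", {
  set.seed(12)
  bins <- twocap:::window_bins(c(-4, 18), 0.1)
  n_units <- 20
  x <- matrix(rnorm(n_units * 221, sd = 0.05), n_units, 221)
  transient <- 5 * exp(-(bins - 0)^2 / (2 * 0.4^2))
  x[1, ] <- x[1, ] + transient
  pca <- cue_centered_pca(list(x))
  expect_gt(pca$explained_fraction[1],
            broken_stick(length(pca$explained_fraction))$thresholds[1])
  expect_gte(pca$retained, 1)
  peak_bin <- which.max(abs(pca$scores[, 1] - mean(pca$scores[, 1])))
  expect_lt(abs(bins[peak_bin]), 0.5)
})

test_that("side-concatenated PCA splits scores back into matching halves", {
  set.seed(13)
  l <- matrix(rnorm(30 * 41), 30, 41)
  # identical halves: identical left and right scores
  fit <- side_concatenated_pca(list(l), list(l))
  expect_equal(fit$projection$left_scores, fit$projection$right_scores,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$projection$approach_index, 21)
  # right = left + constant per unit: score difference constant over time
  shift <- rnorm(30)
  r <- l + shift
  fit2 <- side_concatenated_pca(list(l), list(r))
  d <- fit2$projection$left_scores - fit2$projection$right_scores
  for (k in seq_len(min(3, ncol(d))))
    expect_lt(stats::sd(d[, k]), 1e-8)
  expect_error(side_concatenated_pca(list(l), list(r[, 1:10])),
               "differ in shape")
  expect_error(side_concatenated_pca(list(l), list()), "differ in length")
})

test_that("subspace enumeration matches the binomial coefficient", {
  expect_length(subspace_permutations(9, 3), 84)
  expect_length(subspace_permutations(8, 3), 56)
  expect_identical(subspace_permutations(3, 3), list(1:3))
  expect_error(subspace_permutations(2, 3), "at least")
  for (n in 3:12) {
    for (k in 3:n) {
      subs <- subspace_permutations(n, k)
      expect_length(subs, choose(n, k))
      expect_false(anyDuplicated(subs) > 0)
      expect_true(all(vapply(subs, function(s) all(diff(s) > 0), TRUE)))
    }
  }
  # lexicographic order
  subs <- subspace_permutations(4, 3)
  expect_identical(subs, list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                              c(1L, 3L, 4L), c(2L, 3L, 4L)))
})

test_that("the distance statistic is zero on identical pools and equals
           the offset norm on translated pools", {
  set.seed(14)
  base <- matrix(rnorm(41 * 5), 41, 5)
  subs <- subspace_permutations(5, 3)
  d0 <- permutation_distance(list(base), list(base), subs,
                             n_bootstrap = 100, seed = 1)
  expect_true(all(d0$mean_distance == 0))
  # right = left shifted by +3 on component 2 only
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 3
  d1 <- permutation_distance(list(base), list(shifted), subs,
                             n_bootstrap = 100, seed = 1)
  has2 <- vapply(subs, function(s) 2 %in% s, TRUE)
  expect_equal(d1$mean_distance[has2], rep(3, sum(has2)),
               tolerance = 1e-9)
  expect_equal(d1$mean_distance[!has2], rep(0, sum(!has2)),
               tolerance = 1e-9)
  expect_error(permutation_distance(list(), list(base), subs),
               "empty trial pool")
})

test_that("the distance statistic is seed-reproducible and invariant to
           within-subspace rotation", {
  set.seed(15)
  lpool <- replicate(8, matrix(rnorm(41 * 4), 41, 4), simplify = FALSE)
  rpool <- replicate(6, matrix(rnorm(41 * 4, mean = 0.5), 41, 4),
                     simplify = FALSE)
  subs <- subspace_permutations(4, 3)
  a <- permutation_distance(lpool, rpool, subs, n_bootstrap = 200,
                            seed = 99)
  b <- permutation_distance(lpool, rpool, subs, n_bootstrap = 200,
                            seed = 99)
  expect_identical(a$mean_distance, b$mean_distance)
  # rotate all trials identically within the first subspace
  theta <- 0.7
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta),
                            cos(theta)), 2)
  lrot <- lapply(lpool, function(m) m %*% rot)
  rrot <- lapply(rpool, function(m) m %*% rot)
  c_ <- permutation_distance(lrot, rrot, subs, n_bootstrap = 200,
                             seed = 99)
  expect_equal(c_$mean_distance[1], a$mean_distance[1], tolerance = 1e-9)
})

test_that("loading splits partition by sign with a dead band", {
  pca <- list(coefficients = cbind(c(0.05, -0.02, 0.005)),
              retained = 1L)
  class(pca) <- "pca_result"
  sp <- split_by_loading(pca, 1, threshold = 0.01)
  expect_identical(sp$positive, 1L)
  expect_identical(sp$negative, 2L)
  expect_identical(sp$excluded, 3L)
  # all-zero loadings: everything excluded
  pca0 <- pca; pca0$coefficients <- cbind(c(0, 0, 0))
  sp0 <- split_by_loading(pca0, 1)
  expect_length(sp0$excluded, 3)
  # antisymmetry under sign flip
  pcaf <- pca; pcaf$coefficients <- -pca$coefficients
  spf <- split_by_loading(pcaf, 1)
  expect_identical(spf$positive, sp$negative)
  expect_identical(spf$negative, sp$positive)
  expect_error(split_by_loading(pca, 5), "exceeds")
})

test_that("pre/post side differences follow the left-minus-right sign
           convention", {
  split <- list(positive = 1:2, negative = 3L, excluded = integer(0))
  left <- matrix(5, 3, 41)
  right <- matrix(3, 3, 41)
  pp <- prepost_side_difference(split, left, right, approach_index = 21)
  expect_equal(pp$pre_diff, c(2, 2))
  expect_equal(pp$post_diff, c(2, 2))
  # identical sides: zero
  pp0 <- prepost_side_difference(split, left, left, 21)
  expect_true(all(pp0$pre_diff == 0 & pp0$post_diff == 0))
  # empty group flagged
  split2 <- list(positive = integer(0), negative = 1:3)
  pp2 <- prepost_side_difference(split2, left, right, 21)
  expect_true(pp2$flagged[pp2$group == "positive"])
  expect_true(is.na(pp2$pre_diff[pp2$group == "positive"]))
})

test_that("interaction-component selection intersects session types
           without a silent tie-break", {
  sc <- data.frame(component = 1:5,
                   p_interaction = c(0.5, 0.01, 0.6, 0.02, 0.03))
  si <- data.frame(component = 1:5,
                   p_interaction = c(0.5, 0.6, 0.7, 0.01, 0.02))
  expect_identical(select_interaction_pc(sc, si), c(4L, 5L))
  si2 <- si; si2$p_interaction <- rep(0.9, 5)
  expect_message(out <- select_interaction_pc(sc, si2), "no component")
  expect_length(out, 0)
  # a single qualifying component is returned alone
  sc3 <- data.frame(component = 1:3, p_interaction = c(0.9, 0.01, 0.9))
  si3 <- data.frame(component = 1:3, p_interaction = c(0.9, 0.04, 0.9))
  expect_identical(select_interaction_pc(sc3, si3), 2L)
})

test_that("proactive populations separate left from right before the
           approach; reactive after", {
  pre_s <- cached("pga_pre", {
    s <- generate_session(seed = 31,
                          pop = population_params(
                            side_code_onset = "pre_approach"))
    suppressMessages(side_encoding_analysis(s, seed = 31,
                                            n_components = 9))
  })
  post_s <- cached("pga_post", {
    s <- generate_session(seed = 31,
                          pop = population_params(
                            side_code_onset = "post_approach"))
    suppressMessages(side_encoding_analysis(s, seed = 31,
                                            n_components = 9))
  })
  expect_length(pre_s$distance$mean_distance, 84)
  # pre-approach subspace distances are larger in the proactive regime
  expect_gt(mean(pre_s$distance$mean_distance),
            mean(post_s$distance$mean_distance))
  expect_lt(wilcox.test(pre_s$distance$mean_distance,
                        post_s$distance$mean_distance,
                        alternative = "greater",
                        exact = FALSE)$p.value, 0.01)
  # left/right mean traces diverge before the approach only for the
  # proactive regime
  div <- function(res) {
    d <- abs(colMeans(res$left_mean) - colMeans(res$right_mean))
    ai <- res$projection$approach_index
    c(pre = mean(d[seq_len(ai - 1)]), post = mean(d[(ai + 1):length(d)]))
  }
  dp <- div(pre_s); dr <- div(post_s)
  expect_gt(dp["pre"], dp["post"])
  expect_gt(dr["post"], dr["pre"])
})
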