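test_that("feature-norm generation is deterministic and satisfies invariants", {
  a <- gen_feature_norms(12, 6, 5, cross_corr = 0.4, seed = 42)
  b <- gen_feature_norms(12, 6, 5, cross_corr = 0.4, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$values >= 0))
  expect_true(all(colSums(a$values > 0) >= 2))
  expect_setequal(unique(a$category), c("visual", "semantic"))
  expect_error(gen_feature_norms(12, 6, 5, cross_corr = 2, seed = 1),
               "cross_corr")
  expect_error(gen_feature_norms(12, 6, 5, cross_corr = NaN, seed = 1),
               "cross_corr")
})

test_that("full cross-correlation duplicates the visual similarity structure", {
  norms <- gen_feature_norms(8, 4, 4, cross_corr = 1, seed = 7)
  rv <- build_model_rsm(norms, "visual")
  rs <- build_model_rsm(norms, "semantic")
  expect_equal(max(abs(rv$values - rs$values)), 0)
})

test_that("independent feature blocks give near-zero RSM correlation on average", {
  rhos <- vapply(1:200, function(s) {
    norms <- gen_feature_norms(50, 30, 30, cross_corr = 0, seed = s)
    compare_rsms(build_model_rsm(norms, "visual"),
                 build_model_rsm(norms, "semantic"))$global_rho
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.15)
})

test_that("RSM correlation increases monotonically with the mixing weight", {
  mean_rho <- vapply(c(0, 0.5, 1), function(cc) {
    mean(vapply(1:10, function(s) {
      norms <- gen_feature_norms(30, 15, 15, cross_corr = cc, seed = s)
      compare_rsms(build_model_rsm(norms, "visual"),
                   build_model_rsm(norms, "semantic"))$global_rho
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
  expect_equal(mean_rho[3], 1)
})

test_that("graded responses saturate, center, and reproduce under a seed", {
  theta <- rnorm(50)
  r <- gen_behavior(theta, 30, bias = 100, seed = 1)
  expect_true(all(r$old == 4L) && all(r$new == 4L))
  expect_identical(gen_behavior(theta, 30, seed = 5),
                   gen_behavior(theta, 30, seed = 5))
  expect_error(gen_behavior(theta, 30, thresholds = c(1, 0, 2)), "ascending")
  # symmetric thresholds around 0: unbiased new-item responses average 2.5
  means <- vapply(1:10, function(s)
    mean(gen_behavior(theta, 2000, bias = 0,
                      thresholds = c(-0.75, 0, 0.75), seed = s)$new),
    numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2.5), 2 * mc_se)
})

test_that("synthetic BOLD is linear in the betas and reproducible", {
  ons <- c(10, 50, 90)
  zero <- gen_bold(ons, matrix(0, 3, 4), tr = 2, n_scans = 70, noise_sd = 0)
  expect_true(all(zero$signal == 0))
  expect_error(gen_bold(ons, matrix(0, 3, 4), tr = 2, n_scans = 70,
                        noise_sd = -1), "noise_sd")
  a <- gen_bold(ons, matrix(1, 3, 4), tr = 2, n_scans = 70, noise_sd = 0.5,
                seed = 3)
  b <- gen_bold(ons, matrix(1, 3, 4), tr = 2, n_scans = 70, noise_sd = 0.5,
                seed = 3)
  expect_identical(a$signal, b$signal)
})

test_that("study generation is deterministic and validates its weights", {
  s1 <- small_study(seed = 9, n_participants = 2, roi_spec = toy_roi_spec("other"))
  s2 <- small_study(seed = 9, n_participants = 2, roi_spec = toy_roi_spec("other"))
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$patterns, s2$patterns)
  expect_silent(validate_trial_table(s1$trials))
  # pattern trial ids are a subset of the trial table
  ids <- unlist(lapply(s1$patterns, function(rois)
    lapply(rois, function(ph) lapply(ph, rownames))))
  expect_true(all(ids %in% s1$trials$trial_id))
  bad_truth <- planted_effects(
    data.frame(roi_class = "other", phase = "encoding",
               outcome = "remembered", w_v = 1, w_s = 1), noise_sd = 1)
  expect_error(small_study(seed = 1, truth = bad_truth), "weights missing")
})

test_that("a visual-only planted signal yields visual > semantic IRAFs item-wise", {
  w <- expand.grid(roi_class = "other", phase = c("encoding", "retrieval"),
                   outcome = c("remembered", "forgotten"),
                   stringsAsFactors = FALSE)
  w$w_v <- 1; w$w_s <- 0
  study <- small_study(seed = 3, n_participants = 1, n_old = 24,
                       roi_spec = toy_roi_spec("other", n_voxels = 120),
                       truth = planted_effects(w, noise_sd = 1e-4))
  iraf <- study_iraf_table(study, adjust_bias = FALSE)$iraf
  wide <- merge(iraf[iraf$feature_type == "visual",
                     c("phase", "item", "iraf")],
                iraf[iraf$feature_type == "semantic",
                     c("phase", "item", "iraf")],
                by = c("phase", "item"), suffixes = c("_v", "_s"))
  expect_gte(mean(wide$iraf_v > wide$iraf_s), 0.95)
})

test_that("equal planted weights leave the success contrast centered on zero", {
  w <- expand.grid(roi_class = "other", phase = c("encoding", "retrieval"),
                   outcome = c("remembered", "forgotten"),
                   stringsAsFactors = FALSE)
  w$w_v <- 0.7; w$w_s <- 0.7
  diffs <- vapply(1:20, function(s) {
    study <- small_study(seed = s, n_participants = 2, n_old = 20,
                         roi_spec = toy_roi_spec("other"),
                         truth = planted_effects(w, noise_sd = 1))
    iraf <- study_iraf_table(study, adjust_bias = FALSE)$iraf
    mean(iraf$iraf[iraf$memory == "remembered"]) -
      mean(iraf$iraf[iraf$memory == "forgotten"])
  }, numeric(1))
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * mc_se)
})

test_that("a planted retrieval-success gap yields a positive contrast across seeds", {
  # retrieval weight gap 0.6 with sigma = 1 and 24 voxels clears the
  # 3 sigma / sqrt(n_voxels) detectability margin
  signs <- vapply(1:20, function(s) {
    study <- small_study(seed = s, n_participants = 4, n_old = 30,
                         roi_spec = toy_roi_spec("IPC-like"))
    iraf <- study_iraf_table(study, adjust_bias = FALSE)$iraf
    ret <- iraf[iraf$phase == "retrieval", ]
    mean(ret$iraf[ret$memory == "remembered"]) >
      mean(ret$iraf[ret$memory == "forgotten"])
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
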