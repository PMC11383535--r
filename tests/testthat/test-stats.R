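# balanced two-factor data with a single near-degenerate grouping factor
flat_group_data <- function(n_per_cell = 25, effect = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(g = factor(c("a", "b")), rep = seq_len(n_per_cell))
  d$participant <- factor(sample(rep(1:2, length.out = nrow(d))))
  d$y <- effect * (d$g == "b") + rnorm(nrow(d))
  d
}

test_that("with no grouping variance, fixed effects match ordinary least squares", {
  d <- flat_group_data(effect = 0.8, seed = 2)
  spec <- mixed_spec("y", fixed = "g", random = "participant")
  res <- fit_lmm(d, spec)
  contrasts(d$g) <- contr.sum(2)
  ols <- coef(lm(y ~ g, data = d))
  expect_equal(unname(lme4::fixef(res$fit)), unname(ols), tolerance = 1e-4)
  # refitting identical data reproduces identical estimates
  res2 <- fit_lmm(d, spec)
  expect_identical(lme4::fixef(res$fit), lme4::fixef(res2$fit))
})

test_that("variance components are recovered in a balanced one-factor design", {
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    n_p <- 40; n_obs <- 12
    d <- data.frame(participant = factor(rep(1:n_p, each = n_obs)))
    d$g <- factor(rep(c("a", "b"), length.out = nrow(d)))
    d$y <- rnorm(n_p, 0, 0.5)[d$participant] + rnorm(nrow(d))
    res <- fit_lmm(d, mixed_spec("y", "g", "participant"))
    vc <- as.data.frame(lme4::VarCorr(res$fit))
    abs(vc$sdcor[vc$grp == "participant"] - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("the Type III F collapses to the classical one-way F when groups vanish", {
  # participants balanced over g with their means equalized, so the
  # random-intercept variance is estimated at its boundary of zero and the
  # mixed-model F must agree with the classical one-way ANOVA F
  set.seed(3)
  d <- expand.grid(g = factor(c("a", "b")), rep = 1:5, participant = factor(1:10))
  d$y <- 0.6 * (d$g == "b") + rnorm(nrow(d))
  d$y <- d$y - ave(d$y, d$participant) + mean(d$y)
  res <- fit_lmm(d, mixed_spec("y", "g", "participant"))
  expect_true(res$singular)
  a <- type3_anova(res)
  classical <- anova(lm(y ~ g, data = d))
  expect_equal(a$F, classical$`F value`[1], tolerance = 1e-3)
  expect_equal(a$df_den, nrow(d) - 2, tolerance = 0.5)
  expect_equal(a$df_num, 1L)
})

test_that("non-convergence is reported, not silently tested", {
  res <- structure(list(fit = NULL, converged = FALSE), class = "lmm_result")
  expect_error(type3_anova(res), "converge")
})

test_that("BH adjustment matches the step-up rule and its properties", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  set.seed(4)
  p <- runif(40)^2
  q <- fdr_adjust(p)
  expect_equal(q, bh_brute(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))
  # order-invariance; re-adjusting tied step-up fixed points reproduces them
  o <- sample(40)
  expect_equal(fdr_adjust(p[o]), q[o])
  expect_equal(fdr_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(fdr_adjust(numeric(0)), "empty")
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("marginal means equal cell means in a balanced design", {
  set.seed(5)
  d <- expand.grid(participant = factor(1:6), item = factor(1:10),
                   memory = c("forgotten", "remembered"),
                   phase = c("encoding", "retrieval"))
  d$iraf <- rnorm(nrow(d), sd = 0.3) +
    0.4 * (d$memory == "remembered") * (d$phase == "retrieval")
  res <- fit_lmm(d, mixed_spec("iraf", c("memory", "phase"),
                               c("participant", "item")))
  ct <- posthoc_means(res, factor = "memory", by = "phase")
  cell <- tapply(d$iraf, list(d$memory, d$phase), mean)
  for (ph in c("encoding", "retrieval"))
    expect_equal(ct$estimate[ct$phase == ph],
                 cell["remembered", ph] - cell["forgotten", ph],
                 tolerance = 1e-8)
  expect_equal(ct$t, ct$estimate / ct$se, tolerance = 1e-9)
  # the planted retrieval-only gap shows up in the right place
  expect_lt(ct$p[ct$phase == "retrieval"], 0.05)
  no_int <- fit_lmm(d, mixed_spec("iraf", c("memory", "phase"),
                                  c("participant", "item"),
                                  interactions = FALSE))
  expect_error(posthoc_means(no_int), "interaction")
})

test_that("flip-pattern sorting follows the configured rule", {
  mk <- function(enc_t, enc_p, ret_t, ret_p, enc_est = enc_t) {
    data.frame(phase = c("encoding", "retrieval"),
               estimate = c(enc_est, ret_t), se = 1, df = 100,
               t = c(enc_t, ret_t), p = c(enc_p, ret_p))
  }
  # strong retrieval success with a negative encoding estimate
  expect_equal(classify_flip_pattern(mk(-1.0, 0.31, 3.7, 0.0002)),
               "encoding_retrieval_flip")
  # fails the retrieval gate
  expect_equal(classify_flip_pattern(mk(-1.0, 0.31, 0.5, 0.6)), "none")
  expect_equal(classify_flip_pattern(mk(-1.0, 0.31, -3.0, 0.002)), "none")
  # positive encoding estimate cannot be a flip
  expect_equal(classify_flip_pattern(mk(1.2, 0.2, 3.0, 0.003)),
               "retrieval_success")
  # borderline encoding contrast: both assignments reachable by config
  border <- mk(-1.647, 0.100, 2.732, 0.006)
  expect_equal(classify_flip_pattern(border, flip_rule = "negative_estimate"),
               "encoding_retrieval_flip")
  expect_equal(classify_flip_pattern(border, flip_rule = "significant_negative"),
               "retrieval_success")
  expect_equal(classify_flip_pattern(border, flip_rule = "significant_negative",
                                     enc_alpha = 0.15),
               "encoding_retrieval_flip")
  expect_error(classify_flip_pattern(border[1, ]), "exactly one")
})

test_that("the phase-by-area model detects an area-dependent phase effect", {
  otc_w <- function(ph) if (ph == "encoding") 1.0 else 0.4
  ipc_w <- function(ph) 0.7
  w <- expand.grid(roi_class = c("OTC-like", "IPC-like"),
                   phase = c("encoding", "retrieval"),
                   outcome = c("remembered", "forgotten"),
                   stringsAsFactors = FALSE)
  w$w_v <- ifelse(w$roi_class == "OTC-like",
                  vapply(w$phase, otc_w, numeric(1)),
                  vapply(w$phase, ipc_w, numeric(1)))
  w$w_s <- w$w_v
  study <- small_study(seed = 21, n_participants = 6, n_old = 36,
                       roi_spec = data.frame(
                         roi_id = c("otc1", "otc2", "ipc1", "ipc2"),
                         roi_class = rep(c("OTC-like", "IPC-like"), each = 2),
                         n_voxels = 24),
                       truth = planted_effects(w, noise_sd = 1))
  iraf <- study_iraf_table(study, adjust_bias = FALSE)$iraf
  area_map <- c(otc1 = "OTC", otc2 = "OTC", ipc1 = "IPC", ipc2 = "IPC")
  fit <- fit_area_model(iraf, area_map)
  a <- fit$anova
  expect_true(all(c("phase", "area", "phase:area") %in% a$effect))
  expect_lt(a$p[a$effect == "phase:area"], 0.05)
  otc_t <- abs(fit$posthoc$t[fit$posthoc$area == "OTC"])
  ipc_t <- abs(fit$posthoc$t[fit$posthoc$area == "IPC"])
  expect_gt(otc_t, ipc_t)
  expect_error(fit_area_model(iraf, c(otc1 = "OTC")), "both areas")
})

test_that("simulated power is near alpha at d = 0 and saturates at large d", {
  p0 <- power_sim(d = 0, alpha = 0.05, n_participants = 10, n_items = 24,
                  reps = 100, seed = 3)
  expect_lt(abs(p0$power - 0.05), 2 * sqrt(0.05 * 0.95 / 100) + 0.02)
  p3 <- power_sim(d = 3, alpha = 0.05, n_participants = 6, n_items = 12,
                  reps = 20, seed = 4)
  expect_gte(p3$power, 0.99)
  expect_equal(p0$mc_se, sqrt(p0$power * (1 - p0$power) / p0$reps),
               tolerance = 1e-9)
  expect_error(power_sim(d = 0.4, n_phases = 1, reps = 2), "infeasible")
})
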