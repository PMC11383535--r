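make_norms <- function(values, n_visual) {
  # wrap a raw matrix as feature norms (visual block first)
  n_feat <- ncol(values)
  ids <- sprintf("f%02d", seq_len(n_feat))
  dimnames(values) <- list(sprintf("c%02d", seq_len(nrow(values))), ids)
  structure(list(values = values,
                 category = setNames(rep(c("visual", "semantic"),
                                         c(n_visual, n_feat - n_visual)), ids),
                 concept_ids = rownames(values), feature_ids = ids),
            class = "feature_norms")
}

test_that("model RSM cells equal brute-force Pearson correlations", {
  set.seed(4)
  vals <- matrix(runif(4 * 5), 4, 5)
  norms <- make_norms(cbind(vals, vals[, 1:2] + 0.1), n_visual = 5)
  rsm <- build_model_rsm(norms, "visual")
  for (i in 1:4) for (j in 1:4) {
    expect_lt(abs(rsm$values[i, j] - pearson_brute(vals[i, ], vals[j, ])),
              1e-12)
  }
  expect_equal(unname(diag(rsm$values)), rep(1, 4))
})

test_that("identical and opposite feature vectors give cells 1 and -1", {
  vals <- rbind(c(1, 0), c(1, 0), c(0, 1))
  norms <- make_norms(cbind(vals, vals), n_visual = 2)
  rsm <- build_model_rsm(norms, "visual")
  expect_equal(rsm$values[1, 2], 1)
  expect_equal(rsm$values[1, 3], -1) # [1,0] vs [0,1]
})

test_that("a concept with flat category features is reported by name", {
  vals <- rbind(c(1, 1, 1), c(1, 0, 2), c(0, 2, 1))
  norms <- make_norms(cbind(vals, vals), n_visual = 3)
  expect_error(build_model_rsm(norms, "visual"), "c01")
})

test_that("model RSM is invariant to feature order and concept rescaling", {
  set.seed(8)
  vals <- matrix(runif(5 * 6), 5, 6)
  r1 <- build_model_rsm(make_norms(cbind(vals, vals), 6), "visual")
  perm <- sample(6)
  r2 <- build_model_rsm(make_norms(cbind(vals[, perm], vals), 6), "visual")
  expect_equal(r1$values, r2$values, ignore_attr = TRUE)
  vals3 <- vals; vals3[2, ] <- vals3[2, ] * 7.5
  r3 <- build_model_rsm(make_norms(cbind(vals3, vals3), 6), "visual")
  expect_lt(max(abs(r1$values - r3$values)), 1e-12)
})

test_that("comparing an RSM with itself gives rho 1 globally and item-wise", {
  set.seed(2)
  vals <- matrix(runif(5 * 6), 5, 6)
  a <- build_model_rsm(make_norms(cbind(vals, vals), 6), "visual")
  cmp <- compare_rsms(a, a)
  expect_equal(cmp$global_rho, 1)
  expect_equal(unname(cmp$itemwise_rho), rep(1, 5))
})

test_that("RSM comparison matches a rank-then-Pearson hand computation", {
  set.seed(3)
  v1 <- matrix(runif(5 * 6), 5, 6); v2 <- matrix(runif(5 * 7), 5, 7)
  a <- build_model_rsm(make_norms(cbind(v1, v1), 6), "visual")
  b <- build_model_rsm(make_norms(cbind(v2, v2), 7), "visual")
  b <- model_rsm(b$values, a$item_ids, "semantic")
  cmp <- compare_rsms(a, b)
  lt <- lower.tri(a$values)
  expect_equal(cmp$global_rho, spearman_brute(a$values[lt], b$values[lt]))
  for (i in 1:5)
    expect_equal(unname(cmp$itemwise_rho[i]),
                 spearman_brute(a$values[i, -i], b$values[i, -i]))
})

test_that("scrambled off-diagonals decorrelate the global comparison", {
  set.seed(6)
  vals <- matrix(runif(12 * 10), 12, 10)
  a <- build_model_rsm(make_norms(cbind(vals, vals), 10), "visual")
  rhos <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    v <- a$values[lower.tri(a$values)]
    m <- matrix(0, 12, 12)
    m[lower.tri(m)] <- sample(v)
    m <- m + t(m); diag(m) <- 1
    b <- model_rsm(m, a$item_ids, "semantic")
    compare_rsms(a, b)$global_rho
  }, numeric(1))
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 2 * se)
})

test_that("residualizing orthogonal RSMs just centers them", {
  pair <- correlated_rsm_pair(8, r = 0, seed = 5)
  res <- residualize_rsms(pair$a, pair$b)
  lt <- lower.tri(pair$a$values)
  va <- pair$a$values[lt]
  expect_lt(max(abs(res$a_resid$values[lt] - (va - mean(va)))), 1e-10)
  expect_true(is.na(res$a_resid$values[1, 1]))
  expect_equal(res$a_resid$category, "residual-visual")
})

test_that("mutual residualization of r-correlated matrices yields correlation -r", {
  for (r in c(0.2, 0.5, 0.8)) {
    pair <- correlated_rsm_pair(10, r = r, seed = 11)
    lt <- lower.tri(pair$a$values)
    expect_lt(abs(cor(pair$a$values[lt], pair$b$values[lt]) - r), 1e-12)
    res <- residualize_rsms(pair$a, pair$b)
    got <- cor(res$a_resid$values[lt], res$b_resid$values[lt])
    expect_lt(abs(got - (-r)), 1e-10)
  }
})

test_that("residuals match an explicit normal-equations solution", {
  pair <- correlated_rsm_pair(6, r = 0.45, seed = 13)
  res <- residualize_rsms(pair$a, pair$b)
  lt <- lower.tri(pair$a$values)
  expect_lt(max(abs(res$a_resid$values[lt] -
                      ols_resid_brute(pair$a$values[lt], pair$b$values[lt]))),
            1e-10)
  expect_lt(max(abs(res$b_resid$values[lt] -
                      ols_resid_brute(pair$b$values[lt], pair$a$values[lt]))),
            1e-10)
})

test_that("residualization is idempotent on already-orthogonal inputs", {
  pair <- correlated_rsm_pair(8, r = 0, seed = 21)
  r1 <- residualize_rsms(pair$a, pair$b)
  r2 <- residualize_rsms(r1$a_resid, r1$b_resid)
  lt <- lower.tri(pair$a$values)
  expect_lt(max(abs(r1$a_resid$values[lt] - r2$a_resid$values[lt])), 1e-10)
})

test_that("per-row residualization removes each row's shared component", {
  pair <- correlated_rsm_pair(8, r = 0.6, seed = 31)
  res <- residualize_rsms(pair$a, pair$b, per_row = TRUE)
  expect_true(all(is.na(diag(res$a_resid$values))))
  expect_lt(max(abs(res$a_resid$values - t(res$a_resid$values)), na.rm = TRUE),
            1e-12)
})
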