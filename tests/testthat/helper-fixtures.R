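# shared fixture builders; everything is generated in code at test time

toy_roi_spec <- function(classes = c("OTC-like", "IPC-like", "other"),
                         n_voxels = 24) {
  data.frame(roi_id = paste0("roi", seq_along(classes)),
             roi_class = classes, n_voxels = n_voxels,
             stringsAsFactors = FALSE)
}

# small study with the reference planted effects; sizes chosen for fast tests
small_study <- function(seed = 1, n_participants = 4, n_old = 24,
                        n_catch = 4, n_new = 10, roi_spec = toy_roi_spec(),
                        truth = default_planted_effects(),
                        p_dont_know = 0.08, ...) {
  design <- study_design(n_participants, n_old, n_catch, n_new,
                         roi_spec = roi_spec, p_dont_know = p_dont_know)
  norms <- gen_feature_norms(n_old + n_catch + n_new, 20, 20,
                             cross_corr = 0.25, seed = seed)
  gen_study(design, truth, norms, seed = seed, ...)
}

# hand-built trial table for rule-level tests
toy_trial_table <- function() {
  enc <- data.frame(
    trial_id = sprintf("e%02d", 1:10), participant = "p01",
    phase = "encoding", run = rep(1:2, each = 5), slot = rep(1:5, 2),
    onset = rep(seq(0, 40, by = 10), 2),
    concept_id = sprintf("c%02d", 1:10),
    status = c(rep("target", 8), "catch", "catch"),
    response = c("none", "dont_know", rep("none", 6), "no_match", "no_match"),
    valid = c(TRUE, FALSE, rep(TRUE, 6), FALSE, FALSE),
    memory = "not_applicable", stringsAsFactors = FALSE)
  ret <- data.frame(
    trial_id = sprintf("r%02d", 1:10), participant = "p01",
    phase = "retrieval", run = rep(1:2, each = 5), slot = rep(1:5, 2),
    onset = rep(seq(0, 40, by = 10), 2),
    concept_id = c(sprintf("c%02d", 1:8), "n01", "n02"),
    status = c(rep("target", 8), "new", "new"),
    response = c("4", "3", "2", "1", "4", "3", "2", "1", "2", "1"),
    valid = c(TRUE, FALSE, rep(TRUE, 6), TRUE, TRUE),
    memory = "not_applicable", stringsAsFactors = FALSE)
  rbind(enc, ret)
}

# brute-force Pearson correlation, kept independent of stats::cor
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force Spearman: rank then Pearson
spearman_brute <- function(x, y) pearson_brute(rank(x), rank(y))

# explicit normal-equations OLS residuals of y on (1, x)
ols_resid_brute <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Benjamini-Hochberg step-up by direct application of the rule
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  q[o] <- rev(cummin(rev(pmin(adj, 1))))
  q
}

# symmetric matrices whose lower-triangle vectors are standardized with
# exact correlation r (via QR orthonormalization)
correlated_rsm_pair <- function(n_items, r, seed = 1) {
  set.seed(seed)
  m <- n_items * (n_items - 1) / 2
  z0 <- cbind(stats::rnorm(m), stats::rnorm(m))
  z0 <- sweep(z0, 2, colMeans(z0)) # centered, so Q's columns stay centered
  z <- qr.Q(qr(z0))
  z2 <- r * z[, 1] + sqrt(1 - r^2) * z[, 2]
  fold <- function(v) {
    v <- v / max(abs(v)) # entries in [-1, 1]; rescaling preserves correlation
    M <- matrix(0, n_items, n_items)
    M[lower.tri(M)] <- v
    M <- M + t(M)
    diag(M) <- 1
    M
  }
  a <- fold(z[, 1]); b <- fold(z2)
  list(a = model_rsm(a, sprintf("i%d", 1:n_items), "visual"),
       b = model_rsm(b, sprintf("i%d", 1:n_items), "semantic"))
}
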