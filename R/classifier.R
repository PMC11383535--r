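#' Train on encoding IRAFs, transfer to retrieval
#'
#' Fits a linear maximum-margin classifier (soft-margin SVM, fixed C = 1)
#' to encoding-phase samples labeled by feature type and reports its
#' accuracy on retrieval-phase samples. Training never sees retrieval data:
#' above-chance transfer means the visual/semantic distinction generalizes
#' across memory phases.
#'
#' @param enc_samples numeric matrix (samples x features) or vector of
#'   encoding-phase IRAF samples.
#' @param enc_labels feature-type labels (`"visual"`/`"semantic"`), both
#'   classes present.
#' @param ret_samples,ret_labels retrieval-phase test set with matching
#'   dimensionality.
#' @param seed integer seed (the linear fit is deterministic; the seed
#'   pins any tie-breaking).
#' @param cost SVM regularization constant.
#' @return A `transfer_result`: list with `accuracy`, `n_test`, `correct`.
#' @export
train_transfer <- function(enc_samples, enc_labels, ret_samples, ret_labels,
                           seed = 1, cost = 1) {
  enc_x <- as.matrix(enc_samples)
  ret_x <- as.matrix(ret_samples)
  if (ncol(enc_x) != ncol(ret_x))
    stop("train and test sample dimensionality must match")
  enc_y <- factor(enc_labels)
  if (nlevels(enc_y) < 2) stop("training set must contain both classes")
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = enc_x, y = enc_y, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, ret_x)
  correct <- sum(as.character(pred) == as.character(ret_labels))
  structure(list(accuracy = correct / length(ret_labels),
                 n_test = length(ret_labels), correct = correct),
            class = "transfer_result")
}

#' Null transfer accuracies from simulated participants
#'
#' Simulates participants whose IRAF samples carry no label information
#' (i.i.d. Gaussian features, labels assigned at random) and runs the full
#' train-on-encoding / test-on-retrieval pipeline on each, yielding the
#' empirical chance distribution of transfer accuracy.
#'
#' @param n_sim number of simulated participants (>= 100).
#' @param shape list with `n_train`, `n_test` (samples per phase, >= 4
#'   each) and `n_features` (>= 1).
#' @param seed integer seed.
#' @return numeric vector of `n_sim` null accuracies.
#' @export
simulate_null <- function(n_sim = 1000,
                          shape = list(n_train = 40, n_test = 40, n_features = 1),
                          seed = 1) {
  if (n_sim < 100) stop("`n_sim` must be >= 100")
  if (shape$n_train < 4 || shape$n_test < 4 || shape$n_features < 1)
    stop("degenerate shape: need >= 4 samples per phase and >= 1 feature")
  set.seed(as.integer(seed))
  half <- function(n) rep(c("visual", "semantic"), length.out = n)
  vapply(seq_len(n_sim), function(s) {
    tr_x <- matrix(stats::rnorm(shape$n_train * shape$n_features),
                   shape$n_train, shape$n_features)
    te_x <- matrix(stats::rnorm(shape$n_test * shape$n_features),
                   shape$n_test, shape$n_features)
    tr_y <- sample(half(shape$n_train))
    te_y <- sample(half(shape$n_test))
    train_transfer(tr_x, tr_y, te_x, te_y, seed = s)$accuracy
  }, numeric(1))
}

#' Chi-squared test of classifier performance against simulated chance
#'
#' Compares the observed correct/incorrect totals (summed over real
#' participants) against the expected split under the null accuracy
#' estimated from simulated participants, with a 1-df chi-squared
#' statistic. The raw null draws should be kept alongside, so an
#' empirical-quantile test remains available.
#'
#' @param correct total correct predictions over real participants.
#' @param total total predictions (> 0).
#' @param null_accuracies vector of null accuracies from [simulate_null()].
#' @return A `chance_test`: list with `chi2`, `df` (1), `p`,
#'   `null_mean_accuracy`.
#' @export
chance_test <- function(correct, total, null_accuracies) {
  if (total <= 0) stop("`total` must be > 0")
  if (correct < 0 || correct > total) stop("`correct` must lie in [0, total]")
  p0 <- mean(null_accuracies)
  expected <- c(total * p0, total * (1 - p0))
  if (any(expected < 5))
    warning("expected cell count < 5; chi-squared approximation is weak")
  observed <- c(correct, total - correct)
  chi2 <- sum((observed - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 null_mean_accuracy = p0),
            class = "chance_test")
}

# encoding/retrieval sample sets for one participant x ROI: one scalar
# sample per (item, feature type), labeled by feature type
.iraf_samples <- function(iraf, pp, roi) {
  d <- iraf[iraf$participant == pp & iraf$roi_id == roi, ]
  list(enc = d[d$phase == "encoding", c("iraf", "feature_type", "item")],
       ret = d[d$phase == "retrieval", c("iraf", "feature_type", "item")])
}

#' Per-ROI cross-phase decoding of feature type
#'
#' For every ROI, trains the linear classifier on each real participant's
#' encoding-phase IRAF samples (one scalar sample per item and feature
#' type), tests on that participant's retrieval samples, pools the correct
#' counts over participants, and tests the pooled performance against a
#' simulated-chance null with [chance_test()].
#'
#' @param iraf IRAF table from [build_iraf_table()].
#' @param n_sim simulated null participants per ROI.
#' @param seed integer seed.
#' @param alpha level for the `above_chance` flag.
#' @return list with `by_roi` (data frame: `roi_id`, `accuracy`, `correct`,
#'   `n_test`, `chi2`, `p`, `above_chance`), `by_participant` (per
#'   participant x ROI accuracies), `overall` (pooled accuracy and its
#'   [chance_test()]), and `null_accuracies`.
#' @export
classifier_report <- function(iraf, n_sim = 1000, seed = 1, alpha = 0.05) {
  rois <- unique(iraf$roi_id)
  parts <- unique(iraf$participant)
  per <- list()
  for (roi in rois) {
    for (pp in parts) {
      s <- .iraf_samples(iraf, pp, roi)
      if (nrow(s$enc) < 4 || nrow(s$ret) < 4 ||
          length(unique(s$enc$feature_type)) < 2) next
      tr <- train_transfer(s$enc$iraf, s$enc$feature_type,
                           s$ret$iraf, s$ret$feature_type, seed = seed)
      per[[length(per) + 1L]] <- data.frame(
        roi_id = roi, participant = pp, accuracy = tr$accuracy,
        correct = tr$correct, n_test = tr$n_test, stringsAsFactors = FALSE)
    }
  }
  by_participant <- do.call(rbind, per)
  shape <- list(n_train = round(mean(table(iraf$participant[iraf$phase == "encoding"],
                                           iraf$roi_id[iraf$phase == "encoding"]))),
                n_test = round(mean(by_participant$n_test)), n_features = 1)
  nulls <- simulate_null(n_sim, shape, seed = as.integer(seed) + 1L)
  by_roi <- do.call(rbind, lapply(rois, function(roi) {
    d <- by_participant[by_participant$roi_id == roi, ]
    ct <- chance_test(sum(d$correct), sum(d$n_test), nulls)
    data.frame(roi_id = roi, accuracy = sum(d$correct) / sum(d$n_test),
               correct = sum(d$correct), n_test = sum(d$n_test),
               chi2 = ct$chi2, p = ct$p,
               above_chance = ct$p < alpha &&
                 sum(d$correct) / sum(d$n_test) > ct$null_mean_accuracy,
               stringsAsFactors = FALSE)
  }))
  overall_ct <- chance_test(sum(by_participant$correct),
                            sum(by_participant$n_test), nulls)
  list(by_roi = by_roi, by_participant = by_participant,
       overall = list(accuracy = sum(by_participant$correct) /
                        sum(by_participant$n_test), test = overall_ct),
       null_accuracies = nulls)
}
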