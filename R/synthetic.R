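#' Generate synthetic feature norms
#'
#' Produces a nonnegative concept-by-feature matrix of normalized report
#' frequencies with two feature-category blocks (visual and semantic), the
#' kind of matrix obtained from large-scale property-norming studies where
#' raters list attributes of everyday objects. The semantic block is built as
#' a convex mixture (weight `cross_corr`) of duplicated visual features and
#' fresh independent features, so the expected correlation between the two
#' derived model RSMs increases monotonically with `cross_corr`, reaching
#' identity at `cross_corr = 1`.
#'
#' Feature values are drawn as rectified Gaussians and column-normalized to a
#' maximum of 1 (a "normalized report frequency"). Every feature is
#' guaranteed nonzero for at least two concepts, mirroring the norming
#' convention that features mentioned for a single concept are dropped.
#'
#' @param n_concepts number of concepts (>= 3).
#' @param n_visual,n_semantic number of features per category (each >= 2).
#' @param cross_corr mixing weight in `[0, 1]` controlling visual-semantic
#'   block overlap.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A `feature_norms` object: list with `values` (concepts x features
#'   matrix), `category` (named character vector, `"visual"`/`"semantic"`
#'   per feature), `concept_ids`, `feature_ids`.
#' @examples
#' norms <- gen_feature_norms(20, 10, 10, cross_corr = 0.3, seed = 1)
#' dim(norms$values)
#' @export
gen_feature_norms <- function(n_concepts, n_visual, n_semantic,
                              cross_corr = 0.25, seed = 1) {
  if (!is.finite(cross_corr) || cross_corr < 0 || cross_corr > 1)
    stop("`cross_corr` must be a finite value in [0, 1]")
  if (n_concepts < 3) stop("`n_concepts` must be >= 3")
  if (n_visual < 2 || n_semantic < 2) stop("feature counts must be >= 2")
  set.seed(as.integer(seed))

  rect_block <- function(n_feat) {
    m <- matrix(pmax(stats::rnorm(n_concepts * n_feat), 0), n_concepts, n_feat)
    # guarantee every feature reported for >= 2 concepts
    for (j in seq_len(n_feat)) {
      nz <- sum(m[, j] > 0)
      if (nz < 2) {
        idx <- sample.int(n_concepts, 2)
        m[idx, j] <- abs(stats::rnorm(2)) + 0.1
      }
    }
    m
  }

  vis <- rect_block(n_visual)
  fresh <- rect_block(n_semantic)
  dup <- vis[, ((seq_len(n_semantic) - 1L) %% n_visual) + 1L, drop = FALSE]
  sem <- cross_corr * dup + (1 - cross_corr) * fresh

  values <- cbind(vis, sem)
  values <- sweep(values, 2, apply(values, 2, max), "/")
  concept_ids <- sprintf("c%03d", seq_len(n_concepts))
  feature_ids <- c(sprintf("v%04d", seq_len(n_visual)),
                   sprintf("s%04d", seq_len(n_semantic)))
  dimnames(values) <- list(concept_ids, feature_ids)
  category <- stats::setNames(
    rep(c("visual", "semantic"), c(n_visual, n_semantic)), feature_ids)

  structure(list(values = values, category = category,
                 concept_ids = concept_ids, feature_ids = feature_ids),
            class = "feature_norms")
}

#' @export
print.feature_norms <- function(x, ...) {
  cat(sprintf("<feature_norms> %d concepts x %d features (%d visual, %d semantic)\n",
              nrow(x$values), ncol(x$values),
              sum(x$category == "visual"), sum(x$category == "semantic")))
  invisible(x)
}

#' Describe a synthetic study design
#'
#' @param n_participants number of participants.
#' @param n_old number of target items shown at encoding and re-tested at
#'   retrieval.
#' @param n_catch number of catch items (encoding only; excluded from all
#'   pattern analyses).
#' @param n_new number of new lures presented only at retrieval.
#' @param n_runs_encoding,n_runs_retrieval scanner runs per phase.
#' @param tr repetition time in seconds.
#' @param iti_range two-element numeric, inter-trial-interval bounds in
#'   seconds (uniformly sampled).
#' @param roi_spec data frame with columns `roi_id`, `roi_class` (one of
#'   `"OTC-like"`, `"IPC-like"`, `"other"`) and `n_voxels`.
#' @param p_dont_know probability that a target item draws a "don't know"
#'   press at encoding (such items are excluded from both phases).
#' @return A `study_design` object.
#' @export
study_design <- function(n_participants, n_old, n_catch = 0, n_new,
                         n_runs_encoding = 2, n_runs_retrieval = 2,
                         tr = 2, iti_range = c(2, 7), roi_spec,
                         p_dont_know = 0.08) {
  counts <- c(n_participants = n_participants, n_old = n_old, n_new = n_new,
              n_runs_encoding = n_runs_encoding,
              n_runs_retrieval = n_runs_retrieval)
  if (any(counts < 1) || n_catch < 0)
    stop("all design counts must be positive integers (n_catch >= 0)")
  stopifnot(is.data.frame(roi_spec),
            all(c("roi_id", "roi_class", "n_voxels") %in% names(roi_spec)))
  bad <- setdiff(roi_spec$roi_class, c("OTC-like", "IPC-like", "other"))
  if (length(bad)) stop("unknown roi_class: ", paste(bad, collapse = ", "))
  structure(list(n_participants = as.integer(n_participants),
                 n_old = as.integer(n_old), n_catch = as.integer(n_catch),
                 n_new = as.integer(n_new),
                 n_runs_encoding = as.integer(n_runs_encoding),
                 n_runs_retrieval = as.integer(n_runs_retrieval),
                 tr = tr, iti_range = iti_range, roi_spec = roi_spec,
                 p_dont_know = p_dont_know),
            class = "study_design")
}

#' Planted representational effects for the synthetic generator
#'
#' The generator plants, for every combination of ROI class, memory phase and
#' memory outcome, a pair of weights `(w_v, w_s)` scaling how strongly a
#' trial's voxel pattern follows the item's visual and semantic feature
#' vectors; `noise_sd` is the i.i.d. Gaussian voxel noise.
#'
#' @param weights data frame with columns `roi_class`, `phase`
#'   (`"encoding"`/`"retrieval"`), `outcome` (`"remembered"`/`"forgotten"`),
#'   `w_v`, `w_s`.
#' @param noise_sd voxel noise standard deviation (> 0; may be a small
#'   positive value to approximate the noiseless limit).
#' @return A `planted_effects` object.
#' @export
planted_effects <- function(weights, noise_sd = 1) {
  stopifnot(is.data.frame(weights),
            all(c("roi_class", "phase", "outcome", "w_v", "w_s") %in% names(weights)))
  if (!(noise_sd > 0)) stop("`noise_sd` must be > 0")
  structure(list(weights = weights, noise_sd = noise_sd),
            class = "planted_effects")
}

#' Reference planted-effects configuration
#'
#' Encodes the qualitative pattern the pipeline is designed to detect:
#' occipito-temporal ("OTC-like") regions carry stronger representations at
#' encoding than retrieval regardless of outcome; inferior-parietal
#' ("IPC-like") regions carry a memory-success effect only at retrieval; and
#' `"other"` regions show an encoding-retrieval flip (forgotten > remembered
#' at encoding, remembered > forgotten at retrieval).
#'
#' @param strength overall signal scale multiplying all weights.
#' @param noise_sd voxel noise SD.
#' @export
default_planted_effects <- function(strength = 1, noise_sd = 1) {
  grid <- expand.grid(roi_class = c("OTC-like", "IPC-like", "other"),
                      phase = c("encoding", "retrieval"),
                      outcome = c("remembered", "forgotten"),
                      stringsAsFactors = FALSE)
  w <- function(rc, ph, oc) {
    if (rc == "OTC-like") return(if (ph == "encoding") 1.0 else 0.45)
    if (rc == "IPC-like") {
      if (ph == "encoding") return(0.5)
      return(if (oc == "remembered") 1.0 else 0.4)
    }
    # flip region
    if (ph == "encoding") return(if (oc == "remembered") 0.4 else 1.0)
    if (oc == "remembered") 1.0 else 0.4
  }
  grid$w_v <- strength * mapply(w, grid$roi_class, grid$phase, grid$outcome)
  grid$w_s <- grid$w_v
  planted_effects(grid, noise_sd = noise_sd)
}

#' Generate graded recognition responses
#'
#' Maps latent memory strength to 4-point old/new confidence responses
#' (1 = definitely new ... 4 = definitely old). Old items respond to
#' `theta + bias + noise`, new items to `bias + noise`, binned at three
#' ascending thresholds. A positive `bias` produces an "old" response bias
#' and hence false alarms.
#'
#' @param theta numeric vector of latent strengths for old items.
#' @param n_new number of new items.
#' @param bias additive response bias (0 = unbiased).
#' @param thresholds three strictly ascending cut points. The default sits
#'   above zero, so an unbiased participant mostly rejects new items
#'   (mean new-item response below 2); symmetric thresholds around 0 put
#'   new items at the scale midpoint instead.
#' @param noise_sd response noise SD.
#' @param seed integer seed.
#' @return list with integer vectors `old` and `new` on the 1-4 scale.
#' @export
gen_behavior <- function(theta, n_new, bias = 0,
                         thresholds = c(-0.25, 0.5, 1.25),
                         noise_sd = 1, seed = 1) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("`thresholds` must be 3 strictly ascending values")
  set.seed(as.integer(seed))
  bin <- function(x) findInterval(x, thresholds) + 1L
  old <- bin(theta + bias + stats::rnorm(length(theta), 0, noise_sd))
  new <- bin(bias + stats::rnorm(n_new, 0, noise_sd))
  list(old = old, new = new)
}

# onsets for one phase: trials split across runs, fixed 1.25 s trial duration
# plus uniform ITI
.gen_onsets <- function(n_trials, n_runs, iti_range) {
  run <- rep(seq_len(n_runs), length.out = n_trials)
  run <- sort(run)
  onset <- numeric(n_trials)
  for (r in seq_len(n_runs)) {
    idx <- which(run == r)
    iti <- stats::runif(length(idx), iti_range[1], iti_range[2])
    onset[idx] <- cumsum(c(0, (1.25 + iti)[-length(idx)]))
  }
  data.frame(run = run, onset = onset)
}

#' Generate a complete synthetic study
#'
#' Builds per-participant trial tables, graded recognition responses, and
#' per-ROI single-trial voxel patterns whose similarity structure follows the
#' visual/semantic model RSMs with the planted weights of `truth`. For each
#' ROI, fixed voxel loading maps `V` (visual) and `S` (semantic) are drawn
#' once as i.i.d. standard normals; the pattern of trial `i` is
#' `w_v * V f_v_i + w_s * S f_s_i + noise_sd * eps`, where `f_v_i`, `f_s_i`
#' are the item's category feature vectors and the weights depend on the
#' ROI class, phase, and the trial's memory outcome.
#'
#' Memory outcomes are self-consistent with behavior: a per-item latent
#' strength `theta` (shared across participants, creating an item random
#' effect) plus participant response noise is binned into the 4-point
#' response; an old item counts as remembered when its response is 3 or 4.
#' With the defaults (`theta_mean = 0.85`, thresholds `(-0.25, 0.5, 1.25)`)
#' an unbiased participant hits about 62% of old items and mostly rejects
#' new items (mean new-item response near 1.8), matching recognition
#' performance typical of a day-delayed conceptual memory test. Catch and
#' new items use the "forgotten" weights; they never enter the analyzed
#' contrasts.
#'
#' @param design a [study_design()].
#' @param truth a [planted_effects()]; weights must cover every
#'   (roi_class, phase, outcome) combination the design references.
#' @param norms a [gen_feature_norms()] result with at least
#'   `n_old + n_catch + n_new` concepts.
#' @param seed integer seed; the study is a pure function of
#'   (design, truth, norms, seed).
#' @param bias scalar or per-participant response bias.
#' @param theta_mean,theta_sd mean and SD of the latent per-item memory
#'   strength.
#' @param response_noise_sd SD of per-participant response noise.
#' @param thresholds confidence bin cut points, passed to [gen_behavior()].
#' @return A `synthetic_study`: list with `trials` (one data frame over all
#'   participants), `patterns` (nested list participant -> ROI -> phase,
#'   trials x voxels matrices with trial-id rownames), `norms`, `truth`,
#'   `design`, and `theta` (latent item strengths).
#' @export
gen_study <- function(design, truth, norms, seed = 1, bias = 0,
                      theta_mean = 0.85, theta_sd = 1,
                      response_noise_sd = 0.5,
                      thresholds = c(-0.25, 0.5, 1.25)) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "planted_effects"),
            inherits(norms, "feature_norms"))
  n_items <- design$n_old + design$n_catch + design$n_new
  if (length(norms$concept_ids) < n_items)
    stop("norms must contain at least n_old + n_catch + n_new concepts")
  need <- expand.grid(roi_class = unique(design$roi_spec$roi_class),
                      phase = c("encoding", "retrieval"),
                      outcome = c("remembered", "forgotten"),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$roi_class, d$phase, d$outcome)
  missing_w <- setdiff(key(need), key(truth$weights))
  if (length(missing_w))
    stop("planted weights missing for: ", paste(missing_w, collapse = "; "))

  set.seed(as.integer(seed))
  concepts <- sample(norms$concept_ids, n_items)
  old_ids <- concepts[seq_len(design$n_old)]
  catch_ids <- if (design$n_catch > 0)
    concepts[design$n_old + seq_len(design$n_catch)] else character(0)
  new_ids <- concepts[design$n_old + design$n_catch + seq_len(design$n_new)]

  theta <- stats::setNames(stats::rnorm(design$n_old, theta_mean, theta_sd),
                           old_ids)
  bias <- rep(bias, length.out = design$n_participants)

  vis_f <- t(norms$values[, norms$category == "visual", drop = FALSE])
  sem_f <- t(norms$values[, norms$category == "semantic", drop = FALSE])

  # fixed voxel loading maps, one pair per ROI
  loadings <- lapply(seq_len(nrow(design$roi_spec)), function(k) {
    nv <- design$roi_spec$n_voxels[k]
    list(V = matrix(stats::rnorm(nv * nrow(vis_f)), nv, nrow(vis_f)),
         S = matrix(stats::rnorm(nv * nrow(sem_f)), nv, nrow(sem_f)))
  })
  names(loadings) <- design$roi_spec$roi_id

  wtab <- truth$weights
  lookup_w <- function(rc, ph, oc) {
    i <- which(wtab$roi_class == rc & wtab$phase == ph & wtab$outcome == oc)
    c(wtab$w_v[i[1]], wtab$w_s[i[1]])
  }

  all_trials <- list()
  patterns <- vector("list", design$n_participants)
  for (p in seq_len(design$n_participants)) {
    resp <- gen_behavior(theta, design$n_new, bias = bias[p],
                         thresholds = thresholds,
                         noise_sd = response_noise_sd,
                         seed = as.integer(seed) + 7L * p)
    outcome <- ifelse(resp$old >= 3L, "remembered", "forgotten")
    names(outcome) <- old_ids
    dk <- stats::runif(design$n_old) < design$p_dont_know
    names(dk) <- old_ids

    enc_items <- sample(c(old_ids, catch_ids))
    enc_t <- .gen_onsets(length(enc_items), design$n_runs_encoding,
                         design$iti_range)
    ret_items <- sample(c(old_ids, new_ids))
    ret_t <- .gen_onsets(length(ret_items), design$n_runs_retrieval,
                         design$iti_range)

    mk_rows <- function(phase, items, tt) {
      status <- ifelse(items %in% old_ids, "target",
                       ifelse(items %in% catch_ids, "catch", "new"))
      is_old <- status == "target"
      flagged <- is_old & dk[items]
      response <- character(length(items))
      if (phase == "encoding") {
        response[] <- "none"
        response[status == "catch"] <- "no_match"
        response[flagged] <- "dont_know"
      } else {
        response[is_old] <- as.character(resp$old[match(items[is_old], old_ids)])
        response[status == "new"] <- as.character(
          resp$new[seq_len(sum(status == "new"))])
      }
      valid <- status != "catch" & !(is_old & dk[items])
      memory <- rep("not_applicable", length(items))
      lab <- is_old & valid
      memory[lab] <- outcome[items[lab]]
      slot <- stats::ave(seq_along(items), tt$run, FUN = seq_along)
      data.frame(
        trial_id = sprintf("p%02d_%s_r%d_t%03d", p, substr(phase, 1, 3),
                           tt$run, slot),
        participant = sprintf("p%02d", p), phase = phase, run = tt$run,
        slot = slot, onset = tt$onset, concept_id = items, status = status,
        response = response, valid = valid, memory = memory,
        stringsAsFactors = FALSE)
    }
    enc_rows <- mk_rows("encoding", enc_items, enc_t)
    ret_rows <- mk_rows("retrieval", ret_items, ret_t)
    all_trials[[p]] <- rbind(enc_rows, ret_rows)

    outcome_for_weights <- function(rows) {
      oc <- rep("forgotten", nrow(rows))
      is_old <- rows$status == "target"
      oc[is_old] <- outcome[rows$concept_id[is_old]]
      oc
    }
    patterns[[p]] <- lapply(seq_len(nrow(design$roi_spec)), function(k) {
      rc <- design$roi_spec$roi_class[k]
      L <- loadings[[k]]
      per_phase <- lapply(list(encoding = enc_rows, retrieval = ret_rows),
                          function(rows) {
        oc <- outcome_for_weights(rows)
        sig <- vapply(seq_len(nrow(rows)), function(i) {
          w <- lookup_w(rc, rows$phase[i], oc[i])
          w[1] * (L$V %*% vis_f[, rows$concept_id[i]]) +
            w[2] * (L$S %*% sem_f[, rows$concept_id[i]])
        }, numeric(design$roi_spec$n_voxels[k]))
        m <- t(sig) + matrix(stats::rnorm(nrow(rows) * design$roi_spec$n_voxels[k],
                                          0, truth$noise_sd),
                             nrow(rows), design$roi_spec$n_voxels[k])
        rownames(m) <- rows$trial_id
        m
      })
      per_phase
    })
    names(patterns[[p]]) <- design$roi_spec$roi_id
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  names(patterns) <- sprintf("p%02d", seq_len(design$n_participants))

  structure(list(trials = trials, patterns = patterns, norms = norms,
                 truth = truth, design = design, theta = theta),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants, %d trials, %d ROIs\n",
              x$design$n_participants, nrow(x$trials),
              nrow(x$design$roi_spec)))
  invisible(x)
}

#' Generate a synthetic BOLD run by HRF convolution
#'
#' Forward model of the single-trial GLM: each trial contributes its true
#' voxel betas times an impulse at the trial onset convolved with the
#' double-gamma hemodynamic response, plus i.i.d. Gaussian noise.
#'
#' @param onsets per-trial onset times in seconds (within the run).
#' @param true_betas trials x voxels matrix of true activation amplitudes.
#' @param tr repetition time in seconds.
#' @param n_scans number of volumes; `n_scans * tr` must exceed the last
#'   onset by at least 30 s so the response is fully sampled.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param run_id optional label.
#' @return A `bold_run`: list with `tr`, `n_scans`, `signal`
#'   (scans x voxels), `onsets`, `run_id`.
#' @export
gen_bold <- function(onsets, true_betas, tr, n_scans, noise_sd = 0,
                     seed = 1, run_id = "run1") {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  true_betas <- as.matrix(true_betas)
  if (length(onsets) != nrow(true_betas))
    stop("`true_betas` must have one row per onset")
  if (any(onsets < 0) || max(onsets) + 30 > n_scans * tr)
    stop("onsets must lie within the run, ending >= 30 s before the last scan")
  X <- .trial_regressors(onsets, n_scans, tr)
  signal <- X %*% true_betas
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    signal <- signal + matrix(stats::rnorm(length(signal), 0, noise_sd),
                              nrow(signal), ncol(signal))
  }
  structure(list(tr = tr, n_scans = as.integer(n_scans), signal = signal,
                 onsets = onsets, run_id = run_id),
            class = "bold_run")
}
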