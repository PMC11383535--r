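#' Corrected activity-pattern matrices for a synthetic study
#'
#' Applies the trial-exclusion rules, builds the Pearson APM per
#' participant, ROI and phase over valid old-item trials, and regresses out
#' temporal proximity. New items are excluded from the retrieval APMs so
#' both phases cover the same old-item set.
#'
#' @param study a [gen_study()] result.
#' @return list of entries (`participant`, `roi_id`, `roi_class`, `phase`,
#'   `apm`), the shape expected by [build_iraf_table()].
#' @export
study_apms <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  trials <- study$trials
  valid <- filter_trials(trials)
  valid_targets <- intersect(valid, trials$trial_id[trials$status == "target"])
  item_map <- stats::setNames(trials$concept_id, trials$trial_id)
  roi_spec <- study$design$roi_spec
  out <- list()
  for (pp in names(study$patterns)) {
    for (k in seq_len(nrow(roi_spec))) {
      roi <- roi_spec$roi_id[k]
      for (ph in c("encoding", "retrieval")) {
        bp <- beta_patterns(study$patterns[[pp]][[roi]][[ph]], roi_id = roi)
        apm <- build_apm(bp, valid_targets, item_map = item_map,
                         roi_id = roi, phase = ph)
        trsm <- build_time_rsm(trials, apm$trial_ids)
        out[[length(out) + 1L]] <- list(
          participant = pp, roi_id = roi, roi_class = roi_spec$roi_class[k],
          phase = ph, apm = regress_time(apm, trsm))
      }
    }
  }
  out
}

#' End-to-end IRAF table for a synthetic study
#'
#' Runs the full analysis front end: false-alarm-tendency flags and memory
#' label adjustment, visual and semantic model RSMs from the study's norms,
#' corrected APMs, and the long-format IRAF table.
#'
#' @param study a [gen_study()] result.
#' @param adjust_bias apply the "probably old" demotion for flagged
#'   participants (default `TRUE`).
#' @param fisher_z report Fisher-z IRAFs instead of raw correlations.
#' @return list with `iraf` (the analysis table), `trials` (labels
#'   resolved), `bias` (per-participant bias report), `rsms`.
#' @export
study_iraf_table <- function(study, adjust_bias = TRUE, fisher_z = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  trials <- study$trials
  bias <- behavior_bias_table(trials)
  flags <- stats::setNames(bias$flagged, bias$participant)
  if (!adjust_bias) flags[] <- FALSE
  trials <- adjust_memory_labels(trials, flags)
  rsms <- list(visual = build_model_rsm(study$norms, "visual"),
               semantic = build_model_rsm(study$norms, "semantic"))
  apms <- study_apms(study)
  iraf <- build_iraf_table(apms, rsms, trials, fisher_z = fisher_z)
  list(iraf = iraf, trials = trials, bias = bias, rsms = rsms)
}

#' Per-ROI mixed-model analysis of an IRAF table
#'
#' For every ROI, fits the three-factor model (memory success x memory
#' phase x feature type, full factorial) with participant and item random
#' intercepts, collects Type III F tests with Satterthwaite df, applies a
#' single Benjamini-Hochberg family across all ROIs and terms, runs the
#' phase-wise remembered-forgotten post hoc contrasts, and sorts each ROI's
#' interaction into a qualitative pattern. ROIs whose model fails to
#' converge are reported and excluded, never silently refitted.
#'
#' @param iraf IRAF table from [build_iraf_table()].
#' @param alpha significance level for the pattern gate.
#' @param flip_rule passed to [classify_flip_pattern()].
#' @return list with `effects` (per ROI x term, with FDR `q`), `posthoc`,
#'   `patterns` (per-ROI label), `nonconverged` (ROI ids).
#' @export
roi_effects <- function(iraf, alpha = 0.05,
                        flip_rule = "negative_estimate") {
  spec <- mixed_spec("iraf", fixed = c("memory", "phase", "feature_type"),
                     random = c("participant", "item"), interactions = TRUE)
  rois <- unique(iraf$roi_id)
  eff <- list(); ph <- list(); pat <- list(); bad <- character(0)
  for (roi in rois) {
    d <- iraf[iraf$roi_id == roi, ]
    res <- fit_lmm(d, spec)
    if (!res$converged) {
      bad <- c(bad, roi)
      next
    }
    a <- type3_anova(res)
    a <- cbind(roi_id = roi, a, stringsAsFactors = FALSE)
    eff[[length(eff) + 1L]] <- a
    ct <- posthoc_means(res, factor = "memory", by = "phase")
    ph[[length(ph) + 1L]] <- cbind(roi_id = roi, ct, stringsAsFactors = FALSE)
    pat[[length(pat) + 1L]] <- data.frame(
      roi_id = roi,
      pattern = classify_flip_pattern(ct, alpha = alpha, flip_rule = flip_rule),
      stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, eff)
  if (!is.null(effects)) effects$q <- fdr_adjust(effects$p)
  list(effects = effects,
       posthoc = do.call(rbind, ph),
       patterns = do.call(rbind, pat),
       nonconverged = bad)
}

.default_config <- function() {
  list(seed = 1,
       design = list(n_participants = 6, n_old = 40, n_catch = 6, n_new = 12,
                     n_runs_encoding = 2, n_runs_retrieval = 2, tr = 2,
                     iti_range = c(2, 7), p_dont_know = 0.08),
       rois = data.frame(roi_id = c("otc1", "ipc1", "flip1"),
                         roi_class = c("OTC-like", "IPC-like", "other"),
                         n_voxels = 24, stringsAsFactors = FALSE),
       norms = list(n_concepts = 60, n_visual = 30, n_semantic = 30,
                    cross_corr = 0.25),
       truth = list(strength = 1, noise_sd = 1),
       alpha = 0.05, flip_rule = "negative_estimate",
       fisher_z = FALSE, adjust_bias = TRUE,
       classifier = list(run = FALSE, n_sim = 200))
}

#' Run the full synthetic-study pipeline and write a report bundle
#'
#' Generates (or loads) the study, computes RSMs, APMs, IRAFs, the
#' behavioral report, per-ROI mixed models and interaction patterns, and
#' writes everything as CSV alongside a JSON manifest recording the
#' configuration, seed, package version, per-stage row counts, and any
#' non-converged ROI models.
#'
#' @param config named list overriding entries of the default
#'   configuration (see source of `memrsa:::.default_config`), or a path to
#'   a YAML file with the same structure.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
    if (!is.null(config$rois)) config$rois <- as.data.frame(config$rois)
  }
  cfg <- utils::modifyList(.default_config(), config)
  if (missing(out_dir)) stop("`out_dir` is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  norms <- gen_feature_norms(cfg$norms$n_concepts, cfg$norms$n_visual,
                             cfg$norms$n_semantic, cfg$norms$cross_corr,
                             seed = cfg$seed)
  design <- study_design(cfg$design$n_participants, cfg$design$n_old,
                         cfg$design$n_catch, cfg$design$n_new,
                         cfg$design$n_runs_encoding, cfg$design$n_runs_retrieval,
                         cfg$design$tr, cfg$design$iti_range, cfg$rois,
                         cfg$design$p_dont_know)
  truth <- default_planted_effects(cfg$truth$strength, cfg$truth$noise_sd)
  study <- gen_study(design, truth, norms, seed = cfg$seed)

  front <- study_iraf_table(study, adjust_bias = cfg$adjust_bias,
                            fisher_z = cfg$fisher_z)
  fits <- roi_effects(front$iraf, alpha = cfg$alpha,
                      flip_rule = cfg$flip_rule)
  hits <- summarize_hit_rates(hit_counts(front$trials))

  write_trial_table(front$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(front$iraf, file.path(out_dir, "iraf.csv"), row.names = FALSE)
  utils::write.csv(front$bias, file.path(out_dir, "behavior_bias.csv"),
                   row.names = FALSE)
  utils::write.csv(hits$per_participant, file.path(out_dir, "hit_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(fits$effects, file.path(out_dir, "roi_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(fits$posthoc, file.path(out_dir, "roi_posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(fits$patterns, file.path(out_dir, "roi_patterns.csv"),
                   row.names = FALSE)
  write_rsm_csv(front$rsms$visual, file.path(out_dir, "rsm_visual.csv"))
  write_rsm_csv(front$rsms$semantic, file.path(out_dir, "rsm_semantic.csv"))

  cls <- NULL
  if (isTRUE(cfg$classifier$run)) {
    cls <- classifier_report(front$iraf, n_sim = cfg$classifier$n_sim,
                             seed = cfg$seed)
    utils::write.csv(cls$by_roi, file.path(out_dir, "classifier_by_roi.csv"),
                     row.names = FALSE)
  }

  n_valid <- length(filter_trials(front$trials))
  manifest <- list(
    package = "memrsa",
    version = as.character(utils::packageVersion("memrsa")),
    seed = cfg$seed, config = cfg,
    rows = list(trials = nrow(front$trials), valid_trials = n_valid,
                dropped_trials = nrow(front$trials) - n_valid,
                iraf = nrow(front$iraf),
                effects = if (is.null(fits$effects)) 0L else nrow(fits$effects)),
    nonconverged_rois = fits$nonconverged,
    group_hit_rate = hits$group_mean)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(study = study, front = front, fits = fits, hits = hits,
                 classifier = cls, manifest = manifest))
}
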