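#' Apply the trial-exclusion rules to a trial table
#'
#' Excludes catch trials, target trials with a "don't know" / wrong-letter
#' press at encoding, and - because such a press means the participant could
#' not name the object - the retrieval trial of any item so flagged at
#' encoding. All other trials are retained.
#'
#' @param table a trial table (see [load_trial_table()] for the column
#'   dictionary).
#' @return character vector of retained `trial_id`s, in table order.
#' @export
filter_trials <- function(table) {
  if (anyDuplicated(table$trial_id))
    stop("duplicate trial ids: ",
         paste(unique(table$trial_id[duplicated(table$trial_id)]), collapse = ", "))
  enc_bad <- table$phase == "encoding" & table$status == "target" &
    table$response %in% c("dont_know", "no_match")
  flagged <- unique(paste(table$participant, table$concept_id)[enc_bad])
  drop <- table$status == "catch" | enc_bad |
    (paste(table$participant, table$concept_id) %in% flagged)
  table$trial_id[!drop]
}

#' Construct an activity-pattern matrix container
#'
#' @param values n x n numeric matrix.
#' @param trial_ids ordered trial identifiers.
#' @param item_ids optional concept labels aligned with `trial_ids`.
#' @param roi_id,phase optional metadata.
#' @param corrected whether the temporal-proximity regression has been
#'   applied (corrected matrices have an unused `NA` diagonal).
#' @export
apm_matrix <- function(values, trial_ids, item_ids = NULL, roi_id = NULL,
                       phase = NULL, corrected = FALSE) {
  values <- as.matrix(values)
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("APM must be symmetric")
  if (!corrected) {
    if (any(abs(diag(values) - 1) > 1e-12)) stop("uncorrected APM diagonal must be 1")
    off <- values[lower.tri(values)]
    if (any(off < -1 - 1e-12 | off > 1 + 1e-12))
      stop("uncorrected APM entries must lie in [-1, 1]")
  }
  structure(list(roi_id = roi_id, phase = phase, trial_ids = trial_ids,
                 item_ids = item_ids, values = values, corrected = corrected),
            class = "apm_matrix")
}

#' Build an activity-pattern matrix from single-trial betas
#'
#' Cell (i, j) is the Pearson correlation between the voxel activation
#' vectors of trials i and j, restricted to the valid trials.
#'
#' @param betas a [beta_patterns()] object.
#' @param valid_ids trial ids to retain (order of `betas` is kept).
#' @param item_map optional named vector mapping trial id -> concept id,
#'   stored as `item_ids`.
#' @param roi_id,phase optional metadata.
#' @return An uncorrected [apm_matrix()].
#' @export
build_apm <- function(betas, valid_ids, item_map = NULL, roi_id = NULL,
                      phase = NULL) {
  stopifnot(inherits(betas, "beta_patterns"))
  keep <- betas$trial_ids[betas$trial_ids %in% valid_ids]
  m <- betas$values[keep, , drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 voxels")
  if (nrow(m) < 3) stop("need >= 3 valid trials")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance voxel vector for trial(s): ",
         paste(keep[sds == 0], collapse = ", "))
  item_ids <- if (!is.null(item_map)) unname(item_map[keep]) else NULL
  apm_matrix(stats::cor(t(m)), trial_ids = keep, item_ids = item_ids,
             roi_id = if (is.null(roi_id)) betas$roi_id else roi_id,
             phase = phase, corrected = FALSE)
}

#' Build a temporal-proximity RSM
#'
#' Within a run, cell (i, j) is `1 - |t_i - t_j| / D_run` where `D_run` is
#' the largest within-run onset distance, so trials at the same time score 1
#' and the two furthest-apart trials in a run score 0. Trials in different
#' runs score 0 (no shared scanner drift across runs), and a run holding a
#' single valid trial contributes only its diagonal 1.
#'
#' @param table trial table containing the valid trials (with `onset` and
#'   `run`).
#' @param valid_ids trial ids, in the order used for the matching APM.
#' @return A `time_rsm`: list with `trial_ids` and `values` in `[0, 1]`.
#' @export
build_time_rsm <- function(table, valid_ids) {
  idx <- match(valid_ids, table$trial_id)
  if (anyNA(idx)) stop("valid ids missing from table: ",
                       paste(valid_ids[is.na(idx)], collapse = ", "))
  run <- table$run[idx]
  onset <- table$onset[idx]
  n <- length(valid_ids)
  values <- matrix(0, n, n)
  for (r in unique(run)) {
    k <- which(run == r)
    if (length(k) < 2) next
    d <- abs(outer(onset[k], onset[k], "-"))
    values[k, k] <- 1 - d / max(d)
  }
  diag(values) <- 1
  structure(list(trial_ids = valid_ids, values = values), class = "time_rsm")
}

#' Regress temporal proximity out of an APM
#'
#' Replaces the off-diagonal lower-triangle cells of the APM by the
#' residuals of an OLS fit (with intercept) of the APM cells on the
#' time-RSM cells, then re-symmetrizes. The intercept is not re-added:
#' downstream item-wise fits use correlations, which are shift-invariant.
#' If the time RSM is constant off the diagonal there is nothing to regress
#' and the APM is mean-centered instead (with a warning).
#'
#' @param apm an uncorrected [apm_matrix()].
#' @param time_rsm a [build_time_rsm()] result with the same trial order.
#' @return The corrected [apm_matrix()] (diagonal marked unused).
#' @export
regress_time <- function(apm, time_rsm) {
  stopifnot(inherits(apm, "apm_matrix"))
  if (apm$corrected) stop("APM is already corrected")
  if (!identical(apm$trial_ids, time_rsm$trial_ids))
    stop("APM and time RSM must share trial ordering")
  y <- .lower_vec(apm$values)
  x <- .lower_vec(time_rsm$values)
  if (stats::sd(x) == 0) {
    warning("time RSM constant off the diagonal; falling back to mean-centering")
    resid <- y - mean(y)
  } else {
    resid <- .ols_resid(y, x)
  }
  values <- .refold(resid, length(apm$trial_ids))
  apm_matrix(values, trial_ids = apm$trial_ids, item_ids = apm$item_ids,
             roi_id = apm$roi_id, phase = apm$phase, corrected = TRUE)
}
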