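# canonical double-gamma parameters: 6 s peak, 16 s undershoot, unit
# dispersions, peak/undershoot ratio 6
.hrf_defaults <- list(peak_delay = 6, undershoot_delay = 16,
                      peak_disp = 1, undershoot_disp = 1, p_u_ratio = 6)

# unnormalized double-gamma evaluated at arbitrary times (0 for t < 0)
.dg_raw <- function(t, p) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- stats::dgamma(t[pos], shape = p$peak_delay / p$peak_disp,
                            scale = p$peak_disp) -
    stats::dgamma(t[pos], shape = p$undershoot_delay / p$undershoot_disp,
                  scale = p$undershoot_disp) / p$p_u_ratio
  out
}

# continuous peak value, used so sampled and per-onset evaluations share one
# normalization
.dg_peak <- function(p) max(.dg_raw(seq(0, 30, by = 0.01), p))

.hrf_params <- function(...) {
  p <- utils::modifyList(.hrf_defaults, list(...))
  if (p$peak_disp <= 0 || p$undershoot_disp <= 0)
    stop("HRF dispersions must be positive")
  p
}

#' Sampled double-gamma hemodynamic response function
#'
#' The canonical HRF model: a gamma density peaking near 6 s minus a scaled
#' gamma density modeling the late undershoot, peak-normalized to a maximum
#' of 1 (on the continuous curve).
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (>= 24).
#' @param peak_delay,undershoot_delay gamma delays in seconds.
#' @param peak_disp,undershoot_disp gamma dispersions in seconds (> 0).
#' @param p_u_ratio peak-to-undershoot amplitude ratio.
#' @return numeric kernel sampled at `seq(0, duration, by = tr)`.
#' @examples
#' h <- double_gamma_hrf(tr = 1)
#' which.max(h) # peak a few seconds post stimulus
#' @export
double_gamma_hrf <- function(tr, duration = 32, peak_delay = 6,
                             undershoot_delay = 16, peak_disp = 1,
                             undershoot_disp = 1, p_u_ratio = 6) {
  if (tr <= 0) stop("`tr` must be > 0")
  if (duration < 24) stop("`duration` must be >= 24 s")
  p <- .hrf_params(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                   peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                   p_u_ratio = p_u_ratio)
  t <- seq(0, duration, by = tr)
  .dg_raw(t, p) / .dg_peak(p)
}

# scans x trials matrix of HRF-convolved impulse regressors; scan k sampled
# at time (k - 1) * tr
.trial_regressors <- function(onsets, n_scans, tr, hrf_control = list()) {
  p <- do.call(.hrf_params, hrf_control)
  peak <- .dg_peak(p)
  t_scan <- (seq_len(n_scans) - 1) * tr
  X <- vapply(onsets, function(o) .dg_raw(t_scan - o, p) / peak,
              numeric(n_scans))
  matrix(X, nrow = n_scans)
}

#' Build a single-trial design matrix
#'
#' One column per trial (an impulse at the trial onset convolved with the
#' double-gamma HRF, truncated to the run), followed by any nuisance
#' regressors and a trailing intercept. All trials are modeled
#' simultaneously in one design, so closely spaced trials share variance in
#' the least-squares fit rather than being estimated one-versus-rest.
#'
#' @param onsets per-trial onset seconds; names (if any) become trial ids.
#' @param n_scans number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param nuisance optional numeric matrix of nuisance regressors
#'   (`n_scans` rows); column names are kept in the roles.
#' @param hrf_control named list overriding HRF parameters (see
#'   [double_gamma_hrf()]).
#' @return A `design_matrix`: list with `matrix`
#'   (scans x (trials + nuisance + 1)) and `column_roles`
#'   (`"trial:<id>"`, `"nuisance:<name>"`, `"intercept"`).
#' @export
build_design <- function(onsets, n_scans, tr, nuisance = NULL,
                         hrf_control = list()) {
  ids <- names(onsets)
  if (is.null(ids)) ids <- sprintf("trial_%d", seq_along(onsets))
  run_end <- n_scans * tr
  bad <- which(onsets < 0 | onsets >= run_end)
  if (length(bad))
    stop("onset outside run for trial(s): ", paste(ids[bad], collapse = ", "))
  X <- .trial_regressors(onsets, n_scans, tr, hrf_control)
  roles <- paste0("trial:", ids)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans)
      stop("nuisance regressors must have `n_scans` rows")
    nn <- colnames(nuisance)
    if (is.null(nn)) nn <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    roles <- c(roles, paste0("nuisance:", nn))
  }
  X <- cbind(X, 1)
  roles <- c(roles, "intercept")
  colnames(X) <- roles
  structure(list(matrix = X, column_roles = roles), class = "design_matrix")
}

#' Estimate single-trial betas by ordinary least squares
#'
#' Fits the full design to every voxel simultaneously and returns only the
#' trial-role coefficients, in trial order. A rank-deficient design (for
#' example, exactly collinear trial regressors) raises an explicit error
#' rather than silently pseudo-inverting.
#'
#' @param run a [gen_bold()] run (or any list with `signal` scans x voxels
#'   and `n_scans`).
#' @param design a [build_design()] result with `n_scans` rows.
#' @param roi_id optional label carried through to the output.
#' @return A `beta_patterns`: list with `roi_id`, `trial_ids`, and `values`
#'   (trials x voxels matrix of GLM betas).
#' @export
estimate_betas <- function(run, design, roi_id = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  Y <- as.matrix(run$signal)
  if (nrow(X) != nrow(Y))
    stop("design rows must equal the number of scans in the run")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qx$rank, " < ",
         ncol(X), " columns)")
  coefs <- qr.coef(qx, Y) # design columns x voxels
  trial_cols <- grep("^trial:", design$column_roles)
  values <- coefs[trial_cols, , drop = FALSE]
  trial_ids <- sub("^trial:", "", design$column_roles[trial_cols])
  rownames(values) <- trial_ids
  beta_patterns(values, trial_ids = trial_ids, roi_id = roi_id)
}

#' Construct a beta-patterns container
#'
#' @param values trials x voxels numeric matrix.
#' @param trial_ids ordered trial identifiers (defaults to rownames).
#' @param roi_id optional ROI label.
#' @export
beta_patterns <- function(values, trial_ids = rownames(values), roi_id = NULL) {
  values <- as.matrix(values)
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%d", seq_len(nrow(values)))
  if (anyDuplicated(trial_ids)) stop("duplicate trial ids")
  if (!all(is.finite(values))) stop("beta values must be finite")
  rownames(values) <- trial_ids
  structure(list(roi_id = roi_id, trial_ids = trial_ids, values = values),
            class = "beta_patterns")
}
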