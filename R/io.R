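.trial_columns <- c("trial_id", "participant", "phase", "run", "slot",
                    "onset", "concept_id", "status", "response", "valid",
                    "memory")
.response_vocab <- c("1", "2", "3", "4", "none", "no_match", "dont_know")

#' Validate a trial table
#'
#' Enforces the column dictionary and type invariants: unique trial ids,
#' known phase/status/response/memory vocabularies, catch trials invalid,
#' new items only at retrieval, memory labels only on valid old-item
#' trials.
#'
#' @param table data frame to validate.
#' @return the table, invisibly, or an error naming the offending rows.
#' @export
validate_trial_table <- function(table) {
  miss <- setdiff(.trial_columns, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$trial_id))
    stop("duplicate trial id(s): ",
         paste(unique(table$trial_id[duplicated(table$trial_id)]), collapse = ", "))
  chk <- function(col, vocab) {
    bad <- which(!(table[[col]] %in% vocab))
    if (length(bad))
      stop("unknown ", col, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), ": ",
           paste(unique(table[[col]][bad]), collapse = ", "))
  }
  chk("phase", c("encoding", "retrieval"))
  chk("status", c("target", "catch", "new"))
  chk("response", .response_vocab)
  chk("memory", c("remembered", "forgotten", "not_applicable"))
  bad <- which(table$status == "new" & table$phase == "encoding")
  if (length(bad))
    stop("status 'new' during encoding in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(table$status == "catch" & table$valid)
  if (length(bad))
    stop("catch trials must be invalid; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(table$memory != "not_applicable" &
                 !(table$status == "target" & table$valid))
  if (length(bad))
    stop("memory labels only allowed on valid old-item trials; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(table)
}

#' Read a trial table from CSV
#'
#' @param path CSV with the documented column dictionary: `trial_id`,
#'   `participant`, `phase` (encoding/retrieval), `run`, `slot`, `onset`
#'   (seconds), `concept_id`, `status` (target/catch/new), `response`
#'   (1-4, none, no_match, dont_know), `valid` (logical), `memory`
#'   (remembered/forgotten/not_applicable).
#' @return validated data frame.
#' @export
load_trial_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(response = "character"))
  t$valid <- as.logical(t$valid)
  validate_trial_table(t)
  t
}

#' Write a trial table to CSV
#'
#' @param table validated trial table.
#' @param path output file.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a similarity matrix as CSV with item-id headers
#'
#' @param m matrix with item ids as dimnames (or a `model_rsm`).
#' @param path CSV path.
#' @export
write_rsm_csv <- function(m, path) {
  if (inherits(m, "model_rsm")) m <- m$values
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rsm_csv
#' @export
read_rsm_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Extract per-ROI trial patterns from NIfTI beta and mask volumes
#'
#' The real-data entry point: a 4-D beta volume (x, y, z, trial) and an
#' integer-labeled 3-D ROI mask on the same grid yield one trials-by-voxels
#' matrix per ROI label, voxels in mask order.
#'
#' @param beta_path path to the 4-D NIfTI beta volume.
#' @param mask_path path to the 3-D integer NIfTI ROI mask.
#' @param trial_ids optional trial ids (defaults to `trial_<k>`).
#' @param labels optional integer labels to extract; labels absent from the
#'   mask are skipped with a warning. Defaults to all nonzero mask labels.
#' @return named list of [beta_patterns()], one per ROI label.
#' @export
load_roi_patterns <- function(beta_path, mask_path, trial_ids = NULL,
                              labels = NULL) {
  betas <- RNifti::readNifti(beta_path)
  mask <- RNifti::readNifti(mask_path)
  pad <- function(d, n) c(d, rep(1L, max(0, n - length(d))))[seq_len(n)]
  db <- dim(betas); dm <- pad(dim(mask), 3)
  if (length(db) != 4) stop("beta volume must be 4-D (x, y, z, trial)")
  if (!identical(as.integer(db[1:3]), as.integer(dm)))
    stop("spatial grid mismatch between beta volume and mask")
  n_trials <- db[4]
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%d", seq_len(n_trials))
  flat <- matrix(as.numeric(betas), prod(db[1:3]), n_trials)
  mask_v <- as.integer(round(as.numeric(mask)))
  present <- sort(unique(mask_v[mask_v != 0]))
  if (is.null(labels)) labels <- present
  out <- list()
  for (lab in labels) {
    idx <- which(mask_v == lab)
    if (!length(idx)) {
      warning("ROI label ", lab, " absent from mask; skipped")
      next
    }
    out[[as.character(lab)]] <- beta_patterns(t(flat[idx, , drop = FALSE]),
                                              trial_ids = trial_ids,
                                              roi_id = as.character(lab))
  }
  out
}

#' Write trial patterns as a 4-D NIfTI beta volume
#'
#' Inverse of [load_roi_patterns()] for synthetic data: lays the voxels of
#' each ROI out along x at the given mask labels.
#'
#' @param patterns named list of [beta_patterns()] (same trial count).
#' @param beta_path,mask_path output NIfTI paths.
#' @export
write_roi_patterns <- function(patterns, beta_path, mask_path) {
  n_trials <- nrow(patterns[[1]]$values)
  n_vox_total <- sum(vapply(patterns, function(p) ncol(p$values), integer(1)))
  dimx <- n_vox_total
  beta <- array(0, c(dimx, 1, 1, n_trials))
  mask <- array(0L, c(dimx, 1, 1))
  at <- 0L
  for (k in seq_along(patterns)) {
    nv <- ncol(patterns[[k]]$values)
    beta[at + seq_len(nv), 1, 1, ] <- t(patterns[[k]]$values)
    mask[at + seq_len(nv), 1, 1] <- k
    at <- at + nv
  }
  RNifti::writeNifti(RNifti::asNifti(beta), beta_path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  invisible(c(beta_path, mask_path))
}
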